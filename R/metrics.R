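#' Two-component Gaussian mixture fit
#'
#' EM fit of a 2-Gaussian mixture to a Centiloid distribution; the
#' lower-mean component is the first peak, used as a proxy for the
#' amyloid-negative distribution. Initialisation is seeded (random pairs of
#' observations as starting means, best of `restarts` by log-likelihood), so
#' the fit is deterministic given the seed.
#'
#' @param values Numeric vector (>= 20 values, non-degenerate).
#' @param seed Integer seed.
#' @param restarts Number of seeded EM restarts.
#' @return Object of class `gmm2`: `means`, `sds`, `weights` (summing to 1),
#'   `first_peak` (index of the lower-mean component), `loglik`.
#' @export
fit_gmm2 <- function(values, seed = 0L, restarts = 10L) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 20L) stop("fit_gmm2 needs at least 20 values")
  v0 <- stats::var(values)
  if (v0 <= 0) stop("degenerate sample: zero variance")
  floor_var <- 1e-6 * v0
  em <- function(mu, sd_, w) {
    ll_old <- -Inf
    for (it in 1:500) {
      d1 <- w[1] * stats::dnorm(values, mu[1], sd_[1])
      d2 <- w[2] * stats::dnorm(values, mu[2], sd_[2])
      tot <- d1 + d2
      tot[tot <= 0] <- .Machine$double.xmin
      ll <- sum(log(tot))
      r <- d1 / tot
      n1 <- sum(r); n2 <- n - n1
      if (n1 < 1e-8 || n2 < 1e-8) break
      mu <- c(sum(r * values) / n1, sum((1 - r) * values) / n2)
      sd_ <- sqrt(pmax(c(sum(r * (values - mu[1])^2) / n1,
                         sum((1 - r) * (values - mu[2])^2) / n2), floor_var))
      w <- c(n1, n2) / n
      if (abs(ll - ll_old) < 1e-10 * (1 + abs(ll))) break
      ll_old <- ll
    }
    list(mu = mu, sd = sd_, w = w, ll = ll)
  }
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(restarts)) {
      mu0 <- if (r == 1L) stats::quantile(values, c(0.25, 0.75), names = FALSE)
             else sort(sample(values, 2L))
      if (diff(mu0) == 0) mu0 <- mu0 + c(-1, 1) * sqrt(v0) / 2
      fit <- em(mu0, rep(stats::sd(values) / 2, 2L), c(0.5, 0.5))
      if (is.null(best) || fit$ll > best$ll) best <- fit
    }
  })
  fp <- which.min(best$mu)
  structure(list(means = best$mu, sds = best$sd, weights = best$w,
                 first_peak = fp, loglik = best$ll), class = "gmm2")
}

#' @export
print.gmm2 <- function(x, ...) {
  cat(sprintf("<gmm2> peak1 N(%.2f, %.2f) w=%.2f | peak2 N(%.2f, %.2f) w=%.2f\n",
              x$means[x$first_peak], x$sds[x$first_peak], x$weights[x$first_peak],
              x$means[-x$first_peak], x$sds[-x$first_peak], x$weights[-x$first_peak]))
  invisible(x)
}

# Convenience accessors for the amyloid-negative peak.
first_peak_mean <- function(fit) fit$means[fit$first_peak]
first_peak_sd <- function(fit) fit$sds[fit$first_peak]

#' Derive a longitudinal outlier band from reference rates
#'
#' Central interval covering `percentile`% of the reference annual-rate
#' distribution (for 90, the 5th to 95th percentiles), the convention that
#' produces an asymmetric band such as `[-5.8, 11.2]` CL/year from a
#' right-skewed accumulation-rate sample.
#'
#' @param reference_rates >= 50 reference CL/year values.
#' @param percentile Central mass to cover (default 90).
#' @return Object of class `outlier_band` with `lower` and `upper`.
#' @export
derive_outlier_band <- function(reference_rates, percentile = 90) {
  reference_rates <- reference_rates[is.finite(reference_rates)]
  if (length(reference_rates) < 50L) stop("need at least 50 reference rates")
  tail_ <- (100 - percentile) / 200
  q <- stats::quantile(reference_rates, c(tail_, 1 - tail_), names = FALSE)
  if (q[1] >= q[2]) stop("degenerate band: reference rates have no spread")
  structure(list(lower = q[1], upper = q[2]), class = "outlier_band")
}

#' @export
print.outlier_band <- function(x, ...) {
  cat(sprintf("<outlier_band> [%.2f, %.2f] CL/year\n", x$lower, x$upper))
  invisible(x)
}

#' Percentage of longitudinal rate outliers
#'
#' @param rates Annual rates (CL/year) of consecutive visit pairs.
#' @param band An [derive_outlier_band()] band (or list with lower/upper).
#' @return Named vector `c(neg_pct, pos_pct)`: percentage below/above band.
#' @export
outlier_fraction <- function(rates, band) {
  if (!length(rates)) return(c(neg_pct = 0, pos_pct = 0))
  c(neg_pct = 100 * mean(rates < band$lower),
    pos_pct = 100 * mean(rates > band$upper))
}

#' Hilbert-Schmidt Independence Criterion
#'
#' Biased empirical HSIC `(1/n^2) tr(K H L H)` with Gaussian kernels and
#' median-heuristic bandwidths, measuring (possibly nonlinear) statistical
#' dependence between two samples. Optionally returns a permutation p-value.
#'
#' @param x,y Numeric vectors of equal length (>= 10).
#' @param n_perm If > 0, number of permutations for a p-value.
#' @param seed Seed for the permutations.
#' @return HSIC value; with permutations, attributes `p_value` and `null`
#'   (the permutation null sample).
#' @export
hsic <- function(x, y, n_perm = 0L, seed = 0L) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 10L) stop("hsic needs at least 10 observations")
  gram <- function(v) {
    d2 <- outer(v, v, `-`)^2
    md <- stats::median(sqrt(d2[d2 > 0]))
    if (!is.finite(md) || md == 0) md <- 1
    exp(-d2 / (2 * md^2))
  }
  K <- gram(x)
  L <- gram(y)
  centre <- function(M) {
    cm <- colMeans(M)
    sweep(sweep(M, 1L, rowMeans(M)), 2L, cm) + mean(M)
  }
  Kc <- centre(K)
  val <- sum(Kc * L) / n^2  # tr(KH L H) = <HKH, L>
  if (n_perm > 0L) {
    null <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
      p <- sample(n)
      sum(Kc * L[p, p]) / n^2
    }, 0))
    attr(val, "p_value") <- (1 + sum(null >= val)) / (n_perm + 1)
    attr(val, "null") <- null
  }
  val
}

#' Rank, effect-size and discrimination statistics
#'
#' `spearman`: rank correlation with average ranks for ties. `r_squared`:
#' squared Pearson correlation. `cohens_d`: mean difference over the pooled
#' standard deviation. `auc`: area under the ROC curve via the rank
#' statistic, ties counted half.
#'
#' @param x,y,a,b Numeric vectors.
#' @param scores Classifier scores; `labels` 0/1 or logical.
#' @param labels Binary labels for `auc`.
#' @export
spearman <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("degenerate variance")
  stats::cor(rank(x), rank(y))
}

#' @rdname spearman
#' @export
r_squared <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("degenerate variance")
  stats::cor(x, y)^2
}

#' @rdname spearman
#' @export
cohens_d <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp <- sqrt(((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2))
  if (!is.finite(sp) || sp == 0) stop("degenerate variance")
  (mean(a) - mean(b)) / sp
}

#' @rdname spearman
#' @export
auc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("auc needs both classes")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Paired bootstrap comparison of two methods
#'
#' Resamples matched units with replacement, computes the metric difference
#' (method A minus method B) per resample, and reports the mean difference,
#' its 95% percentile interval, and the non-parametric p-value: the
#' proportion of resamples whose difference sign opposes the mean
#' difference. Significance at p < 0.05 corresponds to the 95% interval
#' excluding zero.
#'
#' @param values_a,values_b Matched per-unit values for the two methods, or
#'   lists/matrices if `metric_fn` needs more structure.
#' @param metric_fn Summary metric applied to a resampled vector (default
#'   [mean]).
#' @param n_boot Number of bootstrap resamples (default 10000).
#' @param seed Seed; fixed seed gives identical output.
#' @return List: `mean_diff`, `ci95`, `p`, `n_boot`.
#' @export
paired_bootstrap <- function(values_a, values_b, metric_fn = mean,
                             n_boot = 10000L, seed = 0L) {
  n <- if (is.matrix(values_a)) nrow(values_a) else length(values_a)
  stopifnot((if (is.matrix(values_b)) nrow(values_b) else length(values_b)) == n)
  take <- function(v, idx) if (is.matrix(v)) v[idx, , drop = FALSE] else v[idx]
  diffs <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    metric_fn(take(values_a, idx)) - metric_fn(take(values_b, idx))
  }, 0))
  md <- mean(diffs)
  p <- if (md == 0) 1 else mean(sign(diffs) != sign(md))
  list(mean_diff = md, ci95 = stats::quantile(diffs, c(0.025, 0.975), names = FALSE),
       p = p, n_boot = n_boot)
}

#' Cross-study stability of the amyloid-negative peak
#'
#' Compares two methods' first-peak statistics across studies: the metric is
#' the standard deviation across studies of the first-peak means (and,
#' separately, of the first-peak SDs), compared by paired bootstrap with the
#' study as the resampling unit. A negative mean difference means method A
#' is more stable.
#'
#' @param fits_a,fits_b Per-study lists of [fit_gmm2()] fits (>= 3 studies),
#'   matched by study.
#' @param n_boot,seed Passed to [paired_bootstrap()].
#' @return List with `means` and `sds` bootstrap comparisons.
#' @export
peak_stability <- function(fits_a, fits_b, n_boot = 10000L, seed = 0L) {
  stopifnot(length(fits_a) == length(fits_b))
  if (length(fits_a) < 3L) stop("peak_stability needs at least 3 studies")
  pm_a <- vapply(fits_a, first_peak_mean, 0); pm_b <- vapply(fits_b, first_peak_mean, 0)
  ps_a <- vapply(fits_a, first_peak_sd, 0); ps_b <- vapply(fits_b, first_peak_sd, 0)
  sd_metric <- function(v) stats::sd(v)
  list(means = paired_bootstrap(pm_a, pm_b, sd_metric, n_boot, seed),
       sds = paired_bootstrap(ps_a, ps_b, sd_metric, n_boot, seed))
}

#' Classify emerging amyloid pathology
#'
#' A participant with a baseline amyloid-negative scan (CL below the
#' positivity threshold, conventionally 30) and at least
#' `min_followup_years` of follow-up is Emergent-positive if any follow-up
#' scan crosses the threshold, otherwise stable-negative. Baselines at 5 CL
#' and above are also assigned a 5-CL-wide baseline bracket in `[5, 30)`.
#'
#' @param cls Longitudinal Centiloid series, sorted by time.
#' @param times_years Acquisition times in years (same order).
#' @param threshold Positivity threshold (default 30 CL).
#' @param min_followup_years Minimum follow-up span (default 4.5).
#' @return List: `label` ("emergent_positive", "stable_negative" or
#'   "ineligible"), `eligible`, `baseline_bracket` (e.g. "[10,15)" or NA).
#' @export
emergent_classification <- function(cls, times_years, threshold = 30,
                                    min_followup_years = 4.5) {
  stopifnot(length(cls) == length(times_years), !is.unsorted(times_years))
  baseline <- cls[1]
  span <- times_years[length(times_years)] - times_years[1]
  bracket <- NA_character_
  if (baseline >= 5 && baseline < threshold) {
    lo <- 5 * (baseline %/% 5)
    bracket <- sprintf("[%d,%d)", lo, lo + 5)
  }
  if (baseline >= threshold || span < min_followup_years)
    return(list(label = "ineligible", eligible = FALSE, baseline_bracket = bracket))
  pos <- any(cls[-1] >= threshold)
  list(label = if (pos) "emergent_positive" else "stable_negative",
       eligible = TRUE, baseline_bracket = bracket)
}
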