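#' Build longitudinal visit pairs
#'
#' For each participant, forms every ordered pair of scans acquired at least
#' 3 months but no more than 3.5 years apart (for three eligible visits the
#' pairs are 1-2, 2-3 and 1-3). Pairs never cross participants.
#'
#' @param scans List of [scan_record()]s (any order; sorted internally).
#' @param min_years,max_years Interval window in years (defaults 0.25, 3.5).
#' @return List of `visit_pair` objects: `scan_t0`, `scan_t1`,
#'   `interval_years`, `participant_id`.
#' @export
build_pairs <- function(scans, min_years = 0.25, max_years = 3.5) {
  if (!length(scans)) return(list())
  ids <- vapply(scans, function(s) s$participant_id, "")
  pairs <- list()
  for (id in unique(ids)) {
    ss <- scans[ids == id]
    ss <- ss[order(vapply(ss, function(s) as.numeric(s$date), 0))]
    n <- length(ss)
    if (n < 2L) next
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      dt <- as.numeric(ss[[j]]$date - ss[[i]]$date) / 365.25
      if (dt >= min_years && dt <= max_years) {
        pairs[[length(pairs) + 1L]] <- structure(
          list(scan_t0 = ss[[i]], scan_t1 = ss[[j]],
               interval_years = dt, participant_id = id),
          class = "visit_pair")
      }
    }
  }
  pairs
}

#' Mean level and annual rate for a visit pair
#'
#' Given the Centiloid values at the two timepoints, returns the pair's mean
#' Centiloid `(CL_T0 + CL_T1)/2` and rate of change `(CL_T1 - CL_T0)/dt` in
#' CL/year.
#'
#' @param pair A `visit_pair` (or anything with `interval_years`).
#' @param cl_t0,cl_t1 Centiloid values at the earlier/later scan.
#' @return Named numeric vector `c(mean_cl, rate_cl_per_year)`.
#' @export
pair_statistics <- function(pair, cl_t0, cl_t1) {
  dt <- pair$interval_years
  if (!is.finite(dt) || dt <= 0) stop("interval_years must be positive")
  c(mean_cl = (cl_t0 + cl_t1) / 2, rate_cl_per_year = (cl_t1 - cl_t0) / dt)
}

#' Fit the natural-history curve of amyloid accumulation
#'
#' Fits a lowess smooth fc relating the pairwise mean Centiloid to the
#' expected annual Centiloid change, the population-level temporal prior used
#' by the training loss. The smooth (tricube weights, one robustness
#' iteration) is evaluated on a uniform grid and linearly interpolated;
#' outside the observed support fc clamps to its boundary values.
#'
#' @param mean_cls,rates Matched numeric vectors (>= 20 pairs).
#' @param smoothing_fraction Lowess span in (0, 1], default 0.2.
#' @param grid_points Evaluation grid size (default 256).
#' @return Object of class `natural_history_curve`; evaluate it with
#'   [predict.natural_history_curve()].
#' @export
fit_natural_history <- function(mean_cls, rates, smoothing_fraction = 0.2,
                                grid_points = 256L) {
  if (length(mean_cls) != length(rates)) stop("mean_cls and rates must match")
  ok <- is.finite(mean_cls) & is.finite(rates)
  mean_cls <- mean_cls[ok]; rates <- rates[ok]
  if (length(mean_cls) < 20L) stop("insufficient pairs (need at least 20)")
  if (smoothing_fraction <= 0 || smoothing_fraction > 1)
    stop("smoothing_fraction must be in (0, 1]")
  lw <- stats::lowess(mean_cls, rates, f = smoothing_fraction, iter = 1L)
  # collapse duplicate x before interpolation
  agg <- tapply(lw$y, lw$x, mean)
  xs <- as.numeric(names(agg)); ys <- as.numeric(agg)
  support <- range(mean_cls)
  gx <- if (diff(support) > 0) seq(support[1], support[2], length.out = grid_points) else support[1]
  gy <- if (length(xs) > 1L) stats::approx(xs, ys, xout = gx, rule = 2)$y else rep(ys, length(gx))
  structure(list(x = gx, y = gy, support_range = support,
                 smoothing_fraction = smoothing_fraction),
            class = "natural_history_curve")
}

#' Evaluate the natural-history curve
#'
#' @param object A `natural_history_curve`.
#' @param newdata Mean-Centiloid values at which to evaluate fc; clamped to
#'   the fitted support.
#' @param ... Unused.
#' @return Expected CL/year at `newdata`.
#' @export
predict.natural_history_curve <- function(object, newdata, ...) {
  if (length(object$x) == 1L) return(rep(object$y, length(newdata)))
  stats::approx(object$x, object$y, xout = pmin(pmax(newdata, object$x[1]),
                                                object$x[length(object$x)]),
                rule = 2)$y
}

# Piecewise-linear slope of fc at x (0 outside the support, where fc clamps).
curve_slope <- function(curve, x) {
  if (length(curve$x) == 1L) return(rep(0, length(x)))
  gx <- curve$x; gy <- curve$y
  slopes <- diff(gy) / diff(gx)
  i <- findInterval(x, gx)
  out <- numeric(length(x))
  inside <- i >= 1L & i < length(gx)
  out[inside] <- slopes[i[inside]]
  out[x < gx[1] | x > gx[length(gx)]] <- 0
  out
}

#' @export
print.natural_history_curve <- function(x, ...) {
  cat(sprintf("<natural_history_curve> lowess span %.2f on [%.1f, %.1f] CL; peak rate %.2f CL/yr\n",
              x$smoothing_fraction, x$support_range[1], x$support_range[2], max(x$y)))
  invisible(x)
}

#' Save / load a fitted curve as JSON
#'
#' @param curve A `natural_history_curve`.
#' @param path JSON file path.
#' @export
write_curve <- function(curve, path) {
  jsonlite::write_json(unclass(curve), path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_curve
#' @export
read_curve <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(x = obj$x, y = obj$y, support_range = obj$support_range,
                 smoothing_fraction = obj$smoothing_fraction[1]),
            class = "natural_history_curve")
}
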