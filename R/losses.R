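#' Loss weights for trajectory-constrained training
#'
#' The combined training loss is `L = mean(Ld) + alpha*mean(Lc) + beta*Ls +
#' gamma*Li` with defaults alpha = 0.2, beta = 1, gamma = 0.01.
#'
#' @param alpha Weight of the curve-deviation loss Lc.
#' @param beta Weight of the anchor slope loss Ls.
#' @param gamma Weight of the anchor intercept loss Li.
#' @export
loss_weights <- function(alpha = 0.2, beta = 1, gamma = 0.01) {
  stopifnot(alpha >= 0, beta >= 0, gamma >= 0)
  structure(list(alpha = alpha, beta = beta, gamma = gamma), class = "loss_weights")
}

#' Monotonicity loss: penalise Centiloid decrease over time
#'
#' `Ld = max(0, CL_T0 - CL_T1)`: in an observational cohort amyloid burden
#' should not decrease, so any decrease is penalised proportionally.
#'
#' @param cl_t0,cl_t1 Corrected Centiloid at the earlier/later timepoint.
#' @return Non-negative loss (vectorised).
#' @export
loss_decrease <- function(cl_t0, cl_t1) pmax(0, cl_t0 - cl_t1)

#' Curve loss: penalise deviation from the natural-history rate
#'
#' `Lc = |(CL_T1 - CL_T0)/dt - fc((CL_T0 + CL_T1)/2)|`: the pair's annual
#' rate should match the expected rate fc at its mean Centiloid.
#'
#' @param cl_t0,cl_t1 Corrected Centiloid values.
#' @param interval_years Positive interval between the scans.
#' @param curve A [fit_natural_history()] curve.
#' @return Non-negative loss (vectorised).
#' @export
loss_curve <- function(cl_t0, cl_t1, interval_years, curve) {
  stopifnot(all(interval_years > 0))
  rate <- (cl_t1 - cl_t0) / interval_years
  abs(rate - predict(curve, (cl_t0 + cl_t1) / 2))
}

#' Anchor loss: keep corrected Centiloids on the uncorrected scale
#'
#' Ordinary least squares of the corrected on the uncorrected Centiloids over
#' the whole batch; with slope `s` and intercept `i`, `Ls = |s - 1|` and
#' `Li = |i|`. This prevents the correction from collapsing or drifting away
#' from the Centiloid scale.
#'
#' @param corrected_cls,uncorrected_cls Matched batch vectors (length >= 3).
#' @return Named vector `c(Ls, Li)` with attributes `slope` and `intercept`.
#' @export
loss_anchor <- function(corrected_cls, uncorrected_cls) {
  n <- length(uncorrected_cls)
  stopifnot(length(corrected_cls) == n)
  if (n < 3L) stop("anchor regression needs a batch of at least 3")
  xb <- mean(uncorrected_cls)
  sxx <- sum((uncorrected_cls - xb)^2)
  if (sxx <= 0) stop("degenerate batch: uncorrected Centiloids have zero variance")
  s <- sum((uncorrected_cls - xb) * (corrected_cls - mean(corrected_cls))) / sxx
  i <- mean(corrected_cls) - s * xb
  structure(c(Ls = abs(s - 1), Li = abs(i)), slope = s, intercept = i)
}

#' Combined training loss for a batch of pairs
#'
#' `L = mean(Ld) + alpha*mean(Lc) + beta*Ls + gamma*Li`, where Ld and Lc are
#' averaged over the pairs in the batch and Ls/Li are batch-level anchor
#' terms over all corrected/uncorrected Centiloids (both scans of every
#' pair).
#'
#' @param cl_t0,cl_t1 Corrected Centiloids per pair.
#' @param uncorrected_t0,uncorrected_t1 Standard Centiloids per pair.
#' @param interval_years Pair intervals.
#' @param weights A [loss_weights()].
#' @param curve A [fit_natural_history()] curve.
#' @return Scalar loss with attribute `components` = c(Ld, Lc, Ls, Li).
#' @export
total_loss <- function(cl_t0, cl_t1, uncorrected_t0, uncorrected_t1,
                       interval_years, weights, curve) {
  ld <- mean(loss_decrease(cl_t0, cl_t1))
  lc <- mean(loss_curve(cl_t0, cl_t1, interval_years, curve))
  an <- loss_anchor(c(cl_t0, cl_t1), c(uncorrected_t0, uncorrected_t1))
  l <- ld + weights$alpha * lc + weights$beta * an[["Ls"]] + weights$gamma * an[["Li"]]
  structure(l, components = c(Ld = ld, Lc = lc, Ls = an[["Ls"]], Li = an[["Li"]]))
}

# Loss and its gradient with respect to each scan's corrected Centiloid.
# Scan layout: corrected_cl / uncorrected_cl are length-2B vectors; pairs is a
# 2-column index matrix (t0, t1) into them; dt the B intervals.
batch_loss_grad <- function(corrected_cl, uncorrected_cl, pairs, dt, weights, curve) {
  B <- nrow(pairs)
  n <- length(corrected_cl)
  c0 <- corrected_cl[pairs[, 1]]
  c1 <- corrected_cl[pairs[, 2]]
  g <- numeric(n)

  ld <- pmax(0, c0 - c1)
  dec <- ld > 0
  g[pairs[dec, 1]] <- g[pairs[dec, 1]] + 1 / B
  g[pairs[dec, 2]] <- g[pairs[dec, 2]] - 1 / B

  m <- (c0 + c1) / 2
  rate <- (c1 - c0) / dt
  resid <- rate - predict(curve, m)
  sgn <- sign(resid)
  fps <- curve_slope(curve, m)
  g[pairs[, 1]] <- g[pairs[, 1]] + weights$alpha / B * sgn * (-1 / dt - fps / 2)
  g[pairs[, 2]] <- g[pairs[, 2]] + weights$alpha / B * sgn * (1 / dt - fps / 2)

  an <- loss_anchor(corrected_cl, uncorrected_cl)
  s <- attr(an, "slope"); i <- attr(an, "intercept")
  xb <- mean(uncorrected_cl)
  sxx <- sum((uncorrected_cl - xb)^2)
  ds <- (uncorrected_cl - xb) / sxx
  di <- 1 / n - xb * ds
  g <- g + weights$beta * sign(s - 1) * ds + weights$gamma * sign(i) * di

  loss <- mean(ld) + weights$alpha * mean(abs(resid)) +
    weights$beta * an[["Ls"]] + weights$gamma * an[["Li"]]
  list(loss = loss, grad_cl = g,
       components = c(Ld = mean(ld), Lc = mean(abs(resid)),
                      Ls = an[["Ls"]], Li = an[["Li"]]))
}
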