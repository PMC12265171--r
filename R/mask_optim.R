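#' Mask optimisation configuration
#'
#' Settings of the gradient-descent derivation of data-driven reference and
#' target masks. Defaults follow the full-scale procedure: binarity weight
#' `delta = 5e-4` boosted by a factor 100 after 20 epochs, 4 mm FWHM
#' Gaussian smoothing of the masks at every iteration, a 3-level
#' multiresolution schedule (x4, x2, x1 downsampling) with minimum
#' iterations 1000/3000/8000 and a convergence tolerance of 1e-7 on the
#' moving-average Pearson loss. Desk-scale runs typically reduce the
#' minimum iterations.
#'
#' @param delta Binarity-loss weight.
#' @param delta_boost_epoch Epoch (full pass over the scan set) after which
#'   delta is multiplied by `delta_boost_factor`.
#' @param delta_boost_factor Boost factor (default 100).
#' @param smooth_fwhm_mm Mask smoothing kernel FWHM in mm.
#' @param level_factors Downsampling factors of the multiresolution levels.
#' @param min_iters Minimum iterations per level.
#' @param max_iters Hard cap per level.
#' @param convergence_tol Minimum improvement of the windowed Pearson loss.
#' @param window Moving-average window (iterations) for the stopping rule.
#' @param lr Step size: gradient steps are normalised so the largest voxel
#'   update per iteration is `lr`.
#' @param augment_every If > 0, re-draws the random PSF smoothing of the
#'   scan set every this many iterations (0 disables).
#' @param max_fwhm Ceiling on the combined PSF for the augmentation.
#' @export
mask_opt_config <- function(delta = 5e-4, delta_boost_epoch = 20L,
                            delta_boost_factor = 100, smooth_fwhm_mm = 4,
                            level_factors = c(4L, 2L, 1L),
                            min_iters = c(1000L, 3000L, 8000L),
                            max_iters = c(20000L, 20000L, 20000L),
                            convergence_tol = 1e-7, window = 50L,
                            lr = 0.05, augment_every = 0L, max_fwhm = 8) {
  stopifnot(delta > 0, convergence_tol > 0, length(level_factors) == length(min_iters))
  structure(as.list(environment()), class = "mask_opt_config")
}

#' Pearson correlation loss
#'
#' `Lp = 1 - R^2` per tracer between mask-derived SUVRs and the target
#' (corrected) SUVRs, averaged over the tracers present.
#'
#' @param mask_suvrs,target_suvrs Matched numeric vectors.
#' @param tracers Tracer code per scan (`NULL` = a single group).
#' @return Mean `1 - R^2` across tracers.
#' @export
pearson_loss <- function(mask_suvrs, target_suvrs, tracers = NULL) {
  stopifnot(length(mask_suvrs) == length(target_suvrs))
  if (is.null(tracers)) tracers <- rep("all", length(mask_suvrs))
  vals <- vapply(split(seq_along(tracers), tracers), function(ix) {
    if (length(ix) < 3L) stop("pearson_loss needs at least 3 scans per tracer")
    if (stats::sd(mask_suvrs[ix]) == 0 || stats::sd(target_suvrs[ix]) == 0)
      stop("degenerate tracer group: zero variance")
    1 - stats::cor(mask_suvrs[ix], target_suvrs[ix])^2
  }, 0)
  mean(vals)
}

#' Binarity loss
#'
#' `Lb = sum_brain (0.5 - |M - 0.5|) / B`: each voxel contributes 0 when the
#' mask value is exactly 0 or 1 and 0.5 when it is 0.5; the sum over brain
#' voxels is normalised by the number of non-zero brain-mask voxels B.
#'
#' @param mask Continuous mask with values in `[0, 1]`.
#' @param brain_mask Binary brain mask on the same grid.
#' @return Non-negative scalar.
#' @export
binarity_loss <- function(mask, brain_mask) {
  if (any(mask < 0 | mask > 1)) stop("mask values must lie in [0, 1]")
  B <- sum(brain_mask != 0)
  if (B == 0) stop("empty brain mask")
  sum((0.5 - abs(mask - 0.5))[brain_mask != 0]) / B
}

#' Dice overlap coefficient
#'
#' `2|A n B| / (|A| + |B|)` after thresholding both masks at `threshold`.
#'
#' @param mask_a,mask_b Masks on the same grid.
#' @param threshold Binarisation threshold (default 0.5).
#' @return Overlap in `[0, 1]`.
#' @export
dice <- function(mask_a, mask_b, threshold = 0.5) {
  stopifnot(all(dim(mask_a) == dim(mask_b)))
  a <- mask_a >= threshold
  b <- mask_b >= threshold
  if (!any(a) && !any(b)) stop("both masks are empty after thresholding")
  2 * sum(a & b) / (sum(a) + sum(b))
}

# Mirror-symmetrise by averaging with the reflection (exactly symmetric and
# differentiable).
mirror_average <- function(mask, lr_axis) (mask + mirror_volume(mask, lr_axis)) / 2

# SUVRs of all scans for a mask pair, from the scan matrix (n x P).
mask_suvr_matrix <- function(V, m_ref, m_tgt) {
  wt <- sum(m_tgt); wr <- sum(m_ref)
  nt <- as.numeric(V %*% m_tgt) / wt
  nr <- as.numeric(V %*% m_ref) / wr
  list(suvr = nt / nr, nt = nt, nr = nr, wt = wt, wr = wr)
}

# dLp/ds per scan for the per-tracer-averaged 1-R^2 loss.
pearson_grad_s <- function(s, y, tracers) {
  g <- numeric(length(s))
  grp <- split(seq_along(s), tracers)
  for (ix in grp) {
    sg <- s[ix]; yg <- y[ix]
    A <- sum((sg - mean(sg)) * (yg - mean(yg)))
    Bq <- sum((sg - mean(sg))^2)
    Cq <- sum((yg - mean(yg))^2)
    if (Bq <= 0 || Cq <= 0) stop("degenerate tracer group: zero variance")
    r <- A / sqrt(Bq * Cq)
    dr <- ((yg - mean(yg)) - r * sqrt(Bq * Cq) / Bq * (sg - mean(sg))) / sqrt(Bq * Cq)
    g[ix] <- -2 * r * dr / length(grp)
  }
  g
}

#' Optimise data-driven reference and target masks
#'
#' Gradient descent on a continuous reference/target mask pair so that the
#' resulting SUVRs maximise the per-tracer Pearson correlation with the
#' supplied corrected SUVRs, with a binarity penalty pushing the masks
#' toward 0/1. Each iteration applies the gradient step, clamps to
#' `[0, 1]`, smooths with the 4 mm FWHM kernel, restricts to the brain and
#' mirrors to exact left-right symmetry. A 3-level multiresolution schedule
#' (x4, x2, full resolution) is used, with per-level minimum iterations and
#' a moving-average convergence test on the Pearson loss.
#'
#' @param scans List of [scan_record()]s (volumes SUVR-normalised).
#' @param corrected_suvrs Target SUVRs, matched to `scans`.
#' @param init_masks Initial [mask_pair()] (typically the standard masks).
#' @param brain_mask Binary brain mask.
#' @param config A [mask_opt_config()].
#' @param grid The [volume_grid()].
#' @param seed Seed (used by the optional PSF augmentation).
#' @return List: `masks` (continuous [mask_pair()]), `masks_binary`
#'   (thresholded at 0.5), `history` (per-iteration data.frame with level,
#'   Lp, Lb, delta), `final_lp`.
#' @export
optimize_masks <- function(scans, corrected_suvrs, init_masks, brain_mask,
                           config = mask_opt_config(), grid = default_grid(),
                           seed = 0L) {
  stopifnot(length(scans) == length(corrected_suvrs))
  tracers <- vapply(scans, function(s) s$tracer, "")
  if (any(table(tracers) < 3L)) stop("each tracer group needs at least 3 scans")
  lr_axis <- grid$lr_axis
  full_d <- grid$shape
  vols <- lapply(scans, function(s) s$volume)
  y <- corrected_suvrs
  m_ref <- init_masks$reference
  m_tgt <- init_masks$target
  hist <- list()
  epoch_counter <- 0L

  for (lev in seq_along(config$level_factors)) {
    f <- config$level_factors[lev]
    d <- full_d %/% f
    vox_mm <- grid$voxel_size_mm * f
    Vl <- do.call(rbind, lapply(vols, function(v) as.numeric(downsample_mean(v, f))))
    brain_l <- downsample_mean(brain_mask, f)
    brain_l <- array(as.numeric(brain_l > 0.5), d)
    Bl <- sum(brain_l)
    to_level <- function(m) {
      if (lev == 1L) downsample_mean(m, f)
      else if (all(dim(m) == d)) m
      else pmin(pmax(upsample_trilinear(m, d), 0), 1)
    }
    ref <- to_level(m_ref)
    tgt <- to_level(m_tgt)
    sig_vox <- fwhm_to_sigma(config$smooth_fwhm_mm) / vox_mm
    cond <- function(m) mirror_average(array(m, d) * brain_l, lr_axis)
    ref <- cond(gaussian_smooth3d(array(ref, d), sig_vox))
    tgt <- cond(gaussian_smooth3d(array(tgt, d), sig_vox))
    Vl_cur <- Vl
    lp_hist <- numeric(0)
    it <- 0L
    repeat {
      it <- it + 1L
      epoch_counter <- epoch_counter + 1L
      if (config$augment_every > 0L && it %% config$augment_every == 1L) {
        Vl_cur <- with_seed(seed + epoch_counter, {
          do.call(rbind, lapply(seq_along(vols), function(i) {
            as.numeric(downsample_mean(
              psf_augment(vols[[i]], scans[[i]]$psf_fwhm_mm, grid,
                          max_fwhm = config$max_fwhm), f))
          }))
        })
      }
      delta_eff <- if (epoch_counter > config$delta_boost_epoch)
        config$delta * config$delta_boost_factor else config$delta
      st <- mask_suvr_matrix(Vl_cur, as.numeric(ref), as.numeric(tgt))
      lp <- pearson_loss(st$suvr, y, tracers)
      lb_r <- binarity_loss(ref, brain_l)
      lb_t <- binarity_loss(tgt, brain_l)
      hist[[length(hist) + 1L]] <- c(level = lev, iter = it, lp = lp,
                                     lb_ref = lb_r, lb_tgt = lb_t, delta = delta_eff,
                                     mass_ref = sum(ref) / prod(d),
                                     mass_tgt = sum(tgt) / prod(d))
      lp_hist <- c(lp_hist, lp)
      w <- config$window
      if (it >= config$min_iters[lev] && it >= 2L * w) {
        improv <- mean(lp_hist[(it - 2L * w + 1L):(it - w)]) -
          mean(lp_hist[(it - w + 1L):it])
        if (improv < config$convergence_tol) break
      }
      if (it >= config$max_iters[lev]) break

      cs <- pearson_grad_s(st$suvr, y, tracers)
      if (!all(is.finite(cs))) stop("non-finite gradient in mask optimisation")
      a_t <- cs / st$nr
      g_tgt <- (as.numeric(crossprod(Vl_cur, a_t)) - sum(a_t * st$nt)) / st$wt
      a_r <- cs * st$suvr / st$nr
      g_ref <- -(as.numeric(crossprod(Vl_cur, a_r)) - sum(a_r * st$nr)) / st$wr
      bin_g <- function(m) -sign(m - 0.5) / Bl * as.numeric(brain_l)
      g_tgt <- array(g_tgt, d) + delta_eff * bin_g(tgt)
      g_ref <- array(g_ref, d) + delta_eff * bin_g(ref)
      if (it == 1L) {
        # fix the step scale per level from the initial gradient magnitude,
        # so steps shrink with the gradient as the level converges (a step
        # normalised anew each iteration would keep eroding the masks under
        # the binarity term long after the correlation loss has converged)
        step_scale <- config$lr / (mean(abs(c(g_ref, g_tgt))) + 1e-12)
      }
      # per-voxel updates are additionally capped at lr mask units, so a
      # mid-run delta boost tightens binarity gradually instead of slamming
      # every voxel to 0/1 in one iteration
      step <- function(m, g) {
        upd <- pmin(pmax(step_scale * g, -config$lr), config$lr)
        pmin(pmax(m - upd, 0), 1)
      }
      ref <- cond(gaussian_smooth3d(step(ref, g_ref), sig_vox))
      tgt <- cond(gaussian_smooth3d(step(tgt, g_tgt), sig_vox))
      if (sum(ref) <= 0 || sum(tgt) <= 0) stop("a mask collapsed to zero mass")
    }
    m_ref <- ref; m_tgt <- tgt
  }
  if (!all(dim(m_ref) == full_d)) {
    m_ref <- pmin(pmax(upsample_trilinear(m_ref, full_d), 0), 1)
    m_tgt <- pmin(pmax(upsample_trilinear(m_tgt, full_d), 0), 1)
    m_ref <- mirror_average(m_ref * (brain_mask != 0), lr_axis)
    m_tgt <- mirror_average(m_tgt * (brain_mask != 0), lr_axis)
  }
  history <- as.data.frame(do.call(rbind, hist))
  list(masks = mask_pair(reference = m_ref, target = m_tgt),
       masks_binary = mask_pair(
         reference = array(as.numeric(m_ref >= 0.5), full_d),
         target = array(as.numeric(m_tgt >= 0.5), full_d)),
       history = history,
       final_lp = history$lp[nrow(history)])
}

#' Per-tracer recalibration of mask SUVRs
#'
#' Least-squares line per tracer mapping the optimised-mask SUVRs onto the
#' corrected-SUVR scale; composing it with the standard Centiloid transform
#' yields the mask-based corrected Centiloid.
#'
#' @param mask_suvrs,corrected_suvrs Matched vectors (>= 3 scans per tracer).
#' @param tracers Tracer code per scan.
#' @return Object of class `recalibration_line`: tracer -> list(slope,
#'   intercept).
#' @export
recalibrate <- function(mask_suvrs, corrected_suvrs, tracers) {
  stopifnot(length(mask_suvrs) == length(corrected_suvrs),
            length(tracers) == length(mask_suvrs))
  out <- lapply(split(seq_along(tracers), tracers), function(ix) {
    if (length(ix) < 3L) stop("recalibrate needs at least 3 scans per tracer")
    if (stats::sd(mask_suvrs[ix]) == 0) stop("degenerate tracer group: zero variance")
    fit <- stats::lm.fit(cbind(1, mask_suvrs[ix]), corrected_suvrs[ix])
    list(slope = unname(fit$coefficients[2]), intercept = unname(fit$coefficients[1]))
  })
  structure(out, class = "recalibration_line")
}

#' @rdname recalibrate
#' @param lines A `recalibration_line` table.
#' @param suvr Mask SUVR values.
#' @export
apply_recalibration <- function(lines, suvr, tracers) {
  vapply(seq_along(suvr), function(i) {
    l <- lines[[tracers[i]]]
    if (is.null(l)) stop(sprintf("no recalibration line for tracer '%s'", tracers[i]))
    l$slope * suvr[i] + l$intercept
  }, 0)
}
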