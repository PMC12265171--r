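# Training-time augmentation: small random rotations (<= 5 degrees), a coarse
# non-rigid deformation (white displacement noise smoothed with a Gaussian of
# sigma 20 full-scale voxels, scaled by magnitude 50), and random Gaussian
# smoothing whose added FWHM is drawn so the combined PSF never exceeds 8 mm
# (quadrature: added_max = sqrt(8^2 - psf^2)).

# Resample a volume at displaced coordinates (trilinear, zero outside).
resample_at <- function(volume, xc, yc, zc) {
  d <- dim(volume)
  x0 <- floor(xc); y0 <- floor(yc); z0 <- floor(zc)
  fx <- xc - x0; fy <- yc - y0; fz <- zc - z0
  val <- numeric(length(xc))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    ix <- x0 + dx; iy <- y0 + dy; iz <- z0 + dz
    wt <- (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy) * (if (dz) fz else 1 - fz)
    ok <- ix >= 1 & ix <= d[1] & iy >= 1 & iy <= d[2] & iz >= 1 & iz <= d[3] & wt > 0
    if (any(ok))
      val[ok] <- val[ok] + wt[ok] * volume[cbind(ix[ok], iy[ok], iz[ok])]
  }
  array(val, d)
}

rotation_matrix3 <- function(ax, ay, az) {
  rx <- matrix(c(1, 0, 0, 0, cos(ax), sin(ax), 0, -sin(ax), cos(ax)), 3, 3)
  ry <- matrix(c(cos(ay), 0, -sin(ay), 0, 1, 0, sin(ay), 0, cos(ay)), 3, 3)
  rz <- matrix(c(cos(az), sin(az), 0, -sin(az), cos(az), 0, 0, 0, 1), 3, 3)
  rz %*% ry %*% rx
}

#' Augment a volume for training
#'
#' Applies, in order: a random rotation of at most `max_rotation_deg` about
#' the volume centre, a smooth random non-rigid deformation (displacement
#' noise smoothed with a Gaussian of `deform_sigma` voxels at full 2 mm
#' scale, scaled by `deform_magnitude`), and Gaussian smoothing with an added
#' FWHM drawn uniformly in `[0, sqrt(max_fwhm^2 - psf^2)]` so the effective
#' PSF never exceeds `max_fwhm` (8 mm). Deterministic under a fixed RNG
#' state.
#'
#' @param volume 3D array.
#' @param scanner_psf_fwhm Scanner PSF FWHM in mm (must be <= `max_fwhm`).
#' @param grid The [volume_grid()] (for mm-to-voxel conversion).
#' @param max_rotation_deg Maximum rotation per axis, degrees.
#' @param deform_sigma,deform_magnitude Non-rigid deformation parameters in
#'   full-scale (2 mm) voxel units; rescaled proportionally to the grid.
#' @param max_fwhm Ceiling on the combined PSF FWHM in mm.
#' @return Augmented volume.
#' @export
augment <- function(volume, scanner_psf_fwhm, grid,
                    max_rotation_deg = 5, deform_sigma = 20,
                    deform_magnitude = 50, max_fwhm = 8) {
  if (scanner_psf_fwhm > max_fwhm)
    stop(sprintf("scanner PSF %.1f mm exceeds the %.1f mm ceiling", scanner_psf_fwhm, max_fwhm))
  d <- dim(volume)
  scale <- 2 / grid$voxel_size_mm  # full-scale voxels -> this grid's voxels

  ang <- stats::runif(3, -max_rotation_deg, max_rotation_deg) * pi / 180
  R <- rotation_matrix3(ang[1], ang[2], ang[3])
  ctr <- (d + 1) / 2
  cc <- as.matrix(expand.grid(x = seq_len(d[1]), y = seq_len(d[2]), z = seq_len(d[3])))
  src <- sweep(sweep(cc, 2, ctr) %*% t(R), 2, ctr, `+`)

  sig <- deform_sigma * scale
  mag <- deform_magnitude * scale
  for (ax in 1:3) {
    field <- gaussian_smooth3d(array(stats::runif(prod(d), -1, 1), d), sig)
    src[, ax] <- src[, ax] + mag * as.numeric(field)
  }
  out <- resample_at(volume, src[, 1], src[, 2], src[, 3])

  add_max <- sqrt(max(0, max_fwhm^2 - scanner_psf_fwhm^2))
  add <- stats::runif(1, 0, add_max)
  if (add > 0)
    out <- gaussian_smooth3d(out, fwhm_to_sigma(add) / grid$voxel_size_mm)
  out
}

# The PSF-smoothing component alone (used by mask optimisation).
psf_augment <- function(volume, scanner_psf_fwhm, grid, max_fwhm = 8) {
  add_max <- sqrt(max(0, max_fwhm^2 - scanner_psf_fwhm^2))
  add <- stats::runif(1, 0, add_max)
  if (add > 0) gaussian_smooth3d(volume, fwhm_to_sigma(add) / grid$voxel_size_mm)
  else volume
}
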