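#' Amyloid-PET tracer codes
#'
#' The five tracers supported throughout the package: \code{PIB} (11C-PiB),
#' \code{NAV} (18F-NAV4694), \code{FBB} (18F-florbetaben), \code{FBP}
#' (18F-florbetapir) and \code{FMM} (18F-flutemetamol). Tracer identity is
#' encoded as a one-hot vector of length 5 inside the correction network.
#'
#' @export
TRACERS <- c("PIB", "NAV", "FBB", "FBP", "FMM")

#' Template-space voxel grid
#'
#' Describes the isotropic voxel grid every volume, mask and network in the
#' package lives on. The default desk-scale grid is 32 x 40 x 32 voxels at
#' 4 mm; the full-resolution template grid (91 x 109 x 91 at 2 mm) is
#' available through [full_grid()].
#'
#' @param shape Integer vector of length 3, voxels per axis (each >= 4).
#' @param voxel_size_mm Positive isotropic voxel size in millimetres.
#' @param lr_axis Axis index (1..3) used for left-right mirroring of masks.
#' @return An object of class `volume_grid`.
#' @examples
#' g <- volume_grid(c(32, 40, 32), 4)
#' g$shape
#' @export
volume_grid <- function(shape = c(32L, 40L, 32L), voxel_size_mm = 4, lr_axis = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 4L))
    stop("grid shape must be three integers, each >= 4")
  if (!is.numeric(voxel_size_mm) || length(voxel_size_mm) != 1L || voxel_size_mm <= 0)
    stop("voxel_size_mm must be a single positive number")
  lr_axis <- as.integer(lr_axis)
  if (!lr_axis %in% 1:3) stop("lr_axis must be 1, 2 or 3")
  structure(list(shape = shape, voxel_size_mm = voxel_size_mm, lr_axis = lr_axis),
            class = "volume_grid")
}

#' @rdname volume_grid
#' @export
default_grid <- function() volume_grid(c(32L, 40L, 32L), 4)

#' @rdname volume_grid
#' @export
full_grid <- function() volume_grid(c(91L, 109L, 91L), 2)

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid> %d x %d x %d voxels @ %g mm isotropic (mirror axis %d)\n",
              x$shape[1], x$shape[2], x$shape[3], x$voxel_size_mm, x$lr_axis))
  invisible(x)
}

# Check that a 3D array matches the grid; error states both shapes.
check_grid <- function(volume, grid) {
  d <- dim(volume)
  if (is.null(d) || length(d) != 3L)
    stop("volume must be a 3D array")
  if (!is.null(grid) && !all(d == grid$shape))
    stop(sprintf("volume shape %s does not match grid %s",
                 paste(d, collapse = "x"), paste(grid$shape, collapse = "x")))
  invisible(TRUE)
}

# Reflect a volume along the grid's left-right axis.
mirror_volume <- function(volume, lr_axis = 1L) {
  d <- dim(volume)
  idx <- rep(list(quote(expr = )), 3L)
  idx[[lr_axis]] <- d[lr_axis]:1
  do.call(`[`, c(list(volume), idx, list(drop = FALSE)))
}

# Evaluate code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# FWHM (mm) <-> Gaussian sigma
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# Separable 3D Gaussian smoothing with edge renormalisation. sigma in voxels.
gaussian_smooth3d <- function(volume, sigma_vox) {
  if (sigma_vox <= 0) return(volume)
  d <- dim(volume)
  smooth_axis <- function(v, axis) {
    n <- d[axis]
    r <- max(1L, ceiling(3 * sigma_vox))
    off <- (-r):r
    k <- exp(-off^2 / (2 * sigma_vox^2))
    K <- matrix(0, n, n)
    for (j in seq_along(off)) {
      i <- seq_len(n) + off[j]
      ok <- i >= 1L & i <= n
      K[cbind(which(ok), i[ok])] <- K[cbind(which(ok), i[ok])] + k[j]
    }
    K <- K / rowSums(K)  # renormalise at the edges
    if (axis == 1L) {
      array(K %*% matrix(v, d[1], d[2] * d[3]), d)
    } else if (axis == 2L) {
      m <- aperm(v, c(2, 1, 3))
      m <- array(K %*% matrix(m, d[2], d[1] * d[3]), c(d[2], d[1], d[3]))
      aperm(m, c(2, 1, 3))
    } else {
      m <- aperm(v, c(3, 1, 2))
      m <- array(K %*% matrix(m, d[3], d[1] * d[2]), c(d[3], d[1], d[2]))
      aperm(m, c(2, 3, 1))
    }
  }
  v <- smooth_axis(volume, 1L)
  v <- smooth_axis(v, 2L)
  smooth_axis(v, 3L)
}

# Mean-pool downsampling by an integer factor (dims must be divisible).
downsample_mean <- function(volume, factor) {
  if (factor == 1L) return(volume)
  d <- dim(volume)
  if (any(d %% factor != 0))
    stop(sprintf("dims %s not divisible by %d", paste(d, collapse = "x"), factor))
  dn <- d %/% factor
  a <- array(volume, c(factor, dn[1], factor, dn[2], factor, dn[3]))
  apply(a, c(2, 4, 6), mean)
}

# Trilinear upsampling back onto a target shape.
upsample_trilinear <- function(volume, target_shape) {
  d <- dim(volume)
  coords <- lapply(1:3, function(ax) {
    # map target voxel centres onto source voxel-centre coordinates
    (seq_len(target_shape[ax]) - 0.5) * d[ax] / target_shape[ax] + 0.5
  })
  interp3 <- function(x, y, z) {
    x0 <- pmin(pmax(floor(x), 1L), d[1]); x1 <- pmin(x0 + 1L, d[1]); fx <- pmin(pmax(x - x0, 0), 1)
    y0 <- pmin(pmax(floor(y), 1L), d[2]); y1 <- pmin(y0 + 1L, d[2]); fy <- pmin(pmax(y - y0, 0), 1)
    z0 <- pmin(pmax(floor(z), 1L), d[3]); z1 <- pmin(z0 + 1L, d[3]); fz <- pmin(pmax(z - z0, 0), 1)
    g <- function(ix, iy, iz) volume[cbind(ix, iy, iz)]
    (g(x0, y0, z0) * (1 - fx) + g(x1, y0, z0) * fx) * (1 - fy) * (1 - fz) +
    (g(x0, y1, z0) * (1 - fx) + g(x1, y1, z0) * fx) * fy * (1 - fz) +
    (g(x0, y0, z1) * (1 - fx) + g(x1, y0, z1) * fx) * (1 - fy) * fz +
    (g(x0, y1, z1) * (1 - fx) + g(x1, y1, z1) * fx) * fy * fz
  }
  cc <- expand.grid(x = coords[[1]], y = coords[[2]], z = coords[[3]])
  array(interp3(cc$x, cc$y, cc$z), target_shape)
}
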