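#' Construct a scan record
#'
#' A scan record holds one spatially normalised PET volume in template space
#' together with its participant, acquisition date, tracer and scanner
#' point-spread-function metadata.
#'
#' @param participant_id Opaque participant identifier.
#' @param date Acquisition date (`Date` or ISO-8601 string).
#' @param tracer One of [TRACERS].
#' @param psf_fwhm_mm Scanner PSF FWHM in mm, in `[0, 8]`.
#' @param volume 3D non-negative intensity array (or `NULL` if not loaded).
#' @param path Optional source path of the volume.
#' @param is_suvr_normalised Whether `volume` is already divided by the
#'   whole-cerebellum (reference) uptake.
#' @return An object of class `scan_record`.
#' @export
scan_record <- function(participant_id, date, tracer, psf_fwhm_mm,
                        volume = NULL, path = NULL, is_suvr_normalised = FALSE) {
  date <- as.Date(date)
  if (is.na(date)) stop("acquisition date must parse as ISO-8601")
  if (!tracer %in% TRACERS)
    stop(sprintf("unknown tracer '%s' (expected one of %s)",
                 tracer, paste(TRACERS, collapse = ", ")))
  if (!is.numeric(psf_fwhm_mm) || psf_fwhm_mm < 0 || psf_fwhm_mm > 8)
    stop("scanner psf_fwhm_mm must be in [0, 8]")
  if (!is.null(volume)) {
    if (!all(is.finite(volume))) stop("volume values must be finite")
    if (any(volume < 0)) stop("volume values must be non-negative")
  }
  structure(list(participant_id = as.character(participant_id), date = date,
                 tracer = tracer, psf_fwhm_mm = psf_fwhm_mm, volume = volume,
                 path = path, is_suvr_normalised = is_suvr_normalised),
            class = "scan_record")
}

#' @export
print.scan_record <- function(x, ...) {
  cat(sprintf("<scan_record> %s %s %s psf=%gmm %s\n", x$participant_id,
              format(x$date), x$tracer, x$psf_fwhm_mm,
              if (is.null(x$volume)) "(volume not loaded)" else
                paste(dim(x$volume), collapse = "x")))
  invisible(x)
}

#' Read a cohort manifest
#'
#' Parses a CSV manifest with header columns `participant_id`, `date`,
#' `tracer`, `psf_fwhm_mm`, `volume_path` into a list of [scan_record()]s
#' sorted by participant then date. Rows with unknown tracer codes, missing
#' volume files or duplicate (participant, date) entries raise errors.
#'
#' @param path Path to the CSV manifest.
#' @param grid Optional [volume_grid()] the volumes must match.
#' @param load_volumes Whether to load the NIfTI volumes into memory.
#' @return List of `scan_record` objects, possibly empty.
#' @export
read_manifest <- function(path, grid = NULL, load_volumes = TRUE) {
  if (!file.exists(path)) stop(sprintf("manifest not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  req <- c("participant_id", "date", "tracer", "psf_fwhm_mm", "volume_path")
  if (!all(req %in% names(df)))
    stop(sprintf("manifest must have columns %s", paste(req, collapse = ", ")))
  if (nrow(df) == 0L) return(list())
  bad <- which(!df$tracer %in% TRACERS)
  if (length(bad))
    stop(sprintf("unknown tracer '%s' in manifest row %d", df$tracer[bad[1]], bad[1]))
  dates <- as.Date(df$date)
  if (anyNA(dates)) stop(sprintf("unparseable date in manifest row %d", which(is.na(dates))[1]))
  key <- paste(df$participant_id, format(dates))
  if (anyDuplicated(key))
    stop(sprintf("duplicate acquisition date for participant %s on %s",
                 df$participant_id[which(duplicated(key))[1]],
                 format(dates[which(duplicated(key))[1]])))
  base_dir <- dirname(path)
  scans <- lapply(seq_len(nrow(df)), function(i) {
    vp <- df$volume_path[i]
    if (!file.exists(vp) && file.exists(file.path(base_dir, vp)))
      vp <- file.path(base_dir, vp)
    vol <- NULL
    if (load_volumes) {
      if (!file.exists(vp)) stop(sprintf("volume file not found: %s", df$volume_path[i]))
      vol <- load_volume(vp, grid = grid)
    }
    scan_record(df$participant_id[i], dates[i], df$tracer[i],
                as.numeric(df$psf_fwhm_mm[i]), volume = vol, path = vp)
  })
  ord <- order(vapply(scans, function(s) s$participant_id, ""),
               vapply(scans, function(s) as.numeric(s$date), 0))
  scans[ord]
}

#' Load / save a template-space volume
#'
#' NIfTI-1 I/O for volumes and masks. `load_volume` errors if the on-disk
#' shape does not match the configured grid; `save_volume` records the grid's
#' voxel size in the header.
#'
#' @param path File path (`.nii` or `.nii.gz`).
#' @param grid Optional [volume_grid()] to validate/stamp.
#' @return `load_volume`: a 3D array. `save_volume`: the path, invisibly.
#' @export
load_volume <- function(path, grid = NULL) {
  img <- RNifti::readNifti(path)
  vol <- array(as.numeric(img), dim = dim(img)[1:3])
  check_grid(vol, grid)
  vol
}

#' @rdname load_volume
#' @param volume 3D array to write.
#' @export
save_volume <- function(volume, path, grid = NULL) {
  check_grid(volume, grid)
  pix <- if (is.null(grid)) c(1, 1, 1) else rep(grid$voxel_size_mm, 3)
  img <- RNifti::asNifti(volume, pixdim = pix)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' SUVR-normalise a volume
#'
#' Divides the image intensity by the mean uptake over the whole-cerebellum
#' (reference) mask, so the reference-weighted mean of the result is 1. This
#' is the input convention of the correction network.
#'
#' @param volume 3D intensity array.
#' @param whole_cerebellum_mask Mask (binary or continuous weights in
#'   `[0, 1]`) on the same grid.
#' @return Normalised volume.
#' @export
suvr_normalise <- function(volume, whole_cerebellum_mask) {
  if (!all(dim(volume) == dim(whole_cerebellum_mask)))
    stop("volume and mask must share a grid")
  w <- sum(whole_cerebellum_mask)
  if (w <= 0) stop("reference mask has zero mass")
  m <- sum(volume * whole_cerebellum_mask) / w
  if (!is.finite(m) || m <= 0) stop("reference-region mean must be positive")
  volume / m
}
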