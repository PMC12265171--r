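#' Reference/target mask pair
#'
#' Holds the continuous-valued reference and target masks used for SUVR
#' computation. Continuous weights in `[0, 1]` are first-class because mask
#' optimisation produces near-binary masks before thresholding.
#'
#' @param reference,target 3D arrays with values in `[0, 1]` and positive mass.
#' @return Object of class `mask_pair`.
#' @export
mask_pair <- function(reference, target) {
  if (!all(dim(reference) == dim(target))) stop("masks must share a grid")
  for (m in list(reference, target)) {
    if (any(m < 0 | m > 1)) stop("mask values must lie in [0, 1]")
    if (sum(m) <= 0) stop("mask must have positive mass")
  }
  structure(list(reference = reference, target = target), class = "mask_pair")
}

#' Compute an SUVR from continuous masks
#'
#' The Standardised Uptake Value Ratio: target-weighted mean uptake divided
#' by reference-weighted mean uptake,
#' \deqn{SUVR = \frac{\sum M_t V / \sum M_t}{\sum M_r V / \sum M_r}.}
#'
#' @param volume 3D non-negative intensity array.
#' @param masks A [mask_pair()].
#' @return Positive scalar SUVR.
#' @examples
#' v <- array(1, c(4, 4, 4)); v[1, , ] <- 2
#' tgt <- array(0, c(4, 4, 4)); tgt[1, , ] <- 1
#' ref <- array(0, c(4, 4, 4)); ref[4, , ] <- 1
#' compute_suvr(v, mask_pair(ref, tgt))  # 2
#' @export
compute_suvr <- function(volume, masks) {
  if (!inherits(masks, "mask_pair")) masks <- mask_pair(masks$reference, masks$target)
  if (!all(dim(volume) == dim(masks$target))) stop("volume and masks must share a grid")
  tm <- sum(masks$target * volume) / sum(masks$target)
  rw <- sum(masks$reference)
  if (rw <= 0) stop("reference mask has zero mass")
  rm_ <- sum(masks$reference * volume) / rw
  if (!is.finite(rm_) || rm_ <= 0) stop("reference-weighted mean must be positive")
  tm / rm_
}

#' Per-tracer SUVR to Centiloid transforms
#'
#' The Centiloid scale maps each tracer's SUVR linearly so that a young
#' control population averages 0 CL and a typical-AD population 100 CL.
#' `centiloid_transforms` builds the table from named slope/intercept pairs;
#' [read_transforms()]/[write_transforms()] exchange it as JSON.
#'
#' @param table Named list: tracer -> list(slope, intercept), slope != 0.
#' @return Object of class `centiloid_transforms`.
#' @export
centiloid_transforms <- function(table) {
  if (is.null(names(table)) || anyDuplicated(names(table)))
    stop("exactly one transform per tracer is required")
  for (tr in names(table)) {
    if (!tr %in% TRACERS) stop(sprintf("unknown tracer '%s' in transform table", tr))
    if (!is.finite(table[[tr]]$slope) || table[[tr]]$slope == 0)
      stop(sprintf("transform slope for %s must be non-zero", tr))
  }
  structure(lapply(table, function(t) list(slope = t$slope, intercept = t$intercept)),
            class = "centiloid_transforms")
}

#' @rdname centiloid_transforms
#' @param path JSON file path.
#' @export
read_transforms <- function(path) {
  centiloid_transforms(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' @rdname centiloid_transforms
#' @param transforms A `centiloid_transforms` table.
#' @export
write_transforms <- function(transforms, path) {
  jsonlite::write_json(unclass(transforms), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

get_transform <- function(transforms, tracer) {
  t <- transforms[[tracer]]
  if (is.null(t)) stop(sprintf("no Centiloid transform for tracer '%s'", tracer))
  t
}

#' Convert between SUVR and Centiloid
#'
#' `CL = slope * SUVR + intercept` per tracer; the two functions are exact
#' inverses.
#'
#' @param suvr,cl Numeric vectors.
#' @param tracer Tracer code(s), length 1 or matching the values.
#' @param transforms A [centiloid_transforms()] table.
#' @export
suvr_to_centiloid <- function(suvr, tracer, transforms) {
  if (length(tracer) == 1L) {
    t <- get_transform(transforms, tracer)
    return(t$slope * suvr + t$intercept)
  }
  stopifnot(length(tracer) == length(suvr))
  vapply(seq_along(suvr), function(i) {
    t <- get_transform(transforms, tracer[i]); t$slope * suvr[i] + t$intercept
  }, 0)
}

#' @rdname suvr_to_centiloid
#' @export
centiloid_to_suvr <- function(cl, tracer, transforms) {
  if (length(tracer) == 1L) {
    t <- get_transform(transforms, tracer)
    return((cl - t$intercept) / t$slope)
  }
  stopifnot(length(tracer) == length(cl))
  vapply(seq_along(cl), function(i) {
    t <- get_transform(transforms, tracer[i]); (cl[i] - t$intercept) / t$slope
  }, 0)
}

#' Apply a correction factor to a standard SUVR
#'
#' The corrected SUVR is `cf * suvr` with the correction factor constrained
#' to `[0, 2]` by the network architecture; values outside that range signal
#' a contract violation upstream and are rejected.
#'
#' @param suvr Non-negative standard SUVR(s).
#' @param cf Correction factor(s) in `[0, 2]`.
#' @return Corrected SUVR(s).
#' @export
apply_correction <- function(suvr, cf) {
  if (any(cf < 0 | cf > 2)) stop("correction factor must lie in [0, 2]")
  cf * suvr
}

#' Quantify a set of scans with fixed masks
#'
#' Standard quantification: SUVR from the mask pair, Centiloid from the
#' per-tracer transforms.
#'
#' @param scans List of [scan_record()]s with volumes loaded.
#' @param masks A [mask_pair()].
#' @param transforms A [centiloid_transforms()] table.
#' @return data.frame with participant_id, date, tracer, psf_fwhm_mm, suvr, cl.
#' @export
quantify_scans <- function(scans, masks, transforms) {
  suvr <- vapply(scans, function(s) compute_suvr(s$volume, masks), 0)
  tr <- vapply(scans, function(s) s$tracer, "")
  data.frame(
    participant_id = vapply(scans, function(s) s$participant_id, ""),
    date = as.Date(vapply(scans, function(s) format(s$date), "")),
    tracer = tr,
    psf_fwhm_mm = vapply(scans, function(s) s$psf_fwhm_mm, 0),
    suvr = suvr,
    cl = suvr_to_centiloid(suvr, tr, transforms),
    stringsAsFactors = FALSE)
}
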