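#' Configuration of the synthetic phantom cohort
#'
#' Defines the study conditions the generator emulates: sigmoid natural
#' history trajectories of amyloid accumulation, up to five tracers with
#' tracer-specific multiplicative reference-region bias, per-scan scanner PSF
#' blurring (<= 8 mm FWHM), a per-scan multiplicative reference-region
#' fluctuation (scanner/scatter variability), additive voxel noise, and
#' whole-cerebellum-analogue intensity normalisation.
#'
#' @param n_participants Number of participants.
#' @param tracers Named sampling weights over [TRACERS] (per participant).
#' @param n_visits Visits per participant.
#' @param interval_years Range of inter-visit intervals (uniform), years.
#' @param negative_fraction Fraction of non-accumulators.
#' @param sigmoid List: `cl_max`, `onset_age_mean`, `onset_age_sd` (years),
#'   `slope_years` (logistic time scale; peak rate = cl_max/(4*slope_years)).
#' @param baseline_age_mean,baseline_age_sd Baseline age distribution.
#' @param spec_amp Specific-binding amplitude: target uptake is
#'   `1 + spec_amp * true_cl/cl_max`, so SUVR spans about `[1, 2]`.
#' @param tracer_ref_bias Named multiplicative factors on reference-region
#'   uptake per tracer (1 = unbiased).
#' @param ref_scale_sd Log-sd of the per-scan multiplicative reference
#'   fluctuation (scanner/scatter variability; 0 disables).
#' @param noise_sd Additive voxel noise as a fraction of the reference mean.
#' @param psf_range_mm Scanner PSF FWHM range (one scanner, hence one value,
#'   per participant), within [0, 8].
#' @param target_heterogeneous If `TRUE`, the inferior portion of the target
#'   shell accumulates late (burden `(cl/cl_max)^2 * cl_max` instead of
#'   `cl`), giving target voxels distinguishable time courses. Off by
#'   default; required for the hidden-mask recovery oracle, where mask
#'   identifiability needs regional heterogeneity.
#' @param wm_jitter_sd Log-sd of an additional per-scan fluctuation of the
#'   white-matter reference component only (0 disables). Emulates
#'   white-matter-specific nonspecific-binding variability and makes the
#'   grey/white reference split identifiable.
#' @param grid The [volume_grid()] scans are rendered on.
#' @param seed Integer seed; identical configs generate bit-identical cohorts.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_participants = 100L,
                       tracers = c(PIB = 0.7, FBP = 0.3),
                       n_visits = 2L,
                       interval_years = c(1.0, 3.2),
                       negative_fraction = 0.35,
                       sigmoid = list(cl_max = 100, onset_age_mean = 72,
                                      onset_age_sd = 8, slope_years = 3),
                       baseline_age_mean = 73, baseline_age_sd = 7,
                       spec_amp = 1,
                       tracer_ref_bias = c(PIB = 1, NAV = 1, FBB = 1, FBP = 1, FMM = 1),
                       ref_scale_sd = 0.02,
                       noise_sd = 0.05,
                       psf_range_mm = c(4, 7),
                       target_heterogeneous = FALSE,
                       wm_jitter_sd = 0,
                       grid = default_grid(),
                       seed = 0L) {
  stopifnot(n_participants >= 1, sigmoid$cl_max > 0,
            negative_fraction >= 0, negative_fraction <= 1,
            all(psf_range_mm >= 0), all(psf_range_mm <= 8),
            all(tracer_ref_bias > 0), all(names(tracers) %in% TRACERS))
  structure(as.list(environment()), class = "sim_config")
}

#' Geometric phantom layout
#'
#' Concentric-shell stand-in for the template-space anatomy: an ellipsoidal
#' brain, a cortical-shell target, and two equal-size inferior spheres
#' playing the roles of cerebellar grey matter and subcortical white matter
#' (their union is the whole-cerebellum-analogue reference). All regions are
#' disjoint, inside the brain, and mirror-symmetric about the grid's
#' left-right axis.
#'
#' @param grid A [volume_grid()].
#' @return Object of class `phantom_layout` with binary arrays `brain`,
#'   `target`, `reference_gm`, `reference_wm` and the derived standard
#'   [mask_pair()] in `$standard_masks`.
#' @export
phantom_layout <- function(grid = default_grid()) {
  d <- grid$shape
  ctr <- (d + 1) / 2
  cc <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]), z = seq_len(d[3]))
  rel <- function(semi, centre = ctr) {
    sqrt(((cc$x - centre[1]) / semi[1])^2 + ((cc$y - centre[2]) / semi[2])^2 +
           ((cc$z - centre[3]) / semi[3])^2)
  }
  sc <- d / c(32, 40, 32)  # proportional scaling for non-default grids
  brain_r <- rel(c(14, 18, 14) * sc)
  brain <- array(as.numeric(brain_r <= 1), d)
  shell <- brain_r >= 0.72 & brain_r <= 1 & cc$z >= ctr[3] - 3.5 * sc[3]
  target <- array(as.numeric(shell), d)
  sph <- function(centre, r) array(as.numeric(rel(rep(r, 3), centre) <= 1), d)
  zref <- ctr[3] - 8 * sc[3]
  gm <- sph(c(ctr[1], ctr[2] - 6.5 * sc[2], zref), 5.5 * min(sc))
  wm <- sph(c(ctr[1], ctr[2] + 6.5 * sc[2], zref), 5.5 * min(sc))
  # restrict to brain and keep away from the target shell; the gm/wm
  # centres are mirror placements in y, so the two counts stay equal
  gm <- gm * (1 - target) * brain
  wm <- wm * (1 - target) * brain
  # early/late split of the target shell (used when the generator renders a
  # heterogeneous target, and as the hidden target of the recovery oracle)
  early <- target * array(as.numeric(cc$z >= ctr[3] + 0.1 * d[3]), d)
  structure(list(grid = grid, brain = brain, target = target,
                 target_early = early, target_slow = target - early,
                 reference_gm = gm, reference_wm = wm,
                 standard_masks = mask_pair(reference = gm + wm, target = target)),
            class = "phantom_layout")
}

#' @export
print.phantom_layout <- function(x, ...) {
  cat(sprintf("<phantom_layout> brain %d vox; target %d; reference gm/wm %d/%d\n",
              sum(x$brain), sum(x$target), sum(x$reference_gm), sum(x$reference_wm)))
  invisible(x)
}

#' Hidden quantification masks for the mask-recovery oracle
#'
#' An alternative mask pair, distinct from the standard phantom masks: a
#' superior sub-shell of the target and the grey-matter reference sphere
#' alone. SUVRs computed with these masks serve as the ground truth of the
#' mask-optimisation recovery experiment. Both masks are mirror-symmetric.
#'
#' @param layout A [phantom_layout()].
#' @return A [mask_pair()].
#' @export
hidden_mask_pair <- function(layout) {
  mask_pair(reference = layout$reference_gm, target = layout$target_early)
}

true_sigmoid_cl <- function(age, onset, cl_max, slope_years) {
  cl_max / (1 + exp(-(age - onset) / slope_years))
}

#' Simulate true amyloid trajectories
#'
#' Accumulators follow the logistic natural-history curve
#' `CL(t) = cl_max / (1 + exp(-(t - t_onset)/slope_years))`; non-accumulators
#' hold a small constant baseline. Every trajectory is non-decreasing in true
#' Centiloid.
#'
#' @param config A [sim_config()].
#' @return data.frame: participant_id, visit, age_years, years_from_baseline,
#'   true_cl, accumulator, tracer, psf_fwhm_mm, ref_jitter.
#' @export
simulate_trajectories <- function(config) {
  with_seed(config$seed, {
    n <- config$n_participants
    sg <- config$sigmoid
    tr_codes <- names(config$tracers)
    out <- vector("list", n)
    for (i in seq_len(n)) {
      acc <- stats::runif(1) >= config$negative_fraction
      onset <- stats::rnorm(1, sg$onset_age_mean, sg$onset_age_sd)
      age0 <- stats::rnorm(1, config$baseline_age_mean, config$baseline_age_sd)
      gaps <- stats::runif(config$n_visits - 1L, config$interval_years[1],
                           config$interval_years[2])
      t_rel <- cumsum(c(0, gaps))
      ages <- age0 + t_rel
      cl <- if (acc) true_sigmoid_cl(ages, onset, sg$cl_max, sg$slope_years)
            else rep(abs(stats::rnorm(1, 0, 2)), length(ages))
      tracer <- sample(tr_codes, 1L, prob = config$tracers)
      # one scanner (hence one PSF) per participant, as in longitudinal
      # follow-up on a single site
      psf <- rep(stats::runif(1, config$psf_range_mm[1], config$psf_range_mm[2]),
                 length(ages))
      jit <- if (config$ref_scale_sd > 0)
        exp(stats::rnorm(length(ages), 0, config$ref_scale_sd)) else rep(1, length(ages))
      out[[i]] <- data.frame(
        participant_id = sprintf("P%04d", i), visit = seq_along(ages),
        age_years = ages, years_from_baseline = t_rel, true_cl = cl,
        accumulator = acc, tracer = tracer, psf_fwhm_mm = psf,
        ref_jitter = jit, stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
}

#' Render one phantom scan
#'
#' Paints the phantom regions (target `1 + spec_amp*true_cl/cl_max`,
#' reference grey/white at 0.8/1.2 scaled by the tracer's reference bias and
#' the per-scan reference jitter, non-specific brain background 0.9), blurs
#' at the scanner PSF, adds voxel noise, and SUVR-normalises by the whole
#' reference mean. A tracer whose reference is inflated by `k` therefore has
#' its standard SUVR deflated by about `k`.
#'
#' @param true_cl True burden in CL units.
#' @param tracer Tracer code.
#' @param layout A [phantom_layout()].
#' @param config A [sim_config()].
#' @param psf_fwhm_mm Scanner PSF for this scan.
#' @param ref_jitter Per-scan multiplicative reference fluctuation.
#' @param noise Whether to add voxel noise.
#' @return SUVR-normalised 3D volume.
#' @export
render_scan <- function(true_cl, tracer, layout, config,
                        psf_fwhm_mm = mean(config$psf_range_mm),
                        ref_jitter = 1, noise = TRUE) {
  bias <- config$tracer_ref_bias[[tracer]]
  if (is.null(bias)) bias <- 1
  b <- bias * ref_jitter
  cl_max <- config$sigmoid$cl_max
  vol <- 0.9 * layout$brain
  vol[layout$target > 0] <- 1 + config$spec_amp * true_cl / cl_max
  if (isTRUE(config$target_heterogeneous)) {
    # the inferior shell accumulates late (quadratic kinetics), so its time
    # course is non-affinely coupled to the primary region's
    vol[layout$target_slow > 0] <- 1 + 0.6 * config$spec_amp * (true_cl / cl_max)^2
  }
  wj <- if (noise && config$wm_jitter_sd > 0)
    exp(stats::rnorm(1, 0, config$wm_jitter_sd)) else 1
  vol[layout$reference_gm > 0] <- 0.8 * b
  vol[layout$reference_wm > 0] <- 1.2 * b * wj
  if (psf_fwhm_mm > 0)
    vol <- gaussian_smooth3d(vol, fwhm_to_sigma(psf_fwhm_mm) / layout$grid$voxel_size_mm)
  if (noise && config$noise_sd > 0) {
    vol <- vol + stats::rnorm(length(vol), 0, config$noise_sd * b)
    vol <- pmax(vol, 0)
  }
  suvr_normalise(array(vol, layout$grid$shape),
                 layout$standard_masks$reference)
}

#' Calibrate per-tracer Centiloid transforms from anchor renderings
#'
#' Renders noiseless, bias-free anchor scans per tracer (true CL 0 for the
#' young-control anchor, `cl_max` for the typical-AD anchor) at the mid-range
#' PSF, and fits the linear map sending their standard SUVRs to 0 and 100
#' CL. This mirrors the calibration-study convention: the transforms are
#' established under calibration conditions, so a site- or scanner-specific
#' reference bias in a cohort is *not* absorbed by them.
#'
#' @param layout A [phantom_layout()].
#' @param config A [sim_config()].
#' @return A [centiloid_transforms()] table covering the config's tracers.
#' @export
calibrate_transforms <- function(layout, config) {
  cfg0 <- config
  cfg0$tracer_ref_bias[] <- 1
  tab <- list()
  for (tr in names(config$tracers)) {
    s0 <- compute_suvr(render_scan(0, tr, layout, cfg0, noise = FALSE),
                       layout$standard_masks)
    s100 <- compute_suvr(render_scan(config$sigmoid$cl_max, tr, layout, cfg0, noise = FALSE),
                         layout$standard_masks)
    slope <- 100 / (s100 - s0)
    tab[[tr]] <- list(slope = slope, intercept = -slope * s0)
  }
  centiloid_transforms(tab)
}

#' Generate a complete phantom cohort
#'
#' Simulates trajectories, renders every scan, calibrates per-tracer
#' Centiloid transforms from anchor groups, and returns (optionally writes)
#' everything every other module consumes: scan records, a ground-truth
#' table, the standard masks and the transforms.
#'
#' @param config A [sim_config()].
#' @param dir If non-`NULL`, writes `manifest.csv`, `ground_truth.csv`,
#'   `transforms.json`, NIfTI volumes and the standard masks there.
#' @return List with `scans` (list of [scan_record()], volumes SUVR
#'   normalised), `truth` (data.frame incl. true_cl and true_suvr), `masks`
#'   (standard [mask_pair()]), `transforms`, `layout`, `config`.
#' @export
make_cohort <- function(config = sim_config(), dir = NULL) {
  layout <- phantom_layout(config$grid)
  truth <- simulate_trajectories(config)
  transforms <- calibrate_transforms(layout, config)
  base_date <- as.Date("2016-01-01")
  truth$date <- base_date + round(truth$years_from_baseline * 365.25)
  truth$ref_bias <- vapply(truth$tracer, function(tr) config$tracer_ref_bias[[tr]], 0)
  truth$true_suvr <- (1 + config$spec_amp * truth$true_cl / config$sigmoid$cl_max) /
    (truth$ref_bias * truth$ref_jitter)
  scans <- with_seed(config$seed + 1L, {
    lapply(seq_len(nrow(truth)), function(i) {
      vol <- render_scan(truth$true_cl[i], truth$tracer[i], layout, config,
                         psf_fwhm_mm = truth$psf_fwhm_mm[i],
                         ref_jitter = truth$ref_jitter[i], noise = TRUE)
      scan_record(truth$participant_id[i], truth$date[i], truth$tracer[i],
                  truth$psf_fwhm_mm[i], volume = vol, is_suvr_normalised = TRUE)
    })
  })
  cohort <- list(scans = scans, truth = truth, masks = layout$standard_masks,
                 transforms = transforms, layout = layout, config = config)
  if (!is.null(dir)) write_cohort(cohort, dir)
  cohort
}

write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- cohort$config$grid
  paths <- character(length(cohort$scans))
  for (i in seq_along(cohort$scans)) {
    s <- cohort$scans[[i]]
    paths[i] <- file.path(dir, sprintf("%s_v%02d.nii.gz", s$participant_id,
                                       cohort$truth$visit[i]))
    save_volume(s$volume, paths[i], grid = g)
  }
  man <- data.frame(participant_id = cohort$truth$participant_id,
                    date = format(cohort$truth$date),
                    tracer = cohort$truth$tracer,
                    psf_fwhm_mm = cohort$truth$psf_fwhm_mm,
                    volume_path = basename(paths))
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  utils::write.csv(cohort$truth, file.path(dir, "ground_truth.csv"), row.names = FALSE)
  write_transforms(cohort$transforms, file.path(dir, "transforms.json"))
  save_volume(cohort$masks$reference, file.path(dir, "ref_mask.nii.gz"), grid = g)
  save_volume(cohort$masks$target, file.path(dir, "target_mask.nii.gz"), grid = g)
  save_volume(cohort$layout$brain, file.path(dir, "brain_mask.nii.gz"), grid = g)
  invisible(dir)
}
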