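test_that("phantom layout regions are disjoint, in-brain and symmetric", {
  lay <- phantom_layout(default_grid())
  expect_gt(sum(lay$target), 0)
  expect_equal(sum(lay$reference_gm), sum(lay$reference_wm))
  expect_equal(sum(lay$target * (lay$reference_gm + lay$reference_wm)), 0)
  expect_true(all(lay$target + lay$reference_gm + lay$reference_wm <= lay$brain))
  for (m in list(lay$brain, lay$target, lay$reference_gm, lay$reference_wm))
    expect_equal(m, deepsuvr:::mirror_volume(m, 1L))
})

test_that("trajectories follow the logistic curve and never decrease", {
  cfg <- sim_config(n_participants = 40L, n_visits = 3L, seed = 11L)
  tr <- simulate_trajectories(cfg)
  expect_equal(nrow(tr), 120L)
  by_p <- split(tr$true_cl, tr$participant_id)
  expect_true(all(vapply(by_p, function(v) all(diff(v) >= 0), TRUE)))

  # at onset age the sigmoid is exactly at half maximum
  expect_equal(deepsuvr:::true_sigmoid_cl(72, 72, 100, 4), 50)

  # all-negative cohort stays flat
  cfg0 <- sim_config(n_participants = 10L, negative_fraction = 1, seed = 3L)
  tr0 <- simulate_trajectories(cfg0)
  expect_true(all(vapply(split(tr0$true_cl, tr0$participant_id),
                         function(v) diff(range(v)) == 0, TRUE)))
  expect_true(all(tr0$true_cl < 10))
})

test_that("sampled rate-vs-level pairs match the analytic sigmoid derivative", {
  cfg <- sim_config(n_participants = 600L, negative_fraction = 0, seed = 0L)
  tr <- simulate_trajectories(cfg)
  by_p <- split(tr, tr$participant_id)
  mean_cl <- vapply(by_p, function(d) mean(d$true_cl), 0)
  rate <- vapply(by_p, function(d) diff(d$true_cl) / diff(d$years_from_baseline), 0)
  # analytic derivative of the logistic: cl' = cl (1 - cl/K) / tau
  K <- cfg$sigmoid$cl_max; tau <- cfg$sigmoid$slope_years
  keep <- mean_cl > 2 & mean_cl < 98
  pred <- mean_cl[keep] * (1 - mean_cl[keep] / K) / tau
  rmse <- sqrt(mean((rate[keep] - pred)^2))
  expect_lt(rmse, 0.05 * (K / (4 * tau)))
})

test_that("rendering honours construction identities", {
  lay <- phantom_layout(default_grid())
  cfg <- sim_config(seed = 1L)
  # no noise, no blur, no bias: SUVR with the true masks is exactly 1 at CL 0
  v0 <- render_scan(0, "PIB", lay, cfg, psf_fwhm_mm = 0, ref_jitter = 1, noise = FALSE)
  expect_equal(compute_suvr(v0, lay$standard_masks), 1, tolerance = 1e-12)

  # reference bias k deflates the standard SUVR by k (within 1%)
  cfgb <- cfg; cfgb$tracer_ref_bias[["FBP"]] <- 1.15
  vb <- render_scan(40, "FBP", lay, cfgb, psf_fwhm_mm = 5, ref_jitter = 1, noise = FALSE)
  vu <- render_scan(40, "FBP", lay, cfg, psf_fwhm_mm = 5, ref_jitter = 1, noise = FALSE)
  ratio <- compute_suvr(vu, lay$standard_masks) / compute_suvr(vb, lay$standard_masks)
  expect_equal(ratio, 1.15, tolerance = 0.01)

  # seeded rendering is deterministic
  v1 <- with_seed_render <- local({
    set.seed(9); render_scan(20, "PIB", lay, cfg)
  })
  v2 <- local({ set.seed(9); render_scan(20, "PIB", lay, cfg) })
  expect_identical(v1, v2)
})

test_that("cohorts are bit-reproducible and internally consistent", {
  cfg <- sim_config(n_participants = 6L, seed = 21L)
  c1 <- make_cohort(cfg)
  c2 <- make_cohort(cfg)
  expect_identical(c1$truth, c2$truth)
  expect_identical(c1$scans[[3]]$volume, c2$scans[[3]]$volume)

  expect_equal(length(c1$scans), 12L)  # 6 participants x 2 visits

  # anchor calibration: true negatives quantify near 0 CL
  q <- quantify_scans(c1$scans, c1$masks, c1$transforms)
  neg <- c1$truth$true_cl < 2
  if (any(neg)) expect_lt(abs(mean(q$cl[neg])), 6)
})

test_that("cohort files on disk are a consumable manifest", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(n_participants = 3L, seed = 2L)
  make_cohort(cfg, dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  scans <- read_manifest(file.path(dir, "manifest.csv"), grid = cfg$grid)
  expect_length(scans, 6L)
  tr <- read_transforms(file.path(dir, "transforms.json"))
  expect_true(all(names(cfg$tracers) %in% names(tr)))
  gt <- utils::read.csv(file.path(dir, "ground_truth.csv"))
  expect_equal(nrow(gt), 6L)
})
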