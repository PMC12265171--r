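test_that("Pearson loss is affine-invariant and averages across tracers", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_loss(x, x), 0)
  expect_equal(pearson_loss(x, 3 * x - 2), 0, tolerance = 1e-12)
  # two groups: one perfectly correlated, one uncorrelated
  set.seed(1)
  a <- rnorm(50); b <- rnorm(50)
  g <- rep(c("PIB", "FBP"), each = 50)
  # construct exact r = 0 for the second group by orthogonalisation
  b2 <- residuals(lm(b ~ a))[1:50]
  lp <- pearson_loss(c(a, a), c(2 * a + 1, b2), g)
  expect_equal(lp, (0 + (1 - cor(a, b2)^2)) / 2, tolerance = 1e-12)
  expect_error(pearson_loss(c(1, 2, 3), rep(1, 3)), "zero variance")
})

test_that("binarity loss matches hand-computed sums", {
  d <- c(4, 4, 4)
  brain <- array(1, d)
  expect_equal(binarity_loss(array(rep(c(0, 1), 32), d), brain), 0)
  expect_equal(binarity_loss(array(0.5, d), brain), 0.5)
  half <- array(c(rep(0.25, 32), rep(1, 32)), d)
  expect_equal(binarity_loss(half, brain), 0.125)
  expect_error(binarity_loss(array(1.2, d), brain), "\\[0, 1\\]")
})

test_that("dice follows the overlap formula", {
  d <- c(6, 6, 6)
  a <- array(0, d); a[1:3, , 1] <- 1
  expect_equal(dice(a, a), 1)
  b <- array(0, d); b[4:6, , 2] <- 1
  expect_equal(dice(a, b), 0)
  # 100 and 100 voxels with 50 shared
  x <- array(0, c(10, 10, 10)); x[1:100] <- 1
  y <- array(0, c(10, 10, 10)); y[51:150] <- 1
  expect_equal(dice(x, y), 0.5)
  expect_error(dice(array(0, d), array(0, d)), "empty")
})

test_that("recalibration lines invert the generating map per tracer", {
  set.seed(2)
  corr <- runif(30, 0.8, 2.2)
  mask <- 0.5 * corr + 0.1
  tr <- rep("PIB", 30)
  lines <- recalibrate(mask, corr, tr)
  expect_equal(lines$PIB$slope, 2, tolerance = 1e-9)
  expect_equal(lines$PIB$intercept, -0.2, tolerance = 1e-9)
  back <- apply_recalibration(lines, mask, tr)
  expect_equal(back, corr, tolerance = 1e-9)
  # affine recalibration does not change R^2
  expect_equal(r_squared(back, corr), 1, tolerance = 1e-12)
  expect_error(recalibrate(rep(1, 5), runif(5), rep("PIB", 5)), "zero variance")
})

test_that("identity recalibration yields slope 1, intercept 0", {
  set.seed(3)
  s <- runif(20, 1, 2)
  lines <- recalibrate(s, s, rep("FBB", 20))
  expect_equal(lines$FBB$slope, 1, tolerance = 1e-9)
  expect_equal(lines$FBB$intercept, 0, tolerance = 1e-9)
})

test_that("delta schedule boosts after the configured epoch", {
  cfg <- mask_opt_config()
  expect_equal(cfg$delta, 5e-4)
  expect_equal(cfg$delta_boost_epoch, 20L)
  expect_equal(cfg$delta_boost_factor, 100)
  expect_equal(cfg$min_iters, c(1000L, 3000L, 8000L))
  # effective delta: before boost epoch = delta, after = delta * 100
  eff <- function(ep) if (ep > cfg$delta_boost_epoch)
    cfg$delta * cfg$delta_boost_factor else cfg$delta
  expect_equal(eff(20), 5e-4)
  expect_equal(eff(21), 5e-2)
})

test_that("mask optimisation at an exact fixed point stays put", {
  coh <- tiny_cohort()
  scans <- coh$scans
  V <- do.call(rbind, lapply(scans, function(s) as.numeric(s$volume)))
  st <- deepsuvr:::mask_suvr_matrix(V, as.numeric(coh$masks$reference),
                                    as.numeric(coh$masks$target))
  # smoothing off and negligible binarity weight: the init masks are an
  # exact optimum, so the optimiser must not move off it
  cfg <- mask_opt_config(level_factors = 1L, min_iters = 25L, max_iters = 25L,
                         window = 10L, lr = 0.02, smooth_fwhm_mm = 0,
                         delta = 1e-9)
  res <- optimize_masks(scans, st$suvr, coh$masks, coh$layout$brain,
                        config = cfg, grid = coh$config$grid, seed = 0)
  expect_lt(res$final_lp, 1e-6)
  expect_gt(dice(res$masks$reference, coh$masks$reference), 0.95)
  expect_gt(dice(res$masks$target, coh$masks$target), 0.95)
  # masks stay in [0,1], mirror-symmetric, with recorded history
  for (m in list(res$masks$reference, res$masks$target)) {
    expect_true(all(m >= 0 & m <= 1))
    expect_equal(m, deepsuvr:::mirror_volume(m, 1L))
  }
  expect_true(all(c("level", "iter", "lp", "lb_ref", "lb_tgt", "delta")
                  %in% names(res$history)))
  # monotone improvement at the level scale
  expect_lte(res$history$lp[nrow(res$history)], res$history$lp[1] + 1e-9)
})

test_that("the delta boost appears in the optimisation history", {
  coh <- tiny_cohort()
  scans <- coh$scans
  V <- do.call(rbind, lapply(scans, function(s) as.numeric(s$volume)))
  st <- deepsuvr:::mask_suvr_matrix(V, as.numeric(coh$masks$reference),
                                    as.numeric(coh$masks$target))
  cfg <- mask_opt_config(level_factors = 1L, min_iters = 30L, max_iters = 30L,
                         window = 10L, lr = 0.02, delta_boost_epoch = 10L)
  res <- optimize_masks(scans, st$suvr, coh$masks, coh$layout$brain,
                        config = cfg, grid = coh$config$grid, seed = 0)
  h <- res$history
  expect_equal(unique(h$delta[h$iter <= 10]), 5e-4)
  expect_equal(unique(h$delta[h$iter > 10]), 5e-2)
})
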