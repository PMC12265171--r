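test_that("two-component mixture recovers generator parameters", {
  set.seed(0)
  n <- 2000
  z <- stats::rbinom(n, 1, 0.3)
  x <- ifelse(z == 1, stats::rnorm(n, 80, 20), stats::rnorm(n, 0, 6))
  fit <- fit_gmm2(x, seed = 0)
  expect_gt(fit$means[fit$first_peak], -1)
  expect_lt(fit$means[fit$first_peak], 1)
  expect_gt(fit$sds[fit$first_peak], 5.4)
  expect_lt(fit$sds[fit$first_peak], 6.6)
  expect_equal(sum(fit$weights), 1, tolerance = 1e-9)

  # two well-separated point clusters
  y <- c(stats::rnorm(500, 0, 0.5), stats::rnorm(500, 100, 0.5))
  f2 <- fit_gmm2(y, seed = 0)
  expect_equal(sort(f2$means), c(0, 100), tolerance = 0.2)

  expect_error(fit_gmm2(rep(5, 30)), "zero variance")
  expect_error(fit_gmm2(stats::rnorm(10)), "at least 20")
})

test_that("mixture fit recovers the negative peak across many seeds", {
  ok <- 0L
  for (s in 1:20) {
    set.seed(100 + s)
    n <- 2000
    z <- stats::rbinom(n, 1, 0.3)
    x <- ifelse(z == 1, stats::rnorm(n, 80, 20), stats::rnorm(n, 0, 6))
    fit <- fit_gmm2(x, seed = s)
    m <- fit$means[fit$first_peak]; sd_ <- fit$sds[fit$first_peak]
    if (m > -1 && m < 1 && sd_ > 5.4 && sd_ < 6.6) ok <- ok + 1L
  }
  expect_gte(ok, 18L)
})

test_that("mixture likelihood matches an independent EM implementation", {
  skip_if_not_installed("mclust")
  suppressMessages(requireNamespace("mclust"))
  set.seed(2)
  x <- c(stats::rnorm(300, 0, 6), stats::rnorm(150, 70, 18))
  fit <- fit_gmm2(x, seed = 0)
  mc <- withr::with_package("mclust",
    mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE))
  expect_equal(fit$loglik, mc$loglik, tolerance = 0.01)
  expect_equal(sort(fit$means), sort(as.numeric(mc$parameters$mean)), tolerance = 0.5)
})

test_that("outlier band is the central percentile interval", {
  set.seed(1)
  r <- runif(20000, -10, 10)
  band <- derive_outlier_band(r)
  expect_equal(band$lower, -9, tolerance = 0.1)
  expect_equal(band$upper, 9, tolerance = 0.1)
  # ~10% of its own reference sample is flagged
  fr <- outlier_fraction(r, band)
  expect_equal(unname(sum(fr)), 10, tolerance = 0.5)
  expect_error(derive_outlier_band(rep(3, 100)), "degenerate")
  expect_error(derive_outlier_band(rnorm(10)), "at least 50")
})

test_that("outlier fractions count band exceedances and are additive", {
  band <- list(lower = -5.8, upper = 11.2)
  expect_equal(outlier_fraction(c(0, 1, -2), band), c(neg_pct = 0, pos_pct = 0))
  r <- c(-7, 12, rep(0, 8))
  expect_equal(outlier_fraction(r, band), c(neg_pct = 10, pos_pct = 10))
  expect_equal(outlier_fraction(numeric(0), band), c(neg_pct = 0, pos_pct = 0))
  # additivity: fraction of a union is the size-weighted average
  a <- rnorm(40); b <- c(rnorm(20), -20, 20)
  fa <- outlier_fraction(a, band); fb <- outlier_fraction(b, band)
  expect_equal(outlier_fraction(c(a, b), band),
               (length(a) * fa + length(b) * fb) / (length(a) + length(b)))
})

test_that("HSIC detects nonlinear dependence and not independence", {
  set.seed(0)
  x <- runif(200, -pi, pi)
  h_dep <- hsic(x, sin(x), n_perm = 1000, seed = 0)
  expect_lt(attr(h_dep, "p_value"), 0.01)
  expect_gt(as.numeric(h_dep), stats::quantile(attr(h_dep, "null"), 0.99))

  # independent samples stay below the permutation threshold most of the time
  reject <- 0L
  for (i in 1:40) {
    set.seed(i)
    a <- rnorm(200); b <- rnorm(200)
    h <- hsic(a, b, n_perm = 200, seed = i)
    if (as.numeric(h) > stats::quantile(attr(h, "null"), 0.95)) reject <- reject + 1L
  }
  expect_lte(reject, 4L)  # ~5% nominal
})

test_that("HSIC is symmetric and vanishes for constant input", {
  set.seed(4)
  x <- rnorm(60); y <- x^2 + rnorm(60, 0, 0.1)
  expect_equal(as.numeric(hsic(x, y)), as.numeric(hsic(y, x)), tolerance = 1e-12)
  expect_equal(as.numeric(hsic(rep(1, 60), y)), 0, tolerance = 1e-12)
  expect_error(hsic(1:20, 1:10), "equal length")
})

test_that("rank and effect-size statistics match their definitions", {
  set.seed(5)
  x <- rnorm(100); y <- 2 * x + rnorm(100)
  expect_equal(spearman(x, y), stats::cor(x, y, method = "spearman"))
  expect_equal(r_squared(x, y), stats::cor(x, y)^2)

  a <- rnorm(10000); b <- rnorm(10000, 1)
  expect_equal(cohens_d(b, a), 1, tolerance = 0.05)
  expect_equal(cohens_d(a, b), -cohens_d(b, a))
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_error(cohens_d(rep(1, 5), rep(1, 5)), "degenerate")
})

test_that("AUC is the rank statistic, invariant under monotone transforms", {
  lab <- c(rep(0, 5), rep(1, 5))
  sc <- c(1:5, 6:10)
  expect_equal(auc(sc, lab), 1)
  expect_equal(auc(-sc, lab), 0)
  set.seed(6)
  sc2 <- rnorm(200); lab2 <- rbinom(200, 1, 0.4)
  expect_equal(auc(exp(sc2), lab2), auc(sc2, lab2))
  expect_error(auc(sc2, rep(1, 200)), "both classes")
  skip_if_not_installed("pROC")
  ref <- as.numeric(pROC::auc(pROC::roc(lab2, sc2, quiet = TRUE, direction = "<")))
  expect_equal(auc(sc2, lab2), ref, tolerance = 1e-12)
})

test_that("paired bootstrap reports sign-based p-values deterministically", {
  set.seed(7)
  a <- rnorm(60)
  pb_same <- paired_bootstrap(a, a, n_boot = 500, seed = 1)
  expect_equal(pb_same$mean_diff, 0)
  expect_equal(pb_same$p, 1)

  b <- a + 5
  pb <- paired_bootstrap(b, a, n_boot = 2000, seed = 1)
  expect_lt(pb$p, 0.001)
  expect_gt(pb$ci95[1], 0)

  pb2 <- paired_bootstrap(b, a, n_boot = 2000, seed = 1)
  expect_identical(pb, pb2)
})

test_that("peak stability flags the method with shrunken peak spread", {
  set.seed(8)
  mk_fit <- function(m) {
    x <- c(rnorm(300, m, 6), rnorm(100, 80, 15))
    fit_gmm2(x, seed = 0)
  }
  means_a <- c(-6, -2, 0, 3, 8)
  fits_a <- lapply(means_a, mk_fit)
  # method B: peak means shrunk 50% toward the grand mean
  fits_b <- lapply(mean(means_a) + 0.5 * (means_a - mean(means_a)), mk_fit)
  ps <- peak_stability(fits_b, fits_a, n_boot = 2000, seed = 0)
  expect_lt(ps$means$mean_diff, 0)      # B more stable
  expect_lt(ps$means$ci95[2], 0)        # significantly so
  identical_ps <- peak_stability(fits_a, fits_a, n_boot = 100, seed = 0)
  expect_equal(identical_ps$means$mean_diff, 0)
  expect_error(peak_stability(fits_a[1:2], fits_a[1:2]), "at least 3")
})

test_that("emergent amyloid classification follows the threshold rules", {
  r1 <- emergent_classification(c(10, 12, 31), c(0, 2, 5))
  expect_equal(r1$label, "emergent_positive")
  expect_equal(r1$baseline_bracket, "[10,15)")

  r2 <- emergent_classification(c(10, 15, 22), c(0, 3, 6))
  expect_equal(r2$label, "stable_negative")

  expect_equal(emergent_classification(c(35, 50), c(0, 5))$label, "ineligible")
  # insufficient follow-up
  expect_equal(emergent_classification(c(10, 40), c(0, 3))$label, "ineligible")
  # baseline below the bracket floor has no bracket
  expect_true(is.na(emergent_classification(c(2, 10), c(0, 5))$baseline_bracket))
})
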