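test_that("conv depth is derived from the grid and never over-reduces", {
  net <- ds_network(default_grid(), seed = 0)
  expect_equal(length(net$plan), 2L)     # 32x40x32 supports two stride-4 blocks
  expect_equal(net$plan[[2]]$out_dims, c(2L, 2L, 2L))
  expect_true(all(vapply(net$plan, function(p) all(p$out_dims >= 1L), TRUE)))

  big <- ds_network(full_grid(), seed = 0)
  expect_lte(length(big$plan), 4L)
  expect_true(all(big$plan[[length(big$plan)]]$out_dims >= 1L))

  expect_error(ds_network(volume_grid(c(4, 4, 4), 4), seed = 0), NA)
  expect_error(volume_grid(c(3, 8, 8), 4), ">= 4")
})

test_that("the correction factor is architecturally bounded in [0, 2]", {
  g <- volume_grid(c(8, 8, 8), 4)
  net <- ds_network(g, seed = 1)
  set.seed(2)
  for (batch in 1:4) {
    V <- matrix(runif(250 * prod(g$shape), 0, 10), 250)
    cf <- deepsuvr:::ds_forward(net, V, sample(TRACERS, 250, TRUE),
                                training = FALSE, keep_cache = FALSE)$cf
    expect_true(all(cf >= 0 & cf <= 2))
  }
  # extreme head biases drive cf to the limits
  net$params$head_b <- 100
  v1 <- array(runif(prod(g$shape)), g$shape)
  expect_equal(predict_cf(net, v1, "PIB"), 2, tolerance = 1e-6)
  net$params$head_b <- -100
  expect_equal(predict_cf(net, v1, "PIB"), 0, tolerance = 1e-6)
  # zero head weights and bias: cf = 2*sigmoid(0) = 1
  net$params$head_W[] <- 0
  net$params$head_b <- 0
  expect_equal(predict_cf(net, v1, "FMM"), 1)
})

test_that("inference is deterministic in evaluation mode", {
  net <- ds_network(default_grid(), seed = 3)
  v <- array(runif(prod(default_grid()$shape)), default_grid()$shape)
  expect_identical(predict_cf(net, v, "NAV"), predict_cf(net, v, "NAV"))
  expect_error(predict_cf(net, array(1, c(8, 8, 8)), "NAV"), "does not match|voxels")
})

test_that("network backward pass matches finite differences", {
  g <- volume_grid(c(16, 16, 16), 4)
  net <- ds_network(g, seed = 3)
  set.seed(42)
  vols <- lapply(1:4, function(i) array(runif(prod(g$shape)), g$shape))
  tracers <- c("PIB", "FBP", "NAV", "PIB")
  wts <- rnorm(4)
  loss_of <- function(net) {
    set.seed(7)
    sum(deepsuvr:::ds_forward(net, vols, tracers, training = TRUE)$cf * wts)
  }
  set.seed(7)
  fw <- deepsuvr:::ds_forward(net, vols, tracers, training = TRUE)
  gr <- deepsuvr:::ds_backward(net, fw, wts)
  eps <- 1e-5
  for (nm in c("conv1_W", "conv2_W", "fc1_W", "fc1_gamma", "fc2_beta",
               "head_W", "head_b")) {
    p <- net$params[[nm]]
    for (i in sample(length(p), min(3, length(p)))) {
      n1 <- net; n1$params[[nm]][i] <- p[i] + eps
      n2 <- net; n2$params[[nm]][i] <- p[i] - eps
      fd <- (loss_of(n1) - loss_of(n2)) / (2 * eps)
      expect_equal(gr[[nm]][i], fd, tolerance = 1e-3,
                   label = sprintf("grad %s[%d]", nm, i))
    }
  }
})

test_that("correct_scan composes SUVR, cf and the Centiloid transform", {
  coh <- tiny_cohort()
  net <- ds_network(default_grid(), seed = 0)
  net$params$head_W[] <- 0; net$params$head_b <- 0  # force cf = 1
  out <- correct_scan(coh$scans[1:5], coh$masks, coh$transforms, net)
  expect_equal(nrow(out), 5L)
  expect_equal(out$cf, rep(1, 5))
  expect_equal(out$corrected_suvr, out$standard_suvr)
  expect_equal(out$corrected_cl,
               suvr_to_centiloid(out$standard_suvr, out$tracer, coh$transforms))
  # order preserved
  expect_equal(out$participant_id,
               vapply(coh$scans[1:5], function(s) s$participant_id, ""))
})

test_that("checkpoints round-trip with a JSON sidecar", {
  dir <- withr::local_tempdir()
  net <- ds_network(volume_grid(c(8, 8, 8), 4), seed = 5)
  p <- file.path(dir, "m.rds")
  write_model(net, p, config = list(lr = 1e-3))
  net2 <- read_model(p)
  v <- array(runif(512), c(8, 8, 8))
  expect_identical(predict_cf(net, v, "FBB"), predict_cf(net2, v, "FBB"))
  side <- jsonlite::read_json(paste0(p, ".json"), simplifyVector = TRUE)
  expect_equal(side$grid$shape, c(8, 8, 8))
  expect_equal(side$config$lr, 1e-3)
})
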