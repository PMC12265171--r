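#' Training control parameters
#'
#' @param batch_pairs Pairs per batch; both images of a pair pass through the
#'   network in the same iteration, so 64 pairs = 128 images per batch.
#' @param lr Initial Adam learning rate.
#' @param lr_decay Per-epoch multiplicative learning-rate decay. The absolute
#'   losses have piecewise-constant gradients, so without annealing the
#'   parameters random-walk around the optimum at small cohort sizes;
#'   the default anneals the rate to a few percent over several hundred
#'   epochs.
#' @param max_epochs Upper bound on epochs.
#' @param patience Early stopping: stop when the validation loss has not
#'   improved for this many consecutive epochs.
#' @param min_epochs Epochs trained before early stopping may trigger.
#' @param augment Whether to apply rotation/deformation/PSF augmentation to
#'   the training volumes each epoch.
#' @param dropout Dropout rate of the fully connected blocks during training
#'   (0 at desk scale; 0.5 in the full-scale architecture).
#' @param verbose Print per-epoch progress.
#' @export
deepsuvr_control <- function(batch_pairs = 64L, lr = 3e-3, lr_decay = 0.995,
                             max_epochs = 600L, patience = 20L,
                             min_epochs = 300L, augment = FALSE,
                             dropout = 0, verbose = FALSE) {
  structure(list(batch_pairs = as.integer(batch_pairs), lr = lr,
                 lr_decay = lr_decay, max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 min_epochs = as.integer(min_epochs),
                 augment = isTRUE(augment), dropout = dropout,
                 verbose = isTRUE(verbose)),
            class = "deepsuvr_control")
}

# Attach standard SUVR/CL and an SUVR-normalised volume to each scan, and
# build the eligible visit pairs carrying those quantities.
prepare_training_pairs <- function(scans, masks, transforms,
                                   min_years = 0.25, max_years = 3.5) {
  scans <- lapply(scans, function(s) {
    s$suvr <- compute_suvr(s$volume, masks)
    s$cl <- suvr_to_centiloid(s$suvr, s$tracer, transforms)
    if (!isTRUE(s$is_suvr_normalised)) {
      s$volume <- suvr_normalise(s$volume, masks$reference)
      s$is_suvr_normalised <- TRUE
    }
    s
  })
  build_pairs(scans, min_years = min_years, max_years = max_years)
}

pair_scan_vectors <- function(pairs) {
  list(
    vols = c(lapply(pairs, function(p) p$scan_t0$volume),
             lapply(pairs, function(p) p$scan_t1$volume)),
    tracers = c(vapply(pairs, function(p) p$scan_t0$tracer, ""),
                vapply(pairs, function(p) p$scan_t1$tracer, "")),
    suvr = c(vapply(pairs, function(p) p$scan_t0$suvr, 0),
             vapply(pairs, function(p) p$scan_t1$suvr, 0)),
    cl = c(vapply(pairs, function(p) p$scan_t0$cl, 0),
           vapply(pairs, function(p) p$scan_t1$cl, 0)),
    psf = c(vapply(pairs, function(p) p$scan_t0$psf_fwhm_mm, 0),
            vapply(pairs, function(p) p$scan_t1$psf_fwhm_mm, 0)),
    dt = vapply(pairs, function(p) p$interval_years, 0))
}

stack_volumes <- function(vols) do.call(rbind, lapply(vols, as.numeric))

eval_pairs_loss <- function(net, pv, weights, curve, transforms) {
  B <- length(pv$dt)
  if (is.null(pv$V)) pv$V <- stack_volumes(pv$vols)
  fw <- ds_forward(net, pv$V, pv$tracers, training = FALSE, keep_cache = FALSE)
  corrected <- suvr_to_centiloid(fw$cf * pv$suvr, pv$tracers, transforms)
  bl <- batch_loss_grad(corrected, pv$cl, cbind(seq_len(B), B + seq_len(B)),
                        pv$dt, weights, curve)
  list(loss = bl$loss, components = bl$components, cf = fw$cf, corrected_cl = corrected)
}

#' Train the correction network on one fold
#'
#' Longitudinal-pair training: per batch, both images of each pair are run
#' through the network in the same iteration in randomised order, the four
#' losses are computed on the corrected Centiloids, and the network is
#' updated with Adam. Early stopping monitors the validation loss (network
#' in evaluation mode) and the checkpoint with the best validation loss is
#' returned.
#'
#' @param train_pairs,val_pairs Visit pairs from [prepare_training_pairs()];
#'   the participant sets must be disjoint.
#' @param weights A [loss_weights()].
#' @param curve The frozen natural-history curve.
#' @param transforms [centiloid_transforms()] table.
#' @param control A [deepsuvr_control()].
#' @param seed Seed for initialisation, shuffling, dropout and augmentation.
#' @param grid The [volume_grid()] (defaults to the volume dims of the first
#'   scan at the configured voxel size).
#' @return List with `network` (best checkpoint), `history` (per-epoch
#'   data.frame), `best_val`, `best_epoch`.
#' @export
train_fold <- function(train_pairs, val_pairs, weights, curve, transforms,
                       control = deepsuvr_control(), seed = 0L, grid = NULL) {
  if (!length(train_pairs)) stop("empty training set")
  tr_ids <- unique(vapply(train_pairs, function(p) p$participant_id, ""))
  va_ids <- unique(vapply(val_pairs, function(p) p$participant_id, ""))
  if (length(intersect(tr_ids, va_ids)))
    stop("training and validation participants must be disjoint")
  if (is.null(grid)) {
    d <- dim(train_pairs[[1]]$scan_t0$volume)
    grid <- volume_grid(d, voxel_size_mm = 4)
  }
  net <- ds_network(grid, seed = seed, dropout = control$dropout)
  opt <- adam_init(net$params)
  tv <- pair_scan_vectors(train_pairs)
  vv <- pair_scan_vectors(val_pairs)
  vv$V <- stack_volumes(vv$vols)
  tvV <- if (!control$augment) stack_volumes(tv$vols) else NULL
  nB <- length(train_pairs)
  slopes <- vapply(tv$tracers, function(t) get_transform(transforms, t)$slope, 0)

  best <- list(val = Inf, params = net$params, running = net$running, epoch = 0L)
  wait <- 0L
  hist <- list()
  with_seed(seed, {
    for (epoch in seq_len(control$max_epochs)) {
      perm_pairs <- sample(nB)
      bstart <- seq(1L, nB, by = control$batch_pairs)
      ep_loss <- 0; ep_n <- 0L
      for (bs in bstart) {
        sel <- perm_pairs[bs:min(bs + control$batch_pairs - 1L, nB)]
        if (length(sel) < 2L) next  # anchor regression needs >= 3 scans
        idx <- c(sel, nB + sel)     # stack layout: t0 block then t1 block
        feed <- sample(length(idx))  # randomised feed order
        Vb <- if (control$augment) {
          vols <- lapply(seq_along(idx), function(i)
            augment(tv$vols[[idx[i]]], tv$psf[idx[i]], grid))
          stack_volumes(vols[feed])
        } else tvV[idx[feed], , drop = FALSE]
        fw <- ds_forward(net, Vb, tv$tracers[idx][feed], training = TRUE)
        cf <- numeric(length(idx)); cf[feed] <- fw$cf
        corrected <- slopes[idx] * (cf * tv$suvr[idx]) +
          vapply(tv$tracers[idx], function(t) get_transform(transforms, t)$intercept, 0)
        B <- length(sel)
        bl <- batch_loss_grad(corrected, tv$cl[idx],
                              cbind(seq_len(B), B + seq_len(B)),
                              tv$dt[sel], weights, curve)
        dcf <- bl$grad_cl * slopes[idx] * tv$suvr[idx]
        grads <- ds_backward(net, fw, dcf[feed])
        net$running <- fw$running
        st <- adam_step(net$params, grads, opt,
                        control$lr * control$lr_decay^(epoch - 1L))
        net$params <- st$params; opt <- st$state
        ep_loss <- ep_loss + bl$loss * B; ep_n <- ep_n + B
      }
      ev <- eval_pairs_loss(net, vv, weights, curve, transforms)
      hist[[epoch]] <- c(epoch = epoch, train_loss = ep_loss / max(ep_n, 1L),
                         val_loss = ev$loss, ev$components)
      if (control$verbose)
        message(sprintf("epoch %3d train %.4f val %.4f", epoch,
                        ep_loss / max(ep_n, 1L), ev$loss))
      if (ev$loss < best$val - 1e-12) {
        best <- list(val = ev$loss, params = net$params, running = net$running,
                     epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= control$patience && epoch >= control$min_epochs) break
      }
    }
  })
  net$params <- best$params
  net$running <- best$running
  list(network = net, history = as.data.frame(do.call(rbind, hist)),
       best_val = best$val, best_epoch = best$epoch)
}

#' Select the best of several restarts
#'
#' Among candidate trained models sharing a validation set, returns the one
#' with the highest Spearman rank correlation between the pairs' mean
#' corrected Centiloid and corrected CL/year; ties are broken by the lowest
#' validation loss, then by candidate order.
#'
#' @param models List of [train_fold()] results.
#' @param val_pairs Common validation pairs.
#' @param weights,curve,transforms As in [train_fold()].
#' @return List: `model` (the winner), `index`, `rho` (all candidates).
#' @export
select_best_restart <- function(models, val_pairs, weights, curve, transforms) {
  vv <- pair_scan_vectors(val_pairs)
  B <- length(val_pairs)
  stats_ <- lapply(models, function(m) {
    ev <- eval_pairs_loss(m$network, vv, weights, curve, transforms)
    mean_cl <- (ev$corrected_cl[seq_len(B)] + ev$corrected_cl[B + seq_len(B)]) / 2
    rate <- (ev$corrected_cl[B + seq_len(B)] - ev$corrected_cl[seq_len(B)]) / vv$dt
    c(rho = spearman(mean_cl, rate), val = ev$loss)
  })
  rho <- vapply(stats_, `[[`, 0, "rho")
  val <- vapply(stats_, `[[`, 0, "val")
  ord <- order(-rho, val)
  list(model = models[[ord[1]]], index = ord[1], rho = rho, val_loss = val)
}

#' Balanced participant fold assignment
#'
#' Greedy snake assignment of participants to `k` folds, stratified so each
#' fold has a similar tracer mix, visit count and Centiloid distribution;
#' each participant belongs to exactly one fold.
#'
#' @param quant data.frame with columns participant_id, tracer, cl (one row
#'   per scan), e.g. from [quantify_scans()].
#' @param k Number of folds.
#' @param seed Seed for tie-shuffling.
#' @return Named integer vector participant_id -> fold in `0..k-1`.
#' @export
make_folds <- function(quant, k = 5L, seed = 0L) {
  agg <- do.call(rbind, lapply(split(quant, quant$participant_id), function(d)
    data.frame(participant_id = d$participant_id[1],
               tracer = names(sort(table(d$tracer), decreasing = TRUE))[1],
               n_visits = nrow(d), mean_cl = mean(d$cl))))
  with_seed(seed, {
    agg <- agg[sample(nrow(agg)), ]
    agg <- agg[order(agg$tracer, agg$n_visits, agg$mean_cl), ]
  })
  snake <- rep(c(0:(k - 1L), (k - 1L):0), length.out = nrow(agg))
  stats::setNames(snake, agg$participant_id)
}

#' Fit a trajectory-constrained SUVR correction model
#'
#' The main fitting entry point. Quantifies the scans with the standard
#' masks and per-tracer Centiloid transforms, builds within-participant
#' visit pairs (3 months to 3.5 years apart), fits (or accepts) the frozen
#' lowess natural-history curve from standard-quantification pairs of the
#' reference tracer, splits participants into training and validation sets,
#' trains the correction network with the combined loss `L = Ld + alpha*Lc +
#' beta*Ls + gamma*Li` under early stopping, over one or more seeded
#' restarts, and returns the model selected by validation Spearman rank
#' correlation of mean corrected CL versus corrected CL/year.
#'
#' @param scans List of [scan_record()]s with volumes.
#' @param masks Standard [mask_pair()].
#' @param transforms [centiloid_transforms()] table.
#' @param curve Optional pre-fitted [fit_natural_history()] curve; if `NULL`
#'   it is fitted from the standard quantification of `curve_tracer` pairs.
#' @param curve_tracer Tracer used for the curve fit (default PIB).
#' @param weights A [loss_weights()].
#' @param control A [deepsuvr_control()].
#' @param restarts Number of seeded restarts (the best is kept).
#' @param val_split Fraction of participants held out for validation.
#' @param seed Base seed; restart r uses `seed + r - 1`.
#' @return Object of class `deepsuvr` with `network`, `history`, `curve`,
#'   `val_cf` etc.; see [predict.deepsuvr()].
#' @export
deepsuvr <- function(scans, masks, transforms, curve = NULL,
                     curve_tracer = "PIB", weights = loss_weights(),
                     control = deepsuvr_control(), restarts = 1L,
                     val_split = 0.25, seed = 0L) {
  pairs <- prepare_training_pairs(scans, masks, transforms)
  if (!length(pairs)) stop("no eligible visit pairs")
  if (is.null(curve)) {
    ps <- vapply(pairs, function(p) {
      if (p$scan_t0$tracer == curve_tracer && p$scan_t1$tracer == curve_tracer)
        pair_statistics(p, p$scan_t0$cl, p$scan_t1$cl) else c(NA_real_, NA_real_)
    }, c(0, 0))
    ok <- is.finite(ps[1, ])
    curve <- fit_natural_history(ps[1, ok], ps[2, ok])
  }
  ids <- vapply(pairs, function(p) p$participant_id, "")
  k <- max(2L, round(1 / val_split))
  quant <- data.frame(
    participant_id = c(ids, ids),
    tracer = c(vapply(pairs, function(p) p$scan_t0$tracer, ""),
               vapply(pairs, function(p) p$scan_t1$tracer, "")),
    cl = c(vapply(pairs, function(p) p$scan_t0$cl, 0),
           vapply(pairs, function(p) p$scan_t1$cl, 0)))
  folds <- make_folds(quant, k = k, seed = seed)
  val_ids <- names(folds)[folds == 0L]
  val_pairs <- pairs[ids %in% val_ids]
  train_pairs <- pairs[!ids %in% val_ids]
  if (!length(val_pairs)) stop("validation split is empty")
  runs <- lapply(seq_len(restarts), function(r)
    train_fold(train_pairs, val_pairs, weights, curve, transforms,
               control = control, seed = seed + r - 1L))
  sel <- if (restarts > 1L)
    select_best_restart(runs, val_pairs, weights, curve, transforms)
  else list(model = runs[[1]], index = 1L, rho = NA_real_)
  vv <- pair_scan_vectors(val_pairs)
  ev <- eval_pairs_loss(sel$model$network, vv, weights, curve, transforms)
  B <- length(val_pairs)
  structure(list(network = sel$model$network, history = sel$model$history,
                 best_epoch = sel$model$best_epoch, best_val = sel$model$best_val,
                 restart_index = sel$index, restart_rho = sel$rho,
                 curve = curve, weights = weights, control = control,
                 transforms = transforms, masks = masks, seed = seed,
                 val_ids = val_ids, val_cf = ev$cf,
                 val_pair_stats = data.frame(
                   mean_cl = (ev$corrected_cl[seq_len(B)] + ev$corrected_cl[B + seq_len(B)]) / 2,
                   rate = (ev$corrected_cl[B + seq_len(B)] - ev$corrected_cl[seq_len(B)]) / vv$dt,
                   dt = vv$dt,
                   expected_rate = predict(curve, (ev$corrected_cl[seq_len(B)] +
                                                     ev$corrected_cl[B + seq_len(B)]) / 2))),
            class = "deepsuvr")
}

#' @export
print.deepsuvr <- function(x, ...) {
  cat("Trajectory-constrained SUVR correction model\n")
  cat(sprintf("  grid %s, %d conv block(s); trained %d epoch(s), best epoch %d\n",
              paste(x$network$grid$shape, collapse = "x"), length(x$network$plan),
              nrow(x$history), x$best_epoch))
  cat(sprintf("  best validation loss %.4f; validation cf in [%.3f, %.3f]\n",
              x$best_val, min(x$val_cf), max(x$val_cf)))
  invisible(x)
}

#' @export
summary.deepsuvr <- function(object, ...) {
  out <- list(
    epochs = nrow(object$history), best_epoch = object$best_epoch,
    best_val = object$best_val,
    cf_quartiles = stats::quantile(object$val_cf, c(0.25, 0.5, 0.75)),
    val_spearman = spearman(object$val_pair_stats$mean_cl, object$val_pair_stats$rate),
    weights = unlist(object$weights))
  class(out) <- "summary.deepsuvr"
  out
}

#' @export
print.summary.deepsuvr <- function(x, ...) {
  cat(sprintf("Epochs trained: %d (best %d, validation loss %.4f)\n",
              x$epochs, x$best_epoch, x$best_val))
  cat(sprintf("Validation cf quartiles: %.3f / %.3f / %.3f\n",
              x$cf_quartiles[1], x$cf_quartiles[2], x$cf_quartiles[3]))
  cat(sprintf("Validation Spearman rho(mean CL, CL/yr): %.3f\n", x$val_spearman))
  cat(sprintf("Loss weights: alpha=%.3g beta=%.3g gamma=%.3g\n",
              x$weights["alpha"], x$weights["beta"], x$weights["gamma"]))
  invisible(x)
}

#' Predict corrected quantification for new scans
#'
#' @param object A fitted [deepsuvr()] model.
#' @param newdata A [scan_record()] or list of them.
#' @param ... Unused.
#' @return data.frame from [correct_scan()].
#' @export
predict.deepsuvr <- function(object, newdata, ...) {
  correct_scan(newdata, object$masks, object$transforms, object$network)
}

#' @export
plot.deepsuvr <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("grey40", "firebrick"),
                    xlab = "epoch", ylab = "loss", ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("topright", c("training", "validation"), lty = 1,
                   col = c("grey40", "firebrick"), bty = "n")
  invisible(x)
}

#' @export
coef.deepsuvr <- function(object, ...) object$network$params

#' Validation-pair rate residuals
#'
#' Residuals of the corrected annual rate against the natural-history
#' expectation at the pair's mean corrected Centiloid, on the held-out
#' validation pairs.
#'
#' @param object A fitted [deepsuvr()] model.
#' @param ... Unused.
#' @export
residuals.deepsuvr <- function(object, ...) {
  object$val_pair_stats$rate - object$val_pair_stats$expected_rate
}

#' Bias-preservation (overfitting-risk) experiment
#'
#' Assigns a fraction of participants, stratified across folds, an
#' artificially accelerated accumulation rate by halving the time interval
#' between their scans, retrains the correction model on the modified
#' cohort, and reports the ratio of median annual rates
#' (accelerated/normal) before and after correction. A corrected ratio
#' close to the uncorrected one means the distinct subgroup trajectory is
#' preserved rather than forced onto the population curve.
#'
#' @param cohort A [make_cohort()] result.
#' @param fraction Fraction of participants to accelerate (default 0.10).
#' @param control,weights,restarts,val_split,seed Passed to [deepsuvr()].
#' @return List with the refitted `model`, per-group median standard and
#'   corrected rates, and `preserved_ratio` (corrected accelerated/normal
#'   median rate ratio).
#' @export
run_bias_preservation_experiment <- function(cohort, fraction = 0.10,
                                             control = deepsuvr_control(),
                                             weights = loss_weights(),
                                             restarts = 1L, val_split = 0.2,
                                             seed = 0L) {
  scans <- cohort$scans
  quant <- quantify_scans(scans, cohort$masks, cohort$transforms)
  folds <- make_folds(quant, k = 5L, seed = seed)
  accel_ids <- character(0)
  if (fraction > 0) {
    for (f in 0:4) {
      ids_f <- names(folds)[folds == f]
      n_acc <- round(fraction * length(ids_f))
      if (n_acc > 0) accel_ids <- c(accel_ids, with_seed(seed + f, sample(ids_f, n_acc)))
    }
  }
  # halve inter-scan intervals for the accelerated participants
  ids <- vapply(scans, function(s) s$participant_id, "")
  for (id in accel_ids) {
    w <- which(ids == id)
    w <- w[order(vapply(scans[w], function(s) as.numeric(s$date), 0))]
    d0 <- scans[[w[1]]]$date
    for (j in w[-1])
      scans[[j]]$date <- d0 + round(as.numeric(scans[[j]]$date - d0) / 2)
  }
  fit <- deepsuvr(scans, cohort$masks, cohort$transforms, weights = weights,
                  control = control, restarts = restarts,
                  val_split = val_split, seed = seed)
  pairs <- prepare_training_pairs(scans, cohort$masks, cohort$transforms)
  consec <- consecutive_pairs(pairs)
  pv <- pair_scan_vectors(consec)
  B <- length(consec)
  ev <- eval_pairs_loss(fit$network, pv, weights, fit$curve, cohort$transforms)
  std_rate <- (pv$cl[B + seq_len(B)] - pv$cl[seq_len(B)]) / pv$dt
  cor_rate <- (ev$corrected_cl[B + seq_len(B)] - ev$corrected_cl[seq_len(B)]) / pv$dt
  grp <- vapply(consec, function(p) p$participant_id %in% accel_ids, TRUE)
  med <- function(v, g) stats::median(v[g])
  res <- list(model = fit, accelerated_ids = accel_ids,
              n_pairs = c(accelerated = sum(grp), normal = sum(!grp)),
              median_standard = c(accelerated = med(std_rate, grp),
                                  normal = med(std_rate, !grp)),
              median_corrected = c(accelerated = med(cor_rate, grp),
                                   normal = med(cor_rate, !grp)))
  res$standard_ratio <- unname(res$median_standard["accelerated"] /
                                 res$median_standard["normal"])
  res$preserved_ratio <- unname(res$median_corrected["accelerated"] /
                                  res$median_corrected["normal"])
  res
}

# Keep only consecutive-visit pairs (visit i with visit i+1).
consecutive_pairs <- function(pairs) {
  keep <- logical(length(pairs))
  ids <- vapply(pairs, function(p) p$participant_id, "")
  for (id in unique(ids)) {
    w <- which(ids == id)
    t0 <- vapply(pairs[w], function(p) as.numeric(p$scan_t0$date), 0)
    t1 <- vapply(pairs[w], function(p) as.numeric(p$scan_t1$date), 0)
    dates <- sort(unique(c(t0, t1)))
    nxt <- stats::setNames(c(dates[-1], NA), dates)
    keep[w] <- !is.na(nxt[as.character(t0)]) & nxt[as.character(t0)] == t1
  }
  pairs[keep]
}
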