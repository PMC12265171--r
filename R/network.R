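# Correction-factor network.
#
# Architecture: up to four 3D convolutional blocks (kernel 4, stride 4, so
# each block is a non-overlapping 4x4x4 patch embedding implemented as a
# matrix product), channels 16/32/64/128, each followed by instance
# normalisation and leaky rectification; the flattened features are
# concatenated with a length-5 tracer one-hot and passed through two fully
# connected blocks (dropout 0.5, affine, batch normalisation, tanh) and a
# final affine + logistic head scaled by 2, so the correction factor is
# architecturally confined to [0, 2].
#
# The number of conv blocks is derived from the grid: blocks = max k with
# floor(axis/4^k) >= 1 on every axis, capped at 4. At full template scale
# (91x109x91) this gives the four-block architecture; the desk-scale
# 32x40x32 grid supports two blocks.

NET_EPS <- 1e-5

conv_block_plan <- function(shape, max_blocks = 4L) {
  plan <- list(); d <- shape
  while (length(plan) < max_blocks && all(d %/% 4L >= 1L)) {
    o <- d %/% 4L
    plan[[length(plan) + 1L]] <- list(in_dims = d, out_dims = o)
    d <- o
  }
  if (!length(plan)) stop("grid too small for a stride-4 convolution")
  plan
}

# Patch-gather index: for stage with input dims d and output dims o, a
# 64 x prod(o) matrix addressing the voxels of each non-overlapping 4x4x4
# patch (within-patch offset fastest).
patch_index <- function(d, o) {
  off <- as.matrix(expand.grid(u = 1:4, v = 1:4, w = 1:4))
  pos <- as.matrix(expand.grid(i = seq_len(o[1]), j = seq_len(o[2]), l = seq_len(o[3])))
  x <- outer(off[, 1], 4L * (pos[, 1] - 1L), `+`)
  y <- outer(off[, 2], 4L * (pos[, 2] - 1L), `+`)
  z <- outer(off[, 3], 4L * (pos[, 3] - 1L), `+`)
  matrix(as.integer(x + (y - 1L) * d[1] + (z - 1L) * d[1] * d[2]), 64L)
}

# Column-gather index for the images-by-features layout: features live in an
# n x (P*cin) matrix with column p + (c-1)*P; the gather produces the im2col
# matrix by pure column subsetting, ordered so reshaping to the
# (n*patches) x (64*cin) weight-input matrix is a dim<- reinterpretation.
gather_index <- function(Im, P_in, cin) {
  as.integer(outer(as.vector(t(Im)), (seq_len(cin) - 1L) * P_in, `+`))
}

#' Construct the correction-factor network
#'
#' Builds an untrained network for a given grid with seeded fan-in-scaled
#' uniform weight initialisation. Normally called through [deepsuvr()] or
#' [train_fold()].
#'
#' @param grid A [volume_grid()].
#' @param seed Integer seed for weight initialisation.
#' @param hidden Widths of the two fully connected blocks.
#' @param leaky Negative slope of the leaky rectification.
#' @param conv_channels Channel progression of the conv blocks (truncated to
#'   the number of blocks the grid supports).
#' @param dropout Dropout rate of the fully connected blocks (active in
#'   training mode only). The full-scale architecture uses 0.5; desk-scale
#'   training sets it to 0 because with only tens of pairs per batch the
#'   dropout-induced output jitter dominates the sign-based loss gradients.
#' @return Object of class `ds_network` (evaluation mode by default).
#' @export
ds_network <- function(grid, seed = 0L, hidden = c(256L, 64L), leaky = 0.01,
                       conv_channels = c(16L, 32L, 64L, 128L), dropout = 0.5) {
  stopifnot(inherits(grid, "volume_grid"))
  plan <- conv_block_plan(grid$shape, max_blocks = length(conv_channels))
  nb <- length(plan)
  chans <- conv_channels[seq_len(nb)]
  idx <- vector("list", nb)
  params <- list()
  with_seed(seed, {
    cin <- 1L
    for (k in seq_len(nb)) {
      Im <- patch_index(plan[[k]]$in_dims, plan[[k]]$out_dims)
      idx[[k]] <- gather_index(Im, prod(plan[[k]]$in_dims), cin)
      fan_in <- 64L * cin
      s <- 1 / sqrt(fan_in)
      params[[paste0("conv", k, "_W")]] <-
        matrix(stats::runif(fan_in * chans[k], -s, s), fan_in, chans[k])
      params[[paste0("conv", k, "_b")]] <- stats::runif(chans[k], -s, s)
      cin <- chans[k]
    }
    feat_dim <- prod(plan[[nb]]$out_dims) * chans[nb]
    din <- feat_dim + length(TRACERS)
    for (st in 1:2) {
      s <- 1 / sqrt(din)
      params[[paste0("fc", st, "_W")]] <- matrix(stats::runif(din * hidden[st], -s, s), din, hidden[st])
      params[[paste0("fc", st, "_b")]] <- stats::runif(hidden[st], -s, s)
      params[[paste0("fc", st, "_gamma")]] <- rep(1, hidden[st])
      params[[paste0("fc", st, "_beta")]] <- rep(0, hidden[st])
      din <- hidden[st]
    }
    s <- 1 / sqrt(din)
    params$head_W <- matrix(stats::runif(din, -s, s), din, 1)
    params$head_b <- stats::runif(1, -s, s)
  })
  running <- list(count = 0)
  for (st in 1:2) {
    running[[paste0("fc", st, "_mean")]] <- rep(0, hidden[st])
    running[[paste0("fc", st, "_var")]] <- rep(1, hidden[st])
  }
  structure(list(grid = grid, plan = plan, idx = idx, channels = chans,
                 hidden = hidden, leaky = leaky, dropout = dropout, seed = seed,
                 feat_dim = prod(plan[[nb]]$out_dims) * chans[nb],
                 params = params, running = running),
            class = "ds_network")
}

#' @export
print.ds_network <- function(x, ...) {
  cat(sprintf("<ds_network> grid %s; %d conv block(s) (channels %s); fc %s; %d parameters\n",
              paste(x$grid$shape, collapse = "x"), length(x$plan),
              paste(x$channels, collapse = ","), paste(x$hidden, collapse = ","),
              sum(vapply(x$params, length, 0L))))
  invisible(x)
}

tracer_onehot <- function(tracer) {
  m <- matrix(0, length(tracer), length(TRACERS))
  j <- match(tracer, TRACERS)
  if (anyNA(j)) stop(sprintf("unknown tracer '%s'", tracer[which(is.na(j))[1]]))
  m[cbind(seq_along(tracer), j)] <- 1
  m
}

# Batched conv stack. Features are carried as an n x (P*channels) matrix
# (column p + (c-1)*P), so patch gathering is a column subset and every
# reshape to/from the (n*patches) x (64*cin) weight-input layout is a free
# dim<- reinterpretation; the whole batch runs through one BLAS product per
# block. Instance norm groups rows with rowsum().
conv_forward_batch <- function(net, V, keep_cache = TRUE) {
  p <- net$params
  n <- nrow(V)
  Fm <- V
  caches <- if (keep_cache) vector("list", length(net$plan)) else NULL
  for (k in seq_along(net$plan)) {
    cin <- if (k == 1L) 1L else net$channels[k - 1L]
    pk <- prod(net$plan[[k]]$out_dims)
    X <- Fm[, net$idx[[k]], drop = FALSE]
    dim(X) <- c(n * pk, 64L * cin)
    H <- X %*% p[[paste0("conv", k, "_W")]]
    H <- sweep(H, 2L, p[[paste0("conv", k, "_b")]], `+`)
    cout <- ncol(H)
    grp <- rep.int(seq_len(n), pk)   # row i + (p-1)*n belongs to image i
    if (pk > 1L) {
      # instance normalisation: per image and channel over spatial positions
      mu <- rowsum(H, grp, reorder = FALSE) / pk
      Hc <- H - mu[grp, , drop = FALSE]
      sd_ <- sqrt(rowsum(Hc * Hc, grp, reorder = FALSE) / pk + NET_EPS)
      Hn <- Hc / sd_[grp, , drop = FALSE]
    } else {
      # a 1x1x1 feature map has no spatial statistics to normalise
      sd_ <- NULL
      Hn <- H
    }
    pos <- Hn > 0
    A <- Hn
    A[!pos] <- A[!pos] * net$leaky
    if (keep_cache) caches[[k]] <- list(X = X, Hn = Hn, sd = sd_, pos = pos)
    dim(A) <- c(n, pk * cout)
    Fm <- A
  }
  list(Z = Fm, caches = caches)
}

conv_backward_batch <- function(net, caches, dZ, grads) {
  nb <- length(net$plan)
  n <- nrow(dZ)
  dFm <- dZ
  for (k in nb:1) {
    ca <- caches[[k]]
    pk <- prod(net$plan[[k]]$out_dims)
    cout <- net$channels[k]
    cin <- if (k == 1L) 1L else net$channels[k - 1L]
    dHn <- dFm
    dim(dHn) <- c(n * pk, cout)
    dHn[!ca$pos] <- dHn[!ca$pos] * net$leaky
    if (pk > 1L) {
      grp <- rep.int(seq_len(n), pk)
      m1 <- rowsum(dHn, grp, reorder = FALSE) / pk
      m2 <- rowsum(dHn * ca$Hn, grp, reorder = FALSE) / pk
      dH <- (dHn - m1[grp, , drop = FALSE] - ca$Hn * m2[grp, , drop = FALSE]) /
        ca$sd[grp, , drop = FALSE]
    } else {
      dH <- dHn
    }
    wnm <- paste0("conv", k, "_W")
    grads[[wnm]] <- grads[[wnm]] + crossprod(ca$X, dH)
    grads[[paste0("conv", k, "_b")]] <- grads[[paste0("conv", k, "_b")]] + colSums(dH)
    if (k > 1L) {
      dX <- dH %*% t(net$params[[wnm]])
      dim(dX) <- c(n, pk * 64L * cin)
      dFm <- matrix(0, n, prod(net$plan[[k]]$in_dims) * cin)
      dFm[, net$idx[[k]]] <- dX
    }
  }
  grads
}

# Forward pass over a batch of volumes.  training=TRUE activates dropout and
# batch-statistics normalisation (updating running stats); training=FALSE is
# deterministic. Returns cf plus caches for the backward pass.
ds_forward <- function(net, vols, tracers, training = FALSE, keep_cache = training) {
  p <- net$params
  if (is.matrix(vols)) {
    if (ncol(vols) != prod(net$grid$shape))
      stop(sprintf("volume matrix has %d voxels per row, grid expects %d",
                   ncol(vols), prod(net$grid$shape)))
    V <- vols
  } else {
    for (v in vols) check_grid(v, net$grid)
    V <- do.call(rbind, lapply(vols, as.numeric))
  }
  n <- nrow(V)
  conv <- conv_forward_batch(net, V, keep_cache = keep_cache)
  Z <- cbind(conv$Z, tracer_onehot(tracers))
  fc_cache <- list()
  running <- net$running
  for (st in 1:2) {
    if (training && net$dropout > 0) {
      keep <- 1 - net$dropout
      mask <- matrix(stats::rbinom(length(Z), 1L, keep) / keep, nrow(Z), ncol(Z))
      Zd <- Z * mask
    } else {
      mask <- NULL
      Zd <- Z
    }
    A <- sweep(Zd %*% p[[paste0("fc", st, "_W")]], 2L, p[[paste0("fc", st, "_b")]], `+`)
    if (training) {
      mu <- colMeans(A)
      Ac <- sweep(A, 2L, mu)
      va <- colMeans(Ac * Ac)
      # cumulative moving average: stable after few batches, which matters
      # when an epoch is only one or two optimiser steps
      cnt <- running$count + (st == 1L)
      w <- 1 / min(cnt, 100)
      running$count <- cnt
      running[[paste0("fc", st, "_mean")]] <-
        (1 - w) * running[[paste0("fc", st, "_mean")]] + w * mu
      running[[paste0("fc", st, "_var")]] <-
        (1 - w) * running[[paste0("fc", st, "_var")]] + w * va
    } else {
      mu <- running[[paste0("fc", st, "_mean")]]
      va <- running[[paste0("fc", st, "_var")]]
      Ac <- sweep(A, 2L, mu)
    }
    sd_ <- sqrt(va + NET_EPS)
    xn <- sweep(Ac, 2L, sd_, `/`)
    y <- sweep(sweep(xn, 2L, p[[paste0("fc", st, "_gamma")]], `*`), 2L,
               p[[paste0("fc", st, "_beta")]], `+`)
    Tt <- tanh(y)
    if (keep_cache)
      fc_cache[[st]] <- list(Zd = Zd, mask = mask, xn = xn, sd = sd_, Tt = Tt)
    Z <- Tt
  }
  z <- as.numeric(Z %*% p$head_W) + p$head_b
  sig <- 1 / (1 + exp(-z))
  cf <- 2 * sig
  list(cf = cf, sig = sig, conv = conv, fc_cache = fc_cache, head_in = Z,
       running = running, training = training)
}

# Backward pass: dcf is dLoss/dcf per image; returns gradients for all params.
ds_backward <- function(net, fw, dcf) {
  p <- net$params
  grads <- lapply(p, function(x) array(0, dim = if (is.matrix(x)) dim(x) else length(x)))
  grads <- lapply(grads, function(g) if (length(dim(g)) == 2L) g else as.numeric(g))
  dz <- dcf * 2 * fw$sig * (1 - fw$sig)
  grads$head_W <- crossprod(fw$head_in, dz)
  grads$head_b <- sum(dz)
  dT <- dz %*% t(p$head_W)
  for (st in 2:1) {
    ca <- fw$fc_cache[[st]]
    dy <- dT * (1 - ca$Tt^2)
    grads[[paste0("fc", st, "_gamma")]] <- colSums(dy * ca$xn)
    grads[[paste0("fc", st, "_beta")]] <- colSums(dy)
    dxn <- sweep(dy, 2L, p[[paste0("fc", st, "_gamma")]], `*`)
    if (fw$training) {
      m1 <- colMeans(dxn)
      m2 <- colMeans(dxn * ca$xn)
      dA <- sweep(sweep(dxn, 2L, m1) - sweep(ca$xn, 2L, m2, `*`), 2L, ca$sd, `/`)
    } else {
      dA <- sweep(dxn, 2L, ca$sd, `/`)
    }
    grads[[paste0("fc", st, "_W")]] <- crossprod(ca$Zd, dA)
    grads[[paste0("fc", st, "_b")]] <- colSums(dA)
    dZd <- dA %*% t(p[[paste0("fc", st, "_W")]])
    dT <- if (!is.null(ca$mask)) dZd * ca$mask else dZd
  }
  dfeat <- dT[, seq_len(net$feat_dim), drop = FALSE]
  conv_backward_batch(net, fw$conv$caches, dfeat, grads)
}

adam_init <- function(params) {
  list(m = lapply(params, function(x) x * 0), v = lapply(params, function(x) x * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Predict a correction factor for a single scan
#'
#' Deterministic single-image inference: the network in evaluation mode maps
#' an SUVR-normalised volume plus its tracer code to a correction factor in
#' `[0, 2]`.
#'
#' @param model A trained `ds_network` or a fitted [deepsuvr()] object.
#' @param volume SUVR-normalised 3D array on the model's grid.
#' @param tracer Tracer code.
#' @return Scalar correction factor.
#' @export
predict_cf <- function(model, volume, tracer) {
  net <- if (inherits(model, "deepsuvr")) model$network else model
  stopifnot(inherits(net, "ds_network"))
  ds_forward(net, list(volume), tracer, training = FALSE, keep_cache = FALSE)$cf
}

#' Correct one or more scans
#'
#' Computes the standard SUVR from the mask pair, the network's correction
#' factor, the corrected SUVR `cf * suvr` and its Centiloid value.
#'
#' @param scans A [scan_record()] or list of them (volumes loaded; raw, not
#'   yet SUVR-normalised unless flagged).
#' @param masks Standard [mask_pair()] used for SUVR and for the reference
#'   normalisation of the network input.
#' @param transforms [centiloid_transforms()] table.
#' @param model Trained `ds_network` or [deepsuvr()] fit.
#' @return data.frame with standard_suvr, cf, corrected_suvr, corrected_cl
#'   (rows in input order).
#' @export
correct_scan <- function(scans, masks, transforms, model) {
  if (inherits(scans, "scan_record")) scans <- list(scans)
  net <- if (inherits(model, "deepsuvr")) model$network else model
  suvr <- vapply(scans, function(s) compute_suvr(s$volume, masks), 0)
  vols <- lapply(scans, function(s)
    if (isTRUE(s$is_suvr_normalised)) s$volume else suvr_normalise(s$volume, masks$reference))
  tr <- vapply(scans, function(s) s$tracer, "")
  cf <- ds_forward(net, vols, tr, training = FALSE, keep_cache = FALSE)$cf
  corr <- apply_correction(suvr, cf)
  data.frame(participant_id = vapply(scans, function(s) s$participant_id, ""),
             tracer = tr, standard_suvr = suvr, cf = cf, corrected_suvr = corr,
             corrected_cl = suvr_to_centiloid(corr, tr, transforms),
             stringsAsFactors = FALSE)
}

#' Save / load a trained network
#'
#' The checkpoint is an RDS file of the weights accompanied by a JSON sidecar
#' recording the architecture, grid, seed and any training configuration.
#'
#' @param net A `ds_network`.
#' @param path Checkpoint path (`.rds`); the sidecar is `<path>.json`.
#' @param config Optional training configuration to record.
#' @export
write_model <- function(net, path, config = NULL) {
  saveRDS(net, path)
  side <- list(grid = list(shape = net$grid$shape, voxel_size_mm = net$grid$voxel_size_mm),
               conv_channels = net$channels, hidden = net$hidden,
               leaky = net$leaky, seed = net$seed, config = config)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) readRDS(path)
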