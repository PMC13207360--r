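# Hybrid convolutional-recurrent neurostate decoder.
#
# The map variant applies a shared three-stage 2-D convolutional encoder
# (16/32/64 filters, 3x3 kernels, same padding, 2x2 pooling after the first
# two stages: 32 -> 16 -> 8 spatial trace, 4096-long flattened feature per
# step) to each of K = 10 consecutive spectral-topographic map stacks, feeds
# the per-step features to an LSTM with 64 hidden units, and ends in two
# heads: a 3-way softmax over CA/DA/SU and a 1-unit sigmoid for the
# continuous cognitive load index. Training optimizes cross-entropy plus
# weighted MSE with Adam. Comparison variants keep the recurrent trunk:
# RAW uses a 1-D convolutional encoder over channel-wise windows, SPECTRAL a
# dense encoder over 43 spectral features (14 channels x 3 bands + FAA).

#' Decoder configuration
#'
#' @param conv_filters widths of the three convolutional stages.
#' @param hidden recurrent hidden size.
#' @param spatial_dropout,temporal_dropout dropout rates.
#' @param lr,weight_decay Adam learning rate and weight decay.
#' @param mse_weight weight of the CLI regression loss against cross-entropy.
#' @param batch_size,max_epochs,patience training loop controls (early
#'   stopping on validation loss).
#' @param K sequence length in windows.
#' @param seed integer seed for initialization, shuffling and dropout.
#' @return list of class `tg_decoder_config`.
#' @export
decoder_config <- function(conv_filters = c(16L, 32L, 64L), hidden = 64L,
                           spatial_dropout = 0.25, temporal_dropout = 0.3,
                           lr = 1e-4, weight_decay = 1e-5, mse_weight = 1,
                           batch_size = 24L, max_epochs = 30L, patience = 10L,
                           K = 10L, seed = 1L) {
  stopifnot(all(conv_filters > 0), spatial_dropout >= 0, spatial_dropout < 1,
            temporal_dropout >= 0, temporal_dropout < 1)
  structure(list(conv_filters = conv_filters, hidden = hidden,
                 spatial_dropout = spatial_dropout,
                 temporal_dropout = temporal_dropout, lr = lr,
                 weight_decay = weight_decay, mse_weight = mse_weight,
                 batch_size = batch_size, max_epochs = max_epochs,
                 patience = patience, K = K, seed = as.integer(seed)),
            class = "tg_decoder_config")
}

#' Chronological train/validation/test split
#'
#' Earliest 70% of windows for training, next 10% for validation, final
#' continuous 20% for test; order is preserved and windows are never
#' shuffled across the boundaries (boundaries at `floor(0.7 n)` and
#' `floor(0.8 n)`, remainder to test).
#'
#' @param n_windows number of chronologically ordered items.
#' @return list of class `tg_chrono_split` with integer index vectors
#'   `train`, `val`, `test`.
#' @export
chronological_split <- function(n_windows) {
  if (n_windows < 10) tg_stop("chronological_split: need at least 10 windows")
  b1 <- floor(0.7 * n_windows)
  b2 <- floor(0.8 * n_windows)
  structure(list(train = seq_len(b1), val = (b1 + 1L):b2,
                 test = (b2 + 1L):n_windows),
            class = "tg_chrono_split")
}

#' Build an untrained decoder
#'
#' @param config a [decoder_config()].
#' @param variant `"MAPS"` (32x32x4 map sequences), `"SPECTRAL"` (43-feature
#'   vectors), or `"RAW"` (channel x time windows).
#' @param input_shape for MAPS `c(32, 32, 4)`, for RAW `c(channels, samples)`,
#'   ignored for SPECTRAL.
#' @return object of class `tg_decoder` with freshly initialized weights
#'   (deterministic under the config seed).
#' @export
build_decoder <- function(config, variant = c("MAPS", "SPECTRAL", "RAW"),
                          input_shape = c(32L, 32L, 4L)) {
  stopifnot(inherits(config, "tg_decoder_config"))
  variant <- match.arg(variant)
  set.seed(config$seed)
  h <- config$hidden
  cf <- config$conv_filters
  if (variant == "MAPS") {
    if (length(input_shape) != 3 || input_shape[1] != input_shape[2]) {
      tg_stop("build_decoder: MAPS input must be square (H, H, B)")
    }
    H <- input_shape[1]; B <- input_shape[3]
    if (H %% 4 != 0) tg_stop("build_decoder: map side must be divisible by 4")
    d_feat <- (H %/% 4)^2 * cf[3]
    params <- list(
      W1 = matrix(glorot(9 * B, cf[1], c(cf[1], 9 * B)), cf[1], 9 * B),
      b1 = numeric(cf[1]),
      W2 = matrix(glorot(9 * cf[1], cf[2], c(cf[2], 9 * cf[1])), cf[2], 9 * cf[1]),
      b2 = numeric(cf[2]),
      W3 = matrix(glorot(9 * cf[2], cf[3], c(cf[3], 9 * cf[2])), cf[3], 9 * cf[2]),
      b3 = numeric(cf[3]))
    dims <- list(H = H, B = B, d_feat = d_feat)
  } else if (variant == "SPECTRAL") {
    d_in <- 43L
    d_feat <- 64L
    params <- list(Wd = glorot(d_in, d_feat), bd = numeric(d_feat))
    dims <- list(d_in = d_in, d_feat = d_feat)
  } else {
    Cc <- input_shape[1]; T_ <- input_shape[2]
    if (T_ %% 16 != 0) tg_stop("build_decoder: RAW window length must be divisible by 16")
    params <- list(
      V1 = matrix(glorot(7 * Cc, cf[1], c(cf[1], 7 * Cc)), cf[1], 7 * Cc),
      c1 = numeric(cf[1]),
      V2 = matrix(glorot(5 * cf[1], cf[2], c(cf[2], 5 * cf[1])), cf[2], 5 * cf[1]),
      c2 = numeric(cf[2]))
    d_feat <- (T_ %/% 16) * cf[2]
    dims <- list(C = Cc, T_ = T_, d_feat = d_feat)
  }
  params$lstm <- NULL
  lstm <- lstm_init(d_feat, h)
  params$Wx <- lstm$Wx; params$Wh <- lstm$Wh; params$bl <- lstm$b
  params$Wc <- glorot(h, 3); params$bc <- numeric(3)
  params$Wr <- glorot(h, 1); params$br <- numeric(1)
  structure(list(variant = variant, config = config, params = params,
                 dims = dims, scaler = NULL, trained = FALSE),
            class = "tg_decoder")
}

#' Number of trainable decoder parameters
#' @param net a `tg_decoder`.
#' @return integer parameter count.
#' @export
n_decoder_params <- function(net) {
  sum(vapply(net$params, length, 0L))
}

# shared LSTM + heads forward; feat [d_feat, K*N] sequence-major columns
decoder_head_fwd <- function(net, feat, N, train, drop_temporal) {
  K <- net$config$K
  h <- net$config$hidden
  Xk <- lapply(seq_len(K), function(k) t(feat[, (0:(N - 1)) * K + k, drop = FALSE]))
  lf <- lstm_fwd(Xk, list(Wx = net$params$Wx, Wh = net$params$Wh, b = net$params$bl))
  Hl <- lf$out
  tmask <- NULL
  if (train && drop_temporal > 0) {
    tmask <- matrix(runif(length(Hl)) >= drop_temporal, nrow(Hl), ncol(Hl)) /
      (1 - drop_temporal)
    Hl <- Hl * tmask
  }
  logits <- Hl %*% net$params$Wc + matrix(net$params$bc, N, 3, byrow = TRUE)
  probs <- softmax_rows(logits)
  z <- as.vector(Hl %*% net$params$Wr) + as.numeric(net$params$br)
  cli <- sigmoid(z)
  list(probs = probs, cli = cli, Hl = Hl, lf = lf, tmask = tmask)
}

decoder_head_bwd <- function(net, hc, dlogits, dz, N) {
  gr <- list()
  gr$Wc <- crossprod(hc$Hl, dlogits)
  gr$bc <- colSums(dlogits)
  gr$Wr <- crossprod(hc$Hl, matrix(dz, ncol = 1))
  gr$br <- sum(dz)
  dH <- dlogits %*% t(net$params$Wc) + outer(dz, as.vector(net$params$Wr))
  if (!is.null(hc$tmask)) dH <- dH * hc$tmask
  lb <- lstm_bwd(dH, hc$lf, list(Wx = net$params$Wx, Wh = net$params$Wh,
                                 b = net$params$bl))
  gr$Wx <- lb$dWx; gr$Wh <- lb$dWh; gr$bl <- lb$db
  K <- net$config$K
  dfeat <- matrix(0, nrow(net$params$Wx), K * N)
  for (k in seq_len(K)) dfeat[, (0:(N - 1)) * K + k] <- t(lb$dX[[k]])
  list(grads = gr, dfeat = dfeat)
}

# full forward; X columns are maps/windows in sequence-major order (for each
# sequence its K steps are consecutive columns)
decoder_fwd <- function(net, X, N, train = FALSE) {
  p <- net$params
  cfg <- net$config
  caches <- list()
  if (net$variant == "MAPS") {
    H <- net$dims$H; B <- net$dims$B
    cf <- cfg$conv_filters
    c1 <- conv2_fwd(X, p$W1, p$b1, H, H, B)
    r1 <- nn_relu_fwd(c1$out)
    p1 <- cpp_maxpool2(r1$out, H, H, cf[1])
    H2 <- H %/% 2
    c2 <- conv2_fwd(p1$out, p$W2, p$b2, H2, H2, cf[1])
    r2 <- nn_relu_fwd(c2$out)
    p2 <- cpp_maxpool2(r2$out, H2, H2, cf[2])
    H3 <- H %/% 4
    c3 <- conv2_fwd(p2$out, p$W3, p$b3, H3, H3, cf[2])
    r3 <- nn_relu_fwd(c3$out)
    feat <- r3$out
    smask <- NULL
    if (train && cfg$spatial_dropout > 0) {
      m <- matrix(runif(cf[3] * ncol(feat)) >= cfg$spatial_dropout,
                  cf[3], ncol(feat)) / (1 - cfg$spatial_dropout)
      smask <- m[rep(seq_len(cf[3]), each = H3 * H3), , drop = FALSE]
      feat <- feat * smask
    }
    caches <- list(c1 = c1, r1 = r1, p1 = p1, c2 = c2, r2 = r2, p2 = p2,
                   c3 = c3, r3 = r3, smask = smask)
  } else if (net$variant == "SPECTRAL") {
    d1 <- p$Wd
    lin <- crossprod(d1, X) + p$bd           # [64, K*N]
    r1 <- nn_relu_fwd(lin)
    feat <- r1$out
    smask <- NULL
    if (train && cfg$spatial_dropout > 0) {
      smask <- matrix(runif(length(feat)) >= cfg$spatial_dropout,
                      nrow(feat), ncol(feat)) / (1 - cfg$spatial_dropout)
      feat <- feat * smask
    }
    caches <- list(X = X, r1 = r1, smask = smask)
  } else {
    T_ <- net$dims$T_; Cc <- net$dims$C
    cf <- cfg$conv_filters
    c1 <- conv1_fwd(X, p$V1, p$c1, T_, Cc, 7L)
    r1 <- nn_relu_fwd(c1$out)
    p1 <- pool1_fwd(r1$out, T_, cf[1], 4L)
    T2 <- T_ %/% 4
    c2 <- conv1_fwd(p1$out, p$V2, p$c2, T2, cf[1], 5L)
    r2 <- nn_relu_fwd(c2$out)
    p2 <- pool1_fwd(r2$out, T2, cf[2], 4L)
    feat <- p2$out
    smask <- NULL
    if (train && cfg$spatial_dropout > 0) {
      smask <- matrix(runif(length(feat)) >= cfg$spatial_dropout,
                      nrow(feat), ncol(feat)) / (1 - cfg$spatial_dropout)
      feat <- feat * smask
    }
    caches <- list(c1 = c1, r1 = r1, p1 = p1, c2 = c2, r2 = r2, p2 = p2,
                   smask = smask)
  }
  hc <- decoder_head_fwd(net, feat, N, train, cfg$temporal_dropout)
  c(list(feat = feat, hc = hc), caches)
}

decoder_bwd <- function(net, fw, X, N, dlogits, dz) {
  hb <- decoder_head_bwd(net, fw$hc, dlogits, dz, N)
  gr <- hb$grads
  dfeat <- hb$dfeat
  cfg <- net$config
  p <- net$params
  if (!is.null(fw$smask)) dfeat <- dfeat * fw$smask
  if (net$variant == "MAPS") {
    H <- net$dims$H; B <- net$dims$B; cf <- cfg$conv_filters
    H2 <- H %/% 2; H3 <- H %/% 4
    KN <- ncol(X)
    d3 <- nn_relu_bwd(dfeat, fw$r3)
    cb3 <- conv2_bwd(d3, fw$c3, p$W3, H3, H3, cf[2], KN)
    gr$W3 <- cb3$dW; gr$b3 <- cb3$db
    dp2 <- cpp_maxpool2_bwd(cb3$dX, fw$p2$idx, H2 * H2 * cf[2])
    d2 <- nn_relu_bwd(dp2, fw$r2)
    cb2 <- conv2_bwd(d2, fw$c2, p$W2, H2, H2, cf[1], KN)
    gr$W2 <- cb2$dW; gr$b2 <- cb2$db
    dp1 <- cpp_maxpool2_bwd(cb2$dX, fw$p1$idx, H * H * cf[1])
    d1 <- nn_relu_bwd(dp1, fw$r1)
    cb1 <- conv2_bwd(d1, fw$c1, p$W1, H, H, B, KN)
    gr$W1 <- cb1$dW; gr$b1 <- cb1$db
  } else if (net$variant == "SPECTRAL") {
    dlin <- nn_relu_bwd(dfeat, fw$r1)
    gr$Wd <- tcrossprod(fw$X, dlin)      # X %*% t(dlin): [d_in, 64]
    gr$bd <- rowSums(dlin)
  } else {
    T_ <- net$dims$T_; Cc <- net$dims$C; cf <- cfg$conv_filters
    T2 <- T_ %/% 4
    KN <- ncol(X)
    dp2 <- pool1_bwd(dfeat, fw$p2)
    d2 <- nn_relu_bwd(dp2, fw$r2)
    cb2 <- conv1_bwd(d2, fw$c2, p$V2, T2, cf[1], 5L, KN)
    gr$V2 <- cb2$dW; gr$c2 <- cb2$db
    dp1 <- pool1_bwd(cb2$dX, fw$p1)
    d1 <- nn_relu_bwd(dp1, fw$r1)
    cb1 <- conv1_bwd(d1, fw$c1, p$V1, T_, Cc, 7L, KN)
    gr$V1 <- cb1$dW; gr$c1 <- cb1$db
  }
  gr
}

scale_input <- function(net, X) {
  if (is.null(net$scaler)) return(X)
  (X - net$scaler$mean) / net$scaler$sd
}

#' Train a decoder on labeled sequences
#'
#' Joint loss: categorical cross-entropy on the class head plus weighted MSE
#' on the CLI head (CLI targets in synthetic use are the ground-truth latent
#' load). Early stopping monitors validation loss. Deterministic under the
#' config seed.
#'
#' @param net an untrained [build_decoder()].
#' @param data list with `X` (input columns, sequence-major: the K steps of
#'   each sequence are consecutive), `y` (integer class 1..3 per sequence),
#'   `cli` (regression target in \[0,1\] per sequence).
#' @param split a [chronological_split()] over sequences.
#' @return net with trained weights and a `history` data.frame.
#' @export
train_decoder <- function(net, data, split) {
  stopifnot(inherits(net, "tg_decoder"), inherits(split, "tg_chrono_split"))
  cfg <- net$config
  K <- cfg$K
  y <- data$y
  miss <- setdiff(1:3, unique(y[split$train]))
  if (length(miss)) {
    tg_stop("train_decoder: class(es) absent from the training block: ",
            paste(NEUROSTATES[miss], collapse = ", "))
  }
  seq_cols <- function(idx) as.vector(outer(seq_len(K), (idx - 1L) * K, "+"))
  # input scaler from the training block only (no temporal leakage)
  tr_cols <- seq_cols(split$train)
  mu <- mean(data$X[, tr_cols])
  sdv <- sd(data$X[, tr_cols])
  net$scaler <- list(mean = mu, sd = max(sdv, 1e-8))
  Xall <- scale_input(net, data$X)
  set.seed(cfg$seed + 1L)
  ad <- adam_init(net$params)
  best <- list(loss = Inf, params = net$params, epoch = 0L)
  hist <- NULL
  eval_split <- function(idx) {
    # chunked evaluation keeps peak memory bounded
    probs <- NULL; clis <- NULL
    for (i in seq(1, length(idx), by = 64L)) {
      sub <- idx[i:min(length(idx), i + 63L)]
      fw <- decoder_fwd(net, Xall[, seq_cols(sub), drop = FALSE], length(sub), FALSE)
      probs <- rbind(probs, fw$hc$probs)
      clis <- c(clis, fw$hc$cli)
    }
    ce <- -mean(log(pmax(probs[cbind(seq_along(idx), y[idx])], 1e-12)))
    mse <- mean((clis - data$cli[idx])^2)
    acc <- mean(max.col(probs) == y[idx])
    c(loss = ce + cfg$mse_weight * mse, acc = acc)
  }
  wait <- 0L
  for (ep in seq_len(cfg$max_epochs)) {
    ord <- sample(split$train)
    bs <- cfg$batch_size
    tr_loss <- c(); tr_acc <- c()
    for (i in seq(1, length(ord), by = bs)) {
      idx <- ord[i:min(length(ord), i + bs - 1L)]
      N <- length(idx)
      Xb <- Xall[, seq_cols(idx), drop = FALSE]
      fw <- decoder_fwd(net, Xb, N, train = TRUE)
      oh <- matrix(0, N, 3); oh[cbind(seq_len(N), y[idx])] <- 1
      dlogits <- (fw$hc$probs - oh) / N
      cl <- fw$hc$cli
      dz <- cfg$mse_weight * 2 * (cl - data$cli[idx]) * cl * (1 - cl) / N
      gr <- decoder_bwd(net, fw, Xb, N, dlogits, dz)
      upd <- adam_step(net$params, gr[names(net$params)], ad,
                       lr = cfg$lr, weight_decay = cfg$weight_decay)
      net$params <- upd$params
      ad <- upd$state
      tr_loss <- c(tr_loss, -mean(log(pmax(fw$hc$probs[cbind(seq_len(N), y[idx])], 1e-12))) +
                     cfg$mse_weight * mean((cl - data$cli[idx])^2))
      tr_acc <- c(tr_acc, mean(max.col(fw$hc$probs) == y[idx]))
    }
    vam <- eval_split(split$val)
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = mean(tr_loss),
                                   train_acc = mean(tr_acc), val_loss = vam["loss"],
                                   val_acc = vam["acc"], row.names = NULL))
    if (vam["loss"] < best$loss - 1e-6) {
      best <- list(loss = vam["loss"], params = net$params, epoch = ep)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= cfg$patience) break
    }
  }
  net$params <- best$params
  net$trained <- TRUE
  net$history <- hist
  net
}

#' Decode a batch of sequences
#'
#' @param net a trained `tg_decoder`.
#' @param X input columns (sequence-major, as in [train_decoder()]).
#' @param n number of sequences in `X`.
#' @return list with `probs` (n x 3, rows on the simplex), `labels`
#'   (CA/DA/SU), `cli` (length-n vector in \[0,1\]).
#' @export
predict_decoder <- function(net, X, n = ncol(X) / net$config$K) {
  K <- net$config$K
  Xs <- scale_input(net, X)
  probs <- NULL; clis <- NULL
  for (i in seq(1, n, by = 128L)) {
    j <- min(n, i + 127L)
    cols <- ((i - 1) * K + 1):(j * K)
    fw <- decoder_fwd(net, Xs[, cols, drop = FALSE], j - i + 1L, train = FALSE)
    probs <- rbind(probs, fw$hc$probs)
    clis <- c(clis, fw$hc$cli)
  }
  list(probs = probs, labels = NEUROSTATES[max.col(probs)], cli = clis)
}

#' Decoder classification metrics
#'
#' Balanced accuracy is the mean of per-class recalls; macro-F1 the
#' unweighted mean of per-class F1. The confusion matrix is row-normalized
#' (rows = truth). Classes absent from the truth are excluded from the
#' averages with a warning.
#'
#' @param pred predicted labels (CA/DA/SU) or a [predict_decoder()] result.
#' @param truth true labels.
#' @return list with `accuracy`, `balanced_accuracy`, `macro_f1`, `recall`,
#'   `confusion`.
#' @export
evaluate_decoder <- function(pred, truth) {
  if (is.list(pred)) pred <- pred$labels
  stopifnot(length(pred) == length(truth))
  lv <- NEUROSTATES
  cm <- table(factor(truth, lv), factor(pred, lv))
  present <- rowSums(cm) > 0
  if (!all(present)) {
    warning("evaluate_decoder: class(es) absent from truth, excluded: ",
            paste(lv[!present], collapse = ", "))
  }
  recall <- ifelse(rowSums(cm) > 0, diag(cm) / rowSums(cm), NA_real_)
  prec <- ifelse(colSums(cm) > 0, diag(cm) / colSums(cm), NA_real_)
  f1 <- ifelse(is.na(recall) | is.na(prec) | (prec + recall) == 0, NA_real_,
               2 * prec * recall / (prec + recall))
  f1[present & is.na(f1)] <- 0  # present class never predicted correctly
  cmn <- cm / pmax(rowSums(cm), 1)
  list(accuracy = mean(pred == truth),
       balanced_accuracy = mean(recall[present]),
       macro_f1 = mean(f1[present]),
       recall = stats::setNames(as.numeric(recall), lv),
       confusion = matrix(as.numeric(cmn), 3, 3, dimnames = list(lv, lv)))
}

#' Temporal stability of consecutive decoder outputs
#'
#' @param outputs list/data.frame with `labels` and `cli` in chronological
#'   order (at least 2 entries).
#' @return list with `adjacent_agreement` (fraction of consecutive equal
#'   labels) and `median_dcli` (median absolute CLI step).
#' @export
temporal_stability <- function(outputs) {
  lb <- outputs$labels
  cli <- outputs$cli
  if (length(lb) < 2) tg_stop("temporal_stability: need at least 2 outputs")
  list(adjacent_agreement = mean(lb[-1] == lb[-length(lb)]),
       median_dcli = median(abs(diff(cli))))
}

# --- dataset construction from sessions ----------------------------------

#' Extract decoder features from a session through the full pipeline
#'
#' Band-pass + notch + ASR + windowing + per-window normalization, then
#' Welch band powers, spectral-topographic maps, and alignment with the
#' ground-truth latent trace.
#'
#' @param session a [generate_session()] bundle with EEG.
#' @param asr_cutoff ASR cutoff (`Inf` disables).
#' @param keep_raw also keep the normalized raw windows (needed for the RAW
#'   representation variant).
#' @return list of class `tg_session_features`.
#' @export
session_features <- function(session, asr_cutoff = 10, keep_raw = FALSE) {
  stopifnot(inherits(session, "tg_session"), !is.null(session$eeg))
  cfg <- session$config
  fs <- session$sample_rate
  x <- bandpass_filter(session$eeg, fs)
  x <- notch_filter(x, fs)
  if (is.finite(asr_cutoff) && cfg$warmup_s >= 30) {
    wu <- x[, seq_len(as.integer(cfg$warmup_s * fs)), drop = FALSE]
    x <- asr_apply(asr_fit(wu, fs, cutoff = asr_cutoff), x)
  }
  starts <- window_start_times(total_duration(cfg))
  bp <- session_band_powers(x, fs, starts, session$channel_names,
                            normalize = TRUE)
  interp <- fit_topo_interpolator(electrode_layout())
  maps <- session_map_array(bp, interp)
  lat <- session$latent
  idx <- match(round(starts, 6), round(lat$start_s, 6))
  raw <- NULL
  if (keep_raw) {
    wlen <- as.integer(fs)
    s0 <- round(starts * fs)
    raw <- matrix(0, wlen * nrow(x), length(starts))
    for (i in seq_along(starts)) {
      w <- x[, (s0[i] + 1L):(s0[i] + wlen), drop = FALSE]
      mu <- rowMeans(w); sdv <- apply(w, 1, sd)
      sdv[sdv < .Machine$double.eps] <- Inf
      raw[, i] <- as.vector(t((w - mu) / sdv))  # t + T*c layout
    }
  }
  structure(list(starts = starts, bp = bp, maps = maps, raw = raw,
                 class = lat$class[idx], load = lat$load[idx],
                 phase = lat$phase[idx], n_channels = nrow(x),
                 sample_rate = fs),
            class = "tg_session_features")
}

#' Build decoder input for a representation variant
#'
#' RAW: normalized channel-wise windows to the 1-D-conv recurrent variant;
#' SPECTRAL: 43-vectors (14 channels x 3 bands log-power + FAA) to the dense
#' recurrent variant; MAPS: the spectral-topographic map stacks.
#'
#' @param variant `"MAPS"`, `"SPECTRAL"` or `"RAW"`.
#' @param feats a [session_features()] result (or list of them).
#' @param seq_stride sequence-start stride in windows (subsampling).
#' @param K sequence length.
#' @param task_only drop sequences whose final window is in the warm-up.
#' @return list with `X` (columns sequence-major), `y`, `cli`, `t0`,
#'   `input_shape`.
#' @export
build_representation <- function(variant = c("MAPS", "SPECTRAL", "RAW"), feats,
                                 seq_stride = 1L, K = 10L, task_only = TRUE) {
  variant <- match.arg(variant)
  if (inherits(feats, "tg_session_features")) feats <- list(feats)
  Xs <- list(); ys <- list(); clis <- list(); t0s <- list()
  shape <- NULL
  for (f in feats) {
    nwin <- length(f$starts)
    starts_i <- seq(1L, nwin - K + 1L, by = seq_stride)
    lab_i <- starts_i + K - 1L          # label/CLI anchored at the final window
    if (task_only) {
      keep <- f$phase[lab_i] == "task"
      starts_i <- starts_i[keep]; lab_i <- lab_i[keep]
    }
    if (!length(starts_i)) next
    win_cols <- as.vector(outer(0:(K - 1L), starts_i, "+")) + 0L
    if (variant == "MAPS") {
      gn <- dim(f$maps)[1]
      X <- matrix(f$maps[, , , win_cols, drop = FALSE], gn * gn * 4,
                  length(win_cols))
      shape <- c(gn, gn, 4L)
    } else if (variant == "SPECTRAL") {
      fe <- rbind(t(log10(pmax(f$bp$theta, .Machine$double.xmin))),
                  t(log10(pmax(f$bp$alpha, .Machine$double.xmin))),
                  t(log10(pmax(f$bp$beta, .Machine$double.xmin))),
                  f$bp$faa)               # 43 x nwin
      X <- fe[, win_cols, drop = FALSE]
      shape <- c(43L)
    } else {
      if (is.null(f$raw)) tg_stop("build_representation: RAW needs keep_raw = TRUE features")
      X <- f$raw[, win_cols, drop = FALSE]
      shape <- c(f$n_channels, as.integer(f$sample_rate))
    }
    Xs[[length(Xs) + 1L]] <- X
    ys[[length(ys) + 1L]] <- match(f$class[lab_i], NEUROSTATES)
    clis[[length(clis) + 1L]] <- f$load[lab_i]
    t0s[[length(t0s) + 1L]] <- f$starts[starts_i]
  }
  list(X = do.call(cbind, Xs), y = unlist(ys), cli = unlist(clis),
       t0 = unlist(t0s), input_shape = shape)
}
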