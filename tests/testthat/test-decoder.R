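test_that("chronological split uses floor boundaries and preserves order", {
  sp <- chronological_split(100)
  expect_length(sp$train, 70); expect_length(sp$val, 10); expect_length(sp$test, 20)
  sp2 <- chronological_split(101)
  expect_length(sp2$train, 70); expect_length(sp2$val, 10); expect_length(sp2$test, 21)
  expect_equal(c(sp$train, sp$val, sp$test), 1:100)
  expect_error(chronological_split(9), "at least 10")
})

test_that("decoder outputs live on the simplex with the documented parameter count", {
  cfg <- decoder_config(seed = 3)
  net <- build_decoder(cfg, "MAPS")
  # 592 + 4640 + 18496 conv; 1,065,216 LSTM; 195 + 65 heads
  expect_equal(n_decoder_params(net), 1089204L)
  set.seed(3)
  X <- matrix(rnorm(4096 * 10 * 4), 4096, 40)
  fw <- topogate:::decoder_fwd(net, X, 4, train = FALSE)
  expect_equal(rowSums(fw$hc$probs), rep(1, 4), tolerance = 1e-6)
  expect_true(all(fw$hc$probs >= 0))
  expect_true(all(fw$hc$cli >= 0 & fw$hc$cli <= 1))
  # identical seeds give identical initial weights
  net2 <- build_decoder(decoder_config(seed = 3), "MAPS")
  expect_identical(net$params, net2$params)
  expect_error(build_decoder(cfg, "MAPS", c(32, 16, 4)), "square")
})

test_that("analytic gradients agree with numerical differentiation", {
  for (variant in c("MAPS", "SPECTRAL", "RAW")) {
    K <- 3L; N <- 3L
    cfg <- decoder_config(K = K, spatial_dropout = 0, temporal_dropout = 0,
                          seed = 7, conv_filters = c(3L, 4L, 5L))
    shape <- switch(variant, MAPS = c(8L, 8L, 2L), SPECTRAL = NULL,
                    RAW = c(3L, 32L))
    net <- build_decoder(cfg, variant, shape)
    d <- switch(variant, MAPS = 128, SPECTRAL = 43, RAW = 96)
    set.seed(99)
    X <- matrix(rnorm(d * K * N), d, K * N)
    y <- sample(1:3, N, TRUE); cli <- runif(N)
    loss_fn <- function(params) {
      net$params <- params
      fw <- topogate:::decoder_fwd(net, X, N, FALSE)
      -mean(log(pmax(fw$hc$probs[cbind(1:N, y)], 1e-12))) +
        mean((fw$hc$cli - cli)^2)
    }
    fw <- topogate:::decoder_fwd(net, X, N, FALSE)
    oh <- matrix(0, N, 3); oh[cbind(1:N, y)] <- 1
    gr <- topogate:::decoder_bwd(net, fw, X, N, (fw$hc$probs - oh) / N,
                                 2 * (fw$hc$cli - cli) * fw$hc$cli *
                                   (1 - fw$hc$cli) / N)
    for (nm in names(net$params)) {
      p <- net$params[[nm]]
      for (j in sample(length(p), min(3, length(p)))) {
        eps <- 1e-5
        pp <- net$params; pp[[nm]][j] <- pp[[nm]][j] + eps
        pm <- net$params; pm[[nm]][j] <- pm[[nm]][j] - eps
        num <- (loss_fn(pp) - loss_fn(pm)) / (2 * eps)
        expect_equal(gr[[nm]][j], num, tolerance = 1e-4,
                     label = paste(variant, nm, "grad"))
      }
    }
  }
})

test_that("representation builders give the documented shapes", {
  ses <- generate_session(session_config(seed = 21, duration_s = 40,
                                         warmup_s = 30))
  f <- session_features(ses, keep_raw = TRUE)
  maps <- build_representation("MAPS", f, seq_stride = 10L, task_only = FALSE)
  expect_equal(maps$input_shape, c(32L, 32L, 4L))
  expect_equal(nrow(maps$X), 4096)
  expect_equal(ncol(maps$X), 10 * length(maps$y))
  spec <- build_representation("SPECTRAL", f, seq_stride = 10L, task_only = FALSE)
  expect_equal(nrow(spec$X), 43)          # 14 channels x 3 bands + FAA
  raw <- build_representation("RAW", f, seq_stride = 10L, task_only = FALSE)
  expect_equal(raw$input_shape, c(14L, 256L))
  expect_equal(nrow(raw$X), 14 * 256)
  expect_true(all(maps$y %in% 1:3))
  expect_true(all(maps$cli >= 0 & maps$cli <= 1))
  expect_error(build_representation("RAW", session_features(ses)), "keep_raw")
})

test_that("training is deterministic, overfits a tiny set, and guards labels", {
  set.seed(31)
  # synthetic separable toy inputs through the SPECTRAL variant (cheap)
  N <- 60; K <- 10
  y <- rep(1:3, length.out = N)
  X <- matrix(rnorm(43 * K * N, sd = 0.3), 43, K * N)
  for (i in seq_len(N)) {
    cols <- ((i - 1) * K + 1):(i * K)
    X[y[i], cols] <- X[y[i], cols] + 3   # class-coded feature bump
  }
  data <- list(X = X, y = y, cli = runif(N))
  split <- chronological_split(N)
  cfg <- decoder_config(seed = 5, lr = 1e-2, max_epochs = 40, patience = 40,
                        batch_size = 16L, spatial_dropout = 0,
                        temporal_dropout = 0)
  net <- train_decoder(build_decoder(cfg, "SPECTRAL"), data, split)
  expect_gte(tail(net$history$train_acc, 1), 0.98)
  net2 <- train_decoder(build_decoder(cfg, "SPECTRAL"), data, split)
  expect_identical(net$params, net2$params)
  # a class missing from the training block is refused
  bad <- data; bad$y[split$train] <- 1L
  expect_error(train_decoder(build_decoder(cfg, "SPECTRAL"), bad, split),
               "absent")
})

test_that("shuffling test labels collapses test accuracy to chance", {
  set.seed(32)
  N <- 90; K <- 10
  y <- rep(1:3, length.out = N)
  X <- matrix(rnorm(43 * K * N, sd = 0.3), 43, K * N)
  for (i in seq_len(N)) {
    cols <- ((i - 1) * K + 1):(i * K)
    X[y[i], cols] <- X[y[i], cols] + 3
  }
  data <- list(X = X, y = y, cli = runif(N))
  split <- chronological_split(N)
  cfg <- decoder_config(seed = 6, lr = 1e-2, max_epochs = 30, patience = 30,
                        batch_size = 16L, spatial_dropout = 0,
                        temporal_dropout = 0)
  net <- train_decoder(build_decoder(cfg, "SPECTRAL"), data, split)
  K10 <- function(idx) as.vector(outer(1:K, (idx - 1L) * K, "+"))
  pr <- predict_decoder(net, data$X[, K10(split$test)], length(split$test))
  acc_true <- mean(pr$labels == NEUROSTATES[data$y[split$test]])
  expect_gt(acc_true, 0.9)
  set.seed(1)
  accs <- replicate(40, {
    mean(pr$labels == NEUROSTATES[sample(data$y[split$test])])
  })
  expect_lt(abs(mean(accs) - 1 / 3), 0.05)
})
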