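test_that("windowing follows the 1 s / 100 ms grid with no partial windows", {
  eeg <- matrix(rnorm(2 * 2560), 2, dimnames = list(c("F3", "F4"), NULL))
  w <- segment_windows(eeg, 256)
  expect_length(w, 91)                      # floor((10-1)/0.1)+1
  expect_equal(w[[1]]$start_time_s, 0)
  expect_equal(ncol(w[[5]]$samples), 256)
  w1 <- segment_windows(eeg[, 1:256, drop = FALSE], 256)
  expect_length(w1, 1)
  expect_warning(w0 <- segment_windows(eeg[, 1:128, drop = FALSE], 256),
                 "shorter")
  expect_length(w0, 0)
})

test_that("band-pass passes 10 Hz within 2% and suppresses slow drift by 20 dB", {
  fs <- 256
  tt <- (0:(30 * fs - 1)) / fs
  mid <- 3000:5000
  y10 <- as.vector(bandpass_filter(matrix(sin(2 * pi * 10 * tt), 1), fs))
  expect_lt(abs(sd(y10[mid]) / sd(sin(2 * pi * 10 * tt)[mid]) - 1), 0.02)
  yd <- as.vector(bandpass_filter(matrix(sin(2 * pi * 0.2 * tt), 1), fs))
  expect_lt(20 * log10(sd(yd[mid]) / sd(sin(2 * pi * 0.2 * tt)[mid])), -20)
  expect_equal(bandpass_filter(matrix(0, 1, 4000), fs),
               matrix(0, 1, 4000), tolerance = 1e-12)
})

test_that("notch removes 50 Hz by 30 dB and leaves 10 Hz within 1%", {
  fs <- 256
  tt <- (0:(30 * fs - 1)) / fs
  mid <- 3000:5000
  y50 <- as.vector(notch_filter(matrix(sin(2 * pi * 50 * tt), 1), fs))
  expect_lt(20 * log10(sd(y50[mid]) / sd(sin(2 * pi * 50 * tt)[mid])), -30)
  y10 <- as.vector(notch_filter(matrix(sin(2 * pi * 10 * tt), 1), fs))
  expect_lt(abs(sd(y10[mid]) / sd(sin(2 * pi * 10 * tt)[mid]) - 1), 0.01)
})

test_that("filter chain is linear and zero-phase", {
  fs <- 256
  set.seed(1)
  x <- matrix(rnorm(2 * fs * 20), 2)
  y <- matrix(rnorm(2 * fs * 20), 2)
  fa <- bandpass_filter(2 * x + 3 * y, fs)
  fb <- 2 * bandpass_filter(x, fs) + 3 * bandpass_filter(y, fs)
  expect_equal(fa, fb, tolerance = 1e-9)
  # zero phase: cross-correlation of band-limited input and output peaks at 0
  tt <- (0:(fs * 20 - 1)) / fs
  s <- sin(2 * pi * 10 * tt)
  out <- as.vector(bandpass_filter(matrix(s, 1), fs))
  cc <- ccf(out[1000:4000], s[1000:4000], lag.max = 10, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("filters refuse streams shorter than the taps", {
  expect_error(bandpass_filter(matrix(rnorm(100), 1), 256), "minimum")
})

test_that("ASR passes clean data, removes spikes, is contractive", {
  fs <- 256
  set.seed(42)
  mix <- matrix(rnorm(16), 4)
  warm <- mix %*% matrix(rnorm(4 * fs * 40), 4)
  model <- asr_fit(warm, fs, cutoff = 5)
  clean <- mix %*% matrix(rnorm(4 * fs * 2), 4)
  out <- asr_apply(model, clean)
  expect_lt(norm(out - clean, "F") / norm(clean, "F"), 0.05)
  # injected 10x spike on one channel is suppressed below 3x background SD
  spiked <- clean
  bg_sd <- sd(clean[2, ])
  spiked[2, 300:350] <- spiked[2, 300:350] + 10 * bg_sd
  rec <- asr_apply(model, spiked)
  expect_lt(max(abs(rec[2, 300:350])), 3 * bg_sd)
  # contraction: per-block output variance never exceeds input variance
  expect_lte(sum(rec^2), sum(spiked^2))
  # infinite cutoff is the identity
  id <- asr_apply(asr_fit(warm, fs, cutoff = Inf), spiked)
  expect_equal(id, spiked)
  # degenerate warm-up
  warm0 <- warm; warm0[1, ] <- 0
  expect_error(asr_fit(warm0, fs), "zero-variance")
  expect_error(asr_fit(warm[, 1:100], fs), "30 s")
})

test_that("per-window normalization z-scores channels and is idempotent", {
  set.seed(7)
  w <- raw_window(rbind(rnorm(256, 5, 3), rep(2, 256)), 0, c("F3", "F4"), 256)
  nw <- normalize_window(w)
  expect_lt(abs(mean(nw$samples[1, ])), 1e-9)
  expect_equal(sd(nw$samples[1, ]), 1)
  expect_equal(nw$samples[2, ], rep(0, 256))   # constant channel -> zeros
  again <- normalize_window(nw)
  expect_equal(again$samples[1, ], nw$samples[1, ], tolerance = 1e-12)
})
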