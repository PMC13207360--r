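# shared fixtures: small, fast session/configs built in code

quick_config <- function(seed = 1L, duration_s = 60, warmup_s = 0, ...) {
  session_config(duration_s = duration_s, warmup_s = warmup_s, seed = seed, ...)
}

# a tiny two-channel sine window helper
sine_window <- function(freq, fs = 256, dur = 1, channels = c("F3", "F4"),
                        amp = 1) {
  tt <- (0:(fs * dur - 1)) / fs
  x <- matrix(rep(amp * sin(2 * pi * freq * tt), length(channels)),
              nrow = length(channels), byrow = TRUE)
  raw_window(x, 0, channels, fs)
}

# brute-force GAE oracle: direct double sum of discounted TD errors
gae_oracle <- function(rewards, values, gamma, lambda, bootstrap = 0) {
  n <- length(rewards)
  vnext <- c(values[-1], bootstrap)
  delta <- rewards + gamma * vnext - values
  sapply(seq_len(n), function(t) {
    k <- 0:(n - t)
    sum((gamma * lambda)^k * delta[t + k])
  })
}

# brute-force within-subject SS decomposition oracle
ss_oracle <- function(tab) {
  n <- nrow(tab); k <- ncol(tab); g <- mean(tab)
  ss_cond <- 0; ss_subj <- 0; ss_err <- 0
  for (i in seq_len(n)) for (j in seq_len(k)) {
    ss_err <- ss_err +
      (tab[i, j] - mean(tab[i, ]) - mean(tab[, j]) + g)^2
  }
  for (j in seq_len(k)) ss_cond <- ss_cond + n * (mean(tab[, j]) - g)^2
  for (i in seq_len(n)) ss_subj <- ss_subj + k * (mean(tab[i, ]) - g)^2
  c(condition = ss_cond, subject = ss_subj, error = ss_err)
}
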