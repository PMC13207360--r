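# Welch spectral estimation and canonical band powers.
#
# Frequency bands follow the canonical workload definitions theta 4-8 Hz,
# alpha 8-12 Hz, beta 13-30 Hz. Bins are assigned by center frequency with a
# lower-inclusive / upper-exclusive rule; the alpha upper edge is carried at
# 13 Hz so that at the 2 Hz resolution of the default Welch settings the bin
# centered on 12 Hz belongs to alpha and beta opens at 13 Hz (beta runs
# through 30 Hz inclusive, hence the 31 Hz exclusive edge).
BAND_EDGES <- list(theta = c(4, 8), alpha = c(8, 13), beta = c(13, 31))

#' Construct a raw EEG window
#'
#' Lightweight container for a channels-by-samples EEG segment.
#'
#' @param samples numeric matrix, channels x time samples.
#' @param start_time_s window start time in seconds.
#' @param channel_names character vector, one label per row of `samples`.
#' @param sample_rate sampling rate in Hz.
#' @return An object of class `tg_window`.
#' @export
raw_window <- function(samples, start_time_s = 0, channel_names = rownames(samples),
                       sample_rate = 256) {
  samples <- as.matrix(samples)
  if (is.null(channel_names)) {
    channel_names <- paste0("ch", seq_len(nrow(samples)))
  }
  if (length(channel_names) != nrow(samples)) {
    tg_stop("channel_names must have one entry per EEG channel")
  }
  structure(
    list(samples = samples, start_time_s = start_time_s,
         channel_names = channel_names, sample_rate = sample_rate),
    class = "tg_window")
}

#' @export
print.tg_window <- function(x, ...) {
  cat(sprintf("<tg_window> %d channels x %d samples @ %g Hz, t0 = %.3f s\n",
              nrow(x$samples), ncol(x$samples), x$sample_rate, x$start_time_s))
  invisible(x)
}

# Periodic Hann window (the spectral-analysis convention).
hann_window <- function(n) 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / n))

# column-wise sample variances without matrixStats
matrixColVars <- function(m) {
  n <- nrow(m)
  mu <- colMeans(m)
  (colSums(m^2) - n * mu^2) / (n - 1)
}

#' Welch power spectral density
#'
#' Mean modified periodogram over 50%-overlapping Hann-tapered segments, with
#' density scaling (power per Hz) and one-sided doubling. Segment means are
#' removed before tapering.
#'
#' @param x numeric vector (one channel).
#' @param fs sampling rate in Hz.
#' @param nperseg segment length in samples (default 128, i.e. 0.5 s at 256 Hz,
#'   giving 2 Hz resolution).
#' @param noverlap overlap in samples (default `nperseg / 2`).
#' @return list with `freq` (Hz) and `psd` (power density per Hz).
#' @export
welch_psd <- function(x, fs, nperseg = 128L, noverlap = nperseg %/% 2L) {
  n <- length(x)
  if (n < nperseg) {
    tg_stop(sprintf("welch_psd: signal has %d samples, needs at least nperseg = %d",
                    n, nperseg))
  }
  hop <- nperseg - noverlap
  starts <- seq(1L, n - nperseg + 1L, by = hop)
  w <- hann_window(nperseg)
  scale <- 1 / (fs * sum(w^2))
  acc <- numeric(nperseg %/% 2L + 1L)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)]
    seg <- (seg - mean(seg)) * w
    sp <- Mod(fft(seg))^2
    acc <- acc + sp[seq_len(length(acc))]
  }
  psd <- acc / length(starts) * scale
  # one-sided doubling, except DC and Nyquist
  psd[2:(length(psd) - 1L)] <- 2 * psd[2:(length(psd) - 1L)]
  list(freq = fs * (0:(nperseg %/% 2L)) / nperseg, psd = psd)
}

band_bin_index <- function(freq, band) which(freq >= band[1] & freq < band[2])

#' Band powers of one EEG window (Welch estimate)
#'
#' Estimates theta/alpha/beta band power per channel using Welch's method with
#' a Hann taper, 128-sample segments and 50% overlap (2 Hz resolution at
#' 256 Hz). Band power is the sum of density bins whose centers fall in the
#' band, times the bin width.
#'
#' @param window a [raw_window()] with at least 128 samples per channel.
#' @param nperseg,noverlap Welch segmentation parameters.
#' @return A channels x bands (`theta`, `alpha`, `beta`) matrix of class
#'   `tg_band_power`, with attribute `freq_res` (Hz).
#' @export
band_power_welch <- function(window, nperseg = 128L, noverlap = nperseg %/% 2L) {
  stopifnot(inherits(window, "tg_window"))
  X <- window$samples
  if (ncol(X) < nperseg) {
    tg_stop(sprintf("band_power_welch: window has %d samples, needs >= %d",
                    ncol(X), nperseg))
  }
  fs <- window$sample_rate
  out <- matrix(NA_real_, nrow(X), length(BAND_EDGES),
                dimnames = list(window$channel_names, names(BAND_EDGES)))
  df <- fs / nperseg
  for (ch in seq_len(nrow(X))) {
    sp <- welch_psd(X[ch, ], fs, nperseg, noverlap)
    for (b in seq_along(BAND_EDGES)) {
      out[ch, b] <- sum(sp$psd[band_bin_index(sp$freq, BAND_EDGES[[b]])]) * df
    }
  }
  structure(out, freq_res = df, class = c("tg_band_power", class(out)))
}

#' Frontal alpha asymmetry
#'
#' FAA is the log alpha-power contrast between right and left frontal
#' electrodes: `ln P_alpha(F4) - ln P_alpha(F3)`.
#'
#' @param band_powers a `tg_band_power` matrix containing rows `F3` and `F4`.
#' @return scalar FAA value.
#' @export
compute_faa <- function(band_powers) {
  if (!all(c("F3", "F4") %in% rownames(band_powers))) {
    tg_stop("compute_faa: band powers must include channels F3 and F4")
  }
  p3 <- band_powers["F3", "alpha"]
  p4 <- band_powers["F4", "alpha"]
  if (!is.finite(p3) || !is.finite(p4) || p3 <= 0 || p4 <= 0) {
    tg_stop("compute_faa: alpha power at F3/F4 must be strictly positive")
  }
  log(p4) - log(p3)
}

# Vectorized per-window band powers over a whole session.
#
# eeg: channels x samples matrix; starts_s: window start times (seconds).
# Window length is fixed at 1 s. Returns list(theta, alpha, beta): each
# nwin x nchan, plus faa (length nwin) when F3/F4 are present.
session_band_powers <- function(eeg, fs, starts_s, channel_names = rownames(eeg),
                                nperseg = 128L, normalize = FALSE) {
  nwin <- length(starts_s)
  nchan <- nrow(eeg)
  hop <- nperseg %/% 2L
  win_len <- as.integer(round(fs))          # 1 s analysis window
  nseg <- (win_len - nperseg) %/% hop + 1L  # segments per window (3 at 256 Hz)
  s0 <- round(starts_s * fs)                # 0-based start samples
  seg_starts <- as.vector(outer(hop * (0:(nseg - 1L)), s0, "+")) + 1L
  w <- hann_window(nperseg)
  scale <- 1 / (fs * sum(w^2))
  freq <- fs * (0:(nperseg %/% 2L)) / nperseg
  df <- fs / nperseg
  bidx <- lapply(BAND_EDGES, band_bin_index, freq = freq)
  idx <- outer(0:(nperseg - 1L), seg_starts, "+")
  widx <- if (normalize) outer(0:(win_len - 1L), s0 + 1L, "+") else NULL
  out <- lapply(BAND_EDGES, function(b) matrix(NA_real_, nwin, nchan))
  half <- nperseg %/% 2L + 1L
  for (ch in seq_len(nchan)) {
    segs <- matrix(eeg[ch, ][idx], nrow = nperseg)
    segs <- (segs - rep(colMeans(segs), each = nperseg)) * w
    sp <- Mod(stats::mvfft(segs))^2 * scale
    sp <- sp[seq_len(half), , drop = FALSE]
    sp[2:(half - 1L), ] <- 2 * sp[2:(half - 1L), ]
    # average the nseg consecutive segments of each window
    psd <- 0
    for (s in seq_len(nseg)) psd <- psd + sp[, seq(s, ncol(sp), by = nseg), drop = FALSE]
    psd <- psd / nseg
    if (normalize) {
      # per-window z-scoring divides each channel by its window SD, which
      # scales the window's power spectrum by 1 / window variance
      wv <- matrixColVars(matrix(eeg[ch, ][widx], nrow = win_len))
      wv[wv < .Machine$double.eps] <- Inf
      psd <- psd / rep(wv, each = half)
    }
    for (b in seq_along(bidx)) {
      out[[b]][, ch] <- colSums(psd[bidx[[b]], , drop = FALSE]) * df
    }
  }
  names(out) <- names(BAND_EDGES)
  for (b in seq_along(out)) colnames(out[[b]]) <- channel_names
  if (all(c("F3", "F4") %in% channel_names)) {
    out$faa <- log(pmax(out$alpha[, "F4"], .Machine$double.xmin)) -
      log(pmax(out$alpha[, "F3"], .Machine$double.xmin))
  }
  out$starts_s <- starts_s
  out
}
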