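# Synthetic dual-station session simulator.
#
# A session is a warm-up phase (baseline task, no scheduled events; used for
# ASR reference and CLI calibration) followed by a task phase in which
# secondary-task blocks, perturbations and hazards arrive as homogeneous
# Poisson processes. The latent workload drive l(t) in [0,1] is a smoothed
# state: baseline under channelized attention, an elevated plateau during
# secondary-task (diverted attention) blocks, a decaying transient after
# perturbations (surprise/startle), and relief while haptic assistance is
# active. EEG is synthesized from l(t) and the event-anchored class so that
# frontal theta and beta power rise and posterior alpha falls with load, and
# frontal alpha asymmetry grows with load.

#' Session configuration
#'
#' @param duration_s task-phase duration in seconds (default 600: each
#'   condition lasts 10 min).
#' @param sample_rate EEG sampling rate in Hz (default 256).
#' @param n_channels EEG channel count (default 14).
#' @param condition one of `"OPEN_LOOP"`, `"PILOT_ONLY"`, `"ENGINEER_ONLY"`,
#'   `"DUAL_LOOP"`.
#' @param warmup_s baseline warm-up preceding the task phase (default 300,
#'   the 5 min calibration phase); must be shorter than `duration_s`.
#' @param event_rates per-minute rates for `secondary` task blocks,
#'   `perturbation` episodes and time-critical `hazard`s.
#' @param secondary_duration_s duration of each secondary-task block.
#' @param behavior behavioral model parameters: `rt_median_ms` baseline
#'   log-normal reaction-time median, `rt_sigma_log` log-SD,
#'   `rt_load_gain` multiplicative load penalty on the RT median,
#'   `haptic_multiplier` RT median multiplier while haptics are active,
#'   `near_miss_ms` near-miss threshold, `attempt_rate_per_min` engineer
#'   speech-attempt base rate, `compliance` attempt-rate factors under the
#'   displayed GREEN/YELLOW/RED gate (imperfect adherence keeps RED
#'   attempts possible).
#' @param latent latent-load parameters: `baseline`, `da_gain` plateau,
#'   `su_gain` spike, `su_tau_s` spike decay, `smooth_tau_s` smoothing,
#'   `haptic_relief` load reduction under full haptic assistance,
#'   `su_window_s` post-perturbation labeling interval (2.5 s, the midpoint
#'   of the 2-3 s convention).
#' @param eeg EEG synthesis parameters (amplitudes in arbitrary microvolt-like
#'   units): background SD, per-band oscillation amplitudes and load gains,
#'   FAA load gain, 50 Hz line amplitude, artifact rate/amplitude, and
#'   `class_contrast` scaling the state-specific spatial signatures.
#' @param seed integer seed; identical config + seed reproduce the session
#'   bit for bit.
#' @return object of class `tg_session_config`.
#' @export
session_config <- function(duration_s = 600, sample_rate = 256, n_channels = 14,
                           condition = c("OPEN_LOOP", "PILOT_ONLY",
                                         "ENGINEER_ONLY", "DUAL_LOOP"),
                           warmup_s = 300,
                           event_rates = list(secondary = 1.0,
                                              perturbation = 2.0,
                                              hazard = 2.0),
                           secondary_duration_s = 20,
                           behavior = list(),
                           latent = list(),
                           eeg = list(),
                           seed = 1L) {
  condition <- match.arg(condition)
  if (!is.numeric(duration_s) || duration_s <= 0) {
    tg_stop("session_config: duration_s must be positive")
  }
  if (warmup_s < 0 || warmup_s >= duration_s) {
    tg_stop("session_config: warmup_s must lie in [0, duration_s)")
  }
  rates <- utils::modifyList(list(secondary = 1.0, perturbation = 2.0,
                                  hazard = 2.0), event_rates)
  if (any(unlist(rates) < 0)) tg_stop("session_config: event rates must be >= 0")
  beh <- utils::modifyList(list(
    rt_median_ms = 380, rt_sigma_log = 0.30, rt_load_gain = 0.6,
    haptic_multiplier = 0.45, near_miss_ms = 800,
    attempt_rate_per_min = 1.8,
    compliance = c(GREEN = 1.0, YELLOW = 0.5, RED = 0.15)), behavior)
  lat <- utils::modifyList(list(
    baseline = 0.30, da_gain = 0.35, su_gain = 0.50, su_tau_s = 2.0,
    smooth_tau_s = 3.0, haptic_relief = 0.15, su_window_s = 2.5,
    drift_sd = 0.15), latent)
  eegp <- utils::modifyList(list(
    bg_sd = 10, line_amp = 0.5, artifact_per_min = 2, artifact_amp_sd = 10,
    amp = c(theta = 4, alpha = 6, beta = 3),
    load_gain = c(theta = 0.9, alpha = 0.9, beta = 0.7),
    faa_gain = 0.8, class_contrast = 1.0, amp_mod_sd = 0), eeg)
  structure(list(duration_s = duration_s, sample_rate = sample_rate,
                 n_channels = n_channels, condition = condition,
                 warmup_s = warmup_s, event_rates = rates,
                 secondary_duration_s = secondary_duration_s,
                 behavior = beh, latent = lat, eeg = eegp,
                 seed = as.integer(seed)),
            class = "tg_session_config")
}

total_duration <- function(config) config$warmup_s + config$duration_s

#' @export
print.tg_session_config <- function(x, ...) {
  cat(sprintf("<tg_session_config> %s, task %g s + warm-up %g s, %d ch @ %g Hz, seed %d\n",
              x$condition, x$duration_s, x$warmup_s, x$n_channels,
              x$sample_rate, x$seed))
  invisible(x)
}

#' Draw the event schedule of a session
#'
#' Secondary-task blocks, perturbations and hazards arrive as independent
#' homogeneous Poisson processes at the configured per-minute rates over the
#' task phase. Times are session-absolute (the task phase starts at
#' `warmup_s`); the warm-up is event-free by construction.
#'
#' @param config a [session_config()].
#' @return data.frame of class `tg_schedule` with columns `onset_s`,
#'   `duration_s`, `type` (`SECONDARY_TASK`, `PERTURBATION`, `HAZARD`),
#'   ordered by onset.
#' @export
generate_schedule <- function(config) {
  stopifnot(inherits(config, "tg_session_config"))
  set.seed(config$seed + 1L)
  t0 <- config$warmup_s
  te <- total_duration(config)
  draw <- function(rate_per_min, dur, type) {
    n <- rpois(1L, rate_per_min * config$duration_s / 60)
    if (n == 0) return(NULL)
    data.frame(onset_s = sort(runif(n, t0, te)), duration_s = dur, type = type,
               stringsAsFactors = FALSE)
  }
  ev <- rbind(draw(config$event_rates$secondary, config$secondary_duration_s,
                   "SECONDARY_TASK"),
              draw(config$event_rates$perturbation, 0, "PERTURBATION"),
              draw(config$event_rates$hazard, 0, "HAZARD"))
  if (is.null(ev)) {
    ev <- data.frame(onset_s = numeric(0), duration_s = numeric(0),
                     type = character(0), stringsAsFactors = FALSE)
  }
  ev <- ev[order(ev$onset_s), , drop = FALSE]
  rownames(ev) <- NULL
  class(ev) <- c("tg_schedule", "data.frame")
  attr(ev, "duration_s") <- te
  ev
}

# slow spontaneous baseline fluctuation of the latent load: two incommensurate
# sinusoids with seed-determined phases, present in warm-up and task alike
# (real operators show intra-state workload variability; a perfectly flat
# baseline would make the warm-up calibration SD meaningless).
latent_drift <- function(config, times) {
  if (config$latent$drift_sd <= 0) return(numeric(length(times)))
  set.seed(config$seed + 4L)
  phi <- runif(2, 0, 2 * pi)
  config$latent$drift_sd / 1.17 *
    (sin(2 * pi * times / 97 + phi[1]) + 0.6 * sin(2 * pi * times / 31 + phi[2]))
}

# deterministic load recursion on the window grid; haptic_level in [0, 1]
# per step (0 OFF, 0.5 LOW, 1 HIGH).
latent_load_trace <- function(times, schedule, config, haptic_level = NULL) {
  lat <- config$latent
  drift <- latent_drift(config, times)
  dt <- if (length(times) > 1) times[2] - times[1] else 0.1
  if (is.null(haptic_level)) haptic_level <- numeric(length(times))
  pert <- schedule$onset_s[schedule$type == "PERTURBATION"]
  blocks <- schedule[schedule$type == "SECONDARY_TASK", , drop = FALSE]
  in_block <- vapply(times, function(t) {
    any(t < blocks$onset_s + blocks$duration_s & t + 1 > blocks$onset_s)
  }, logical(1))
  decay <- exp(-dt / lat$su_tau_s)
  alpha_s <- 1 - exp(-dt / lat$smooth_tau_s)
  l <- numeric(length(times))
  su_amp <- 0
  cur <- lat$baseline
  for (i in seq_along(times)) {
    su_amp <- su_amp * decay +
      lat$su_gain * sum(pert >= times[i] - dt & pert < times[i])
    target <- lat$baseline + drift[i] + lat$da_gain * in_block[i] + su_amp -
      lat$haptic_relief * haptic_level[i]
    cur <- cur + (target - cur) * alpha_s
    l[i] <- min(1, max(0, cur))
  }
  l
}

# event-anchored class of each window start (precedence SU > DA > CA)
classify_windows <- function(times, schedule, config) {
  suw <- config$latent$su_window_s
  pert <- schedule$onset_s[schedule$type == "PERTURBATION"]
  blocks <- schedule[schedule$type == "SECONDARY_TASK", , drop = FALSE]
  cls <- rep("CA", length(times))
  if (nrow(blocks)) {
    da <- vapply(times, function(t) {
      any(t < blocks$onset_s + blocks$duration_s & t + 1 > blocks$onset_s)
    }, logical(1))
    cls[da] <- "DA"
  }
  if (length(pert)) {
    su <- vapply(times, function(t) any(t >= pert & t < pert + suw), logical(1))
    cls[su] <- "SU"
  }
  cls
}

# ground-truth per-window band-power features implied by the generator gains
# (channel-mean intended power and FAA target), used for the recoverability
# ceiling and available to tests as an oracle.
latent_truth_features <- function(load, cls, config) {
  eeg <- config$eeg
  gain <- state_band_gains(load, cls, config)
  data.frame(
    theta = (eeg$amp["theta"] * gain$theta_scalar)^2,
    alpha = (eeg$amp["alpha"] * gain$alpha_scalar)^2,
    beta = (eeg$amp["beta"] * gain$beta_scalar)^2,
    faa = eeg$faa_gain * load)
}

# scalar (channel-averaged) state/load gains; also used by the synthesizer
state_band_gains <- function(load, cls, config) {
  eeg <- config$eeg
  cc <- eeg$class_contrast
  g_th <- (1 + eeg$load_gain["theta"] * load) *
    ifelse(cls == "DA", 1 + 0.25 * cc, ifelse(cls == "SU", 1 + 0.2 * cc, 1))
  g_al <- (1 + eeg$load_gain["alpha"] * (1 - load)) /
    ifelse(cls == "DA", 1 + 0.15 * cc, 1)
  g_be <- (1 + eeg$load_gain["beta"] * load) *
    ifelse(cls == "SU", 1 + 0.4 * cc, 1)
  list(theta_scalar = g_th, alpha_scalar = g_al, beta_scalar = g_be)
}

#' Ground-truth latent trace of a session
#'
#' Labels every window on the analysis grid with its event-anchored class
#' (SU inside the 2.5 s post-perturbation interval, DA when the window
#' overlaps a secondary-task block, CA otherwise; precedence SU > DA > CA)
#' and computes the deterministic open-loop latent load drive.
#'
#' @param schedule a [generate_schedule()] result (or compatible data.frame).
#' @param config the [session_config()].
#' @return data.frame of class `tg_latent` with columns `start_s`, `phase`
#'   (`warmup`/`task`), `class`, `load`, and ground-truth feature columns
#'   `gt_theta`, `gt_alpha`, `gt_beta`, `gt_faa`.
#' @export
label_latent <- function(schedule, config) {
  times <- window_start_times(total_duration(config))
  cls <- classify_windows(times, schedule, config)
  load <- latent_load_trace(times, schedule, config)
  gt <- latent_truth_features(load, cls, config)
  out <- data.frame(start_s = times,
                    phase = ifelse(times < config$warmup_s, "warmup", "task"),
                    class = cls, load = load,
                    gt_theta = gt$theta, gt_alpha = gt$alpha,
                    gt_beta = gt$beta, gt_faa = gt$faa,
                    stringsAsFactors = FALSE)
  class(out) <- c("tg_latent", "data.frame")
  out
}

# channel topography profiles for the 14-channel montage
channel_profiles <- function(channel_names) {
  frontal <- channel_names %in% c("AF3", "AF4", "F3", "F4", "F7", "F8")
  posterior <- channel_names %in% c("P7", "P8", "O1", "O2")
  temporal <- channel_names %in% c("T7", "T8", "FC5", "FC6")
  list(theta = ifelse(frontal, 1.3, 0.8),
       alpha = ifelse(posterior, 1.4, 0.8),
       beta = rep(1.0, length(channel_names)),
       frontal = frontal, posterior = posterior, temporal = temporal)
}

# band-limited unit-variance noise via FFT masking with raised-cosine edges
band_noise <- function(n, fs, low, high) {
  x <- rnorm(n)
  f <- (0:(n - 1)) * fs / n
  f <- pmin(f, fs - f)
  edge <- 0.5
  m <- rep(0, n)
  m[f >= low & f <= high] <- 1
  ramp_lo <- f >= low - edge & f < low
  ramp_hi <- f > high & f <= high + edge
  m[ramp_lo] <- 0.5 * (1 + cos(pi * (low - f[ramp_lo]) / edge))
  m[ramp_hi] <- 0.5 * (1 + cos(pi * (f[ramp_hi] - high) / edge))
  y <- Re(fft(fft(x) * m, inverse = TRUE)) / n
  y / sd(y)
}

# slow unit-variance modulation track (low-passed white noise) for
# spontaneous band-power fluctuation
slow_mod <- function(n, fs, cutoff = 0.125) {
  x <- rnorm(n)
  f <- (0:(n - 1)) * fs / n
  f <- pmin(f, fs - f)
  m <- as.numeric(f <= cutoff)
  y <- Re(fft(fft(x) * m, inverse = TRUE)) / n
  y / sd(y)
}

# 1/f background, unit variance
pink_noise <- function(n, fs) {
  x <- rnorm(n)
  f <- (0:(n - 1)) * fs / n
  f <- pmin(f, fs - f)
  g <- ifelse(f < 0.5, 0, 1 / sqrt(f))
  y <- Re(fft(fft(x) * g, inverse = TRUE)) / n
  y / sd(y)
}

#' Synthesize multichannel EEG from a latent trace
#'
#' Each channel is a 1/f background plus band-limited theta/alpha/beta
#' oscillations whose amplitudes follow fixed channel topographies (frontal
#' theta, posterior alpha) scaled by load- and state-dependent gains, plus an
#' optional 50 Hz line component and sparse high-amplitude artifact
#' transients. Under load, frontal theta and beta power rise, posterior
#' alpha falls, and the F4/F3 alpha ratio (FAA) grows.
#'
#' @param latent a [label_latent()] trace (or one with realized task loads).
#' @param layout an [electrode_layout()].
#' @param config the [session_config()].
#' @return channels x samples matrix with channel rownames.
#' @export
synthesize_eeg <- function(latent, layout, config) {
  set.seed(config$seed + 3L)
  fs <- config$sample_rate
  n <- as.integer(round(total_duration(config) * fs))
  chn <- layout$label
  prof <- channel_profiles(chn)
  eegp <- config$eeg
  tt <- (0:(n - 1)) / fs
  # per-sample load / class via step interpolation of the window grid
  li <- approx(latent$start_s, latent$load, xout = tt, method = "constant",
               rule = 2)$y
  ci <- latent$class[pmax(1L, pmin(length(latent$class),
                                   findInterval(tt, latent$start_s)))]
  ci[is.na(ci)] <- "CA"
  gains <- state_band_gains(li, ci, config)
  faa_half <- exp(eegp$faa_gain * li / 4)
  # spontaneous slow band-power fluctuation, shared across channels per band
  # (arousal-like global modulation; real band power varies widely within a
  # behavioral state, which keeps state shifts a realistic number of
  # warm-up SDs)
  mod <- if (eegp$amp_mod_sd > 0) {
    lapply(1:3, function(b) exp(eegp$amp_mod_sd * slow_mod(n, fs)))
  } else list(1, 1, 1)
  out <- matrix(0, length(chn), n, dimnames = list(chn, NULL))
  for (i in seq_along(chn)) {
    bg <- eegp$bg_sd * pink_noise(n, fs)
    a_th <- eegp$amp["theta"] * prof$theta[i] * gains$theta_scalar * mod[[1]]
    a_al <- eegp$amp["alpha"] * prof$alpha[i] * gains$alpha_scalar * mod[[2]]
    a_be <- eegp$amp["beta"] * prof$beta[i] * gains$beta_scalar * mod[[3]]
    if (chn[i] == "F4") a_al <- a_al * faa_half
    if (chn[i] == "F3") a_al <- a_al / faa_half
    x <- bg +
      a_th * band_noise(n, fs, 4, 8) +
      a_al * band_noise(n, fs, 8, 12) +
      a_be * band_noise(n, fs, 13, 30)
    if (eegp$line_amp > 0) {
      x <- x + eegp$line_amp * sin(2 * pi * 50 * tt + runif(1, 0, 2 * pi))
    }
    out[i, ] <- x
  }
  # sparse artifact transients: 10x background SD, 100-300 ms, random channel
  n_art <- rpois(1L, eegp$artifact_per_min * total_duration(config) / 60)
  if (n_art > 0) {
    for (k in seq_len(n_art)) {
      ch <- sample.int(length(chn), 1L)
      dur <- runif(1, 0.1, 0.3)
      at <- runif(1, 0, total_duration(config) - dur)
      idx <- (round(at * fs) + 1L):min(n, round((at + dur) * fs))
      bump <- sin(pi * seq_along(idx) / length(idx))
      out[ch, idx] <- out[ch, idx] +
        sample(c(-1, 1), 1L) * eegp$artifact_amp_sd * eegp$bg_sd * bump
    }
  }
  out
}
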