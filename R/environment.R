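# Step-wise task environment over the 100 ms control grid, and full session
# generation. The environment is what the controller is trained against:
# hazards draw log-normal reaction times whose median falls while haptics are
# active, engineer speech attempts arrive at a context-dependent Poisson rate
# modulated by compliance with the displayed gate (the gate informs, it never
# physically silences: attempts during RED are emitted and logged), and the
# latent load responds to haptic relief.

HAPTIC_LEVELS <- c(OFF = 0, LOW = 0.5, HIGH = 1)
ENG_ACTIONS <- c("OPEN", "WARN", "BLOCK")
GATES <- c("GREEN", "YELLOW", "RED")

#' Initialize a session environment
#'
#' @param config a [session_config()].
#' @param schedule optional pre-drawn [generate_schedule()]; drawn from the
#'   config seed if omitted.
#' @return environment state of class `tg_env` (step it with [sim_env_step()]).
#' @export
sim_env_init <- function(config, schedule = NULL) {
  stopifnot(inherits(config, "tg_session_config"))
  if (is.null(schedule)) schedule <- generate_schedule(config)
  dt <- 0.1
  n_steps <- as.integer(round(config$duration_s / dt))
  times <- config$warmup_s + dt * (0:(n_steps - 1L))
  cls <- classify_windows(times, schedule, config)
  blocks <- schedule[schedule$type == "SECONDARY_TASK", , drop = FALSE]
  in_block <- vapply(times, function(t) {
    any(t < blocks$onset_s + blocks$duration_s & t + 1 > blocks$onset_s)
  }, logical(1))
  pert <- schedule$onset_s[schedule$type == "PERTURBATION"]
  haz <- schedule$onset_s[schedule$type == "HAZARD"]
  st <- new.env(parent = emptyenv())
  st$config <- config
  st$schedule <- schedule
  st$dt <- dt
  st$n_steps <- n_steps
  st$times <- times
  st$class <- cls
  st$in_block <- in_block
  st$pert <- pert
  st$haz <- haz
  st$drift <- latent_drift(config, times)
  st$k <- 0L
  st$load <- config$latent$baseline
  st$su_amp <- 0
  st$last_attempt_s <- -Inf
  st$last_hazard_s <- -Inf
  st$recent_attempts <- numeric(0)
  # logs
  st$log_load <- numeric(n_steps)
  st$log_gate <- character(n_steps)
  st$log_pilot <- character(n_steps)
  st$log_eng <- character(n_steps)
  st$log_attempt <- integer(n_steps)
  st$log_cli_est <- numeric(n_steps)
  st$log_class_obs <- character(n_steps)
  st$rt_ms <- numeric(0)
  st$rt_time_s <- numeric(0)
  st$near_miss <- logical(0)
  st$score <- 0
  class(st) <- "tg_env"
  st
}

#' Observation served to the controller before a step
#'
#' @param st a `tg_env` state.
#' @return list with `cli_est` (noisy latent-load estimate standing in for the
#'   decoder CLI head), `class_obs` (ground-truth class with small label
#'   noise), telemetry / gaze / communication summaries, and `time_s`.
#' @export
sim_env_observe <- function(st) {
  k <- st$k + 1L
  if (st$k >= st$n_steps) tg_stop("sim_env_observe: episode has ended")
  tnow <- st$times[k]
  cls <- st$class[k]
  cli_est <- min(1, max(0, st$load + rnorm(1, 0, 0.05)))
  class_obs <- if (runif(1) < 0.95) cls else sample(setdiff(NEUROSTATES, cls), 1L)
  hazard_recent <- as.numeric(tnow - st$last_hazard_s < 5)
  gaze <- c(off_target = min(1, max(0, (if (cls == "DA") 0.8 else 0.1) + rnorm(1, 0, 0.05))),
            pupil = min(1, max(0, st$load + rnorm(1, 0, 0.1))))
  tel <- c(hazard_recent = hazard_recent,
           progress_rate = 1.5 - 0.8 * st$load)
  st$recent_attempts <- st$recent_attempts[st$recent_attempts > tnow - 10]
  comm <- c(since_last = min(10, tnow - st$last_attempt_s) / 10,
            recent = length(st$recent_attempts) / 5)
  list(cli_est = cli_est, class_obs = class_obs, tel = tel, gaze = gaze,
       comm = comm, time_s = tnow)
}

#' Advance the environment by one 100 ms step
#'
#' Applies the condition semantics (open-loop forces haptics OFF and the gate
#' GREEN; pilot-only forces the gate GREEN; engineer-only forces haptics OFF),
#' updates the latent load with haptic relief, draws hazard reaction times and
#' engineer speech attempts, and returns the step transition.
#'
#' @param st a `tg_env` state (modified in place).
#' @param action list with `pilot` in OFF/LOW/HIGH, `eng` in OPEN/WARN/BLOCK,
#'   and optionally `gate` (the semaphore after any safety override; defaults
#'   to the order-preserving mapping of `eng`).
#' @param obs the matching [sim_env_observe()] result (re-drawn if omitted).
#' @return list `transition` with the step outcome flags and `done`.
#' @export
sim_env_step <- function(st, action, obs = NULL) {
  if (st$k >= st$n_steps) tg_stop("sim_env_step: episode has ended")
  k <- st$k + 1L
  if (is.null(obs)) obs <- sim_env_observe(st)
  cfg <- st$config
  beh <- cfg$behavior
  tnow <- st$times[k]
  pilot <- match.arg(action$pilot, names(HAPTIC_LEVELS))
  eng <- match.arg(action$eng, ENG_ACTIONS)
  gate <- action$gate %||% map_semaphore(eng)
  # condition semantics
  if (cfg$condition == "OPEN_LOOP") { pilot <- "OFF"; gate <- "GREEN" }
  if (cfg$condition == "PILOT_ONLY") gate <- "GREEN"
  if (cfg$condition == "ENGINEER_ONLY") pilot <- "OFF"
  hl <- HAPTIC_LEVELS[[pilot]]

  # latent load update (same recursion as the open-loop trace)
  lat <- cfg$latent
  st$su_amp <- st$su_amp * exp(-st$dt / lat$su_tau_s) +
    lat$su_gain * sum(st$pert >= tnow - st$dt & st$pert < tnow)
  target <- lat$baseline + st$drift[k] + lat$da_gain * st$in_block[k] +
    st$su_amp - lat$haptic_relief * hl
  st$load <- min(1, max(0, st$load + (target - st$load) *
                          (1 - exp(-st$dt / lat$smooth_tau_s))))

  # hazards falling in this step
  n_haz <- sum(st$haz >= tnow & st$haz < tnow + st$dt)
  rt_ms <- NA_real_
  near_miss <- FALSE
  if (n_haz > 0) {
    st$last_hazard_s <- tnow
    med <- beh$rt_median_ms *
      beh$haptic_multiplier^(hl > 0) *
      (1 + beh$rt_load_gain * st$load)
    draws <- rlnorm(n_haz, log(med), beh$rt_sigma_log)
    st$rt_ms <- c(st$rt_ms, draws)
    st$rt_time_s <- c(st$rt_time_s, rep(tnow, n_haz))
    nm <- draws > beh$near_miss_ms
    st$near_miss <- c(st$near_miss, nm)
    rt_ms <- draws[1]
    near_miss <- any(nm)
  }

  # engineer speech attempts: context-dependent inhomogeneous Poisson with
  # compliance to the displayed gate
  boost <- 1 + as.numeric(tnow - st$last_hazard_s < 5)
  p_attempt <- beh$attempt_rate_per_min / 60 * st$dt * boost *
    beh$compliance[[gate]]
  attempt <- as.integer(runif(1) < p_attempt)
  if (attempt == 1L) {
    st$last_attempt_s <- tnow
    st$recent_attempts <- c(st$recent_attempts, tnow)
  }

  dscore <- (1.5 - 0.8 * st$load) * st$dt
  st$score <- st$score + dscore

  st$log_load[k] <- st$load
  st$log_gate[k] <- gate
  st$log_pilot[k] <- pilot
  st$log_eng[k] <- eng
  st$log_attempt[k] <- attempt
  st$log_cli_est[k] <- obs$cli_est
  st$log_class_obs[k] <- obs$class_obs
  st$k <- k

  list(time_s = tnow, pilot = pilot, eng = eng, gate = gate,
       attempt = attempt, hazard = n_haz > 0, rt_ms = rt_ms,
       near_miss = near_miss, dscore = dscore, dtime = st$dt,
       cli_est = obs$cli_est, class_obs = obs$class_obs, load = st$load,
       done = st$k >= st$n_steps)
}

# collect the per-step logs of a finished episode as a data.frame
sim_env_log <- function(st) {
  k <- st$k
  data.frame(time_s = st$times[seq_len(k)],
             load = st$log_load[seq_len(k)],
             gate = st$log_gate[seq_len(k)],
             pilot = st$log_pilot[seq_len(k)],
             eng = st$log_eng[seq_len(k)],
             attempt = st$log_attempt[seq_len(k)],
             cli_est = st$log_cli_est[seq_len(k)],
             class_obs = st$log_class_obs[seq_len(k)],
             class_true = st$class[seq_len(k)],
             stringsAsFactors = FALSE)
}

#' Generate a full synthetic session bundle
#'
#' Draws the event schedule, runs the step-wise environment under the given
#' policy (or the condition's neutral default), then synthesizes the EEG from
#' the realized latent trace. Identical config + seed give a bit-identical
#' bundle.
#'
#' @param config a [session_config()].
#' @param policy `NULL`, or a function `(obs) -> list(pilot=, eng=, gate=)`
#'   (typically a controller closure including the safety override).
#' @param synthesize if `FALSE`, skip EEG synthesis (events/behavior only).
#' @return object of class `tg_session`: list with `eeg`, `sample_rate`,
#'   `channel_names`, `schedule`, `latent` (realized), `steps` (per-step log),
#'   `comm` (attempt times and gate at emission), `outcomes` (hazard RTs and
#'   near-miss flags), `score`, `config`.
#' @export
generate_session <- function(config, policy = NULL, synthesize = TRUE) {
  stopifnot(inherits(config, "tg_session_config"))
  schedule <- generate_schedule(config)
  set.seed(config$seed + 2L)
  st <- sim_env_init(config, schedule)
  while (st$k < st$n_steps) {
    obs <- sim_env_observe(st)
    act <- if (is.null(policy)) list(pilot = "OFF", eng = "OPEN") else policy(obs)
    sim_env_step(st, act, obs)
  }
  steps <- sim_env_log(st)
  # latent trace: warm-up baseline grid + realized task loads
  latent <- label_latent(schedule, config)
  task <- latent$phase == "task"
  idx <- match(round(latent$start_s[task], 6), round(steps$time_s, 6))
  ok <- !is.na(idx)
  latent$load[task][ok] <- steps$load[idx[ok]]
  gt <- latent_truth_features(latent$load, latent$class, config)
  latent$gt_theta <- gt$theta; latent$gt_alpha <- gt$alpha
  latent$gt_beta <- gt$beta; latent$gt_faa <- gt$faa
  layout <- electrode_layout()
  eeg <- if (synthesize) synthesize_eeg(latent, layout, config) else NULL
  comm <- data.frame(time_s = steps$time_s[steps$attempt == 1L],
                     gate = steps$gate[steps$attempt == 1L],
                     stringsAsFactors = FALSE)
  outcomes <- data.frame(time_s = st$rt_time_s, rt_ms = st$rt_ms,
                         near_miss = st$near_miss, stringsAsFactors = FALSE)
  structure(list(eeg = eeg, sample_rate = config$sample_rate,
                 channel_names = layout$label, schedule = schedule,
                 latent = latent, steps = steps, comm = comm,
                 outcomes = outcomes, score = st$score, config = config),
            class = "tg_session")
}

#' @export
print.tg_session <- function(x, ...) {
  cat(sprintf("<tg_session> %s, %g s task (+%g s warm-up), %d hazards, %d attempts, seed %d\n",
              x$config$condition, x$config$duration_s, x$config$warmup_s,
              nrow(x$outcomes), nrow(x$comm), x$config$seed))
  invisible(x)
}
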