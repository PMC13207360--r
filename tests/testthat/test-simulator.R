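test_that("schedules are seeded Poisson draws within the task phase", {
  cfg <- quick_config(seed = 3, duration_s = 120, warmup_s = 30)
  s1 <- generate_schedule(cfg)
  s2 <- generate_schedule(cfg)
  expect_identical(s1, s2)
  expect_true(all(s1$onset_s >= 30 & s1$onset_s < 150))
  expect_false(is.unsorted(s1$onset_s))
  empty <- generate_schedule(quick_config(event_rates = list(
    secondary = 0, perturbation = 0, hazard = 0)))
  expect_equal(nrow(empty), 0)
  expect_error(session_config(event_rates = list(secondary = -1)), ">= 0")
})

test_that("Poisson event counts match rate x duration", {
  counts <- vapply(1:200, function(s) {
    cfg <- session_config(duration_s = 600, warmup_s = 0, seed = s,
                          event_rates = list(secondary = 0, hazard = 0,
                                             perturbation = 0.5))
    nrow(generate_schedule(cfg))
  }, 0L)
  se <- sqrt(5 / 200)    # Poisson mean 5, SE of the mean over 200 seeds
  expect_lt(abs(mean(counts) - 5), 3 * se)
})

test_that("latent labeling applies SU > DA > CA with the 2.5 s window", {
  cfg <- quick_config(duration_s = 200, warmup_s = 0)
  sched <- data.frame(onset_s = c(100, 50), duration_s = c(0, 20),
                      type = c("PERTURBATION", "SECONDARY_TASK"))
  lat <- label_latent(sched, cfg)
  su <- lat$start_s >= 100 & lat$start_s < 102.5
  expect_true(all(lat$class[su] == "SU"))
  expect_true(all(lat$class[lat$start_s >= 102.6 & lat$start_s < 104] != "SU"))
  # DA when the 1 s window overlaps the block (starts in (49, 70))
  expect_equal(lat$class[lat$start_s == 55], "DA")
  expect_equal(lat$class[lat$start_s == 49.5], "DA")   # overlap from the left
  expect_equal(lat$class[lat$start_s == 30], "CA")
  # precedence: perturbation inside a block
  sched2 <- data.frame(onset_s = c(55, 50), duration_s = c(0, 20),
                       type = c("PERTURBATION", "SECONDARY_TASK"))
  lat2 <- label_latent(sched2, cfg)
  expect_equal(lat2$class[lat2$start_s == 55.5], "SU")
  # empty schedule: all CA, load near baseline
  lat0 <- label_latent(sched[0, ], cfg)
  expect_true(all(lat0$class == "CA"))
  expect_true(all(abs(lat0$load - cfg$latent$baseline) <=
                    cfg$latent$drift_sd * 2 + 0.02))
  expect_true(all(lat0$load >= 0 & lat0$load <= 1))
})

test_that("class mix across seeds matches the reference ranges", {
  fr <- vapply(1:12, function(s) {
    cfg <- session_config(seed = s)
    lat <- label_latent(generate_schedule(cfg), cfg)
    tab <- table(factor(lat$class[lat$phase == "task"], NEUROSTATES))
    as.numeric(tab / sum(tab))
  }, numeric(3))
  pooled <- rowMeans(fr)
  expect_gt(pooled[1], 0.60); expect_lt(pooled[1], 0.70)   # CA
  expect_gt(pooled[3], 0.05); expect_lt(pooled[3], 0.10)   # SU
})

test_that("synthetic EEG is seeded and spectrally structured", {
  cfg <- quick_config(seed = 5, duration_s = 40,
                      eeg = list(line_amp = 0, artifact_per_min = 0))
  s1 <- generate_session(cfg)
  s2 <- generate_session(cfg)
  expect_identical(s1$eeg, s2$eeg)
  # alpha-only generation concentrates Welch power in 8-12 Hz
  cfg_a <- quick_config(seed = 6, duration_s = 40,
                        eeg = list(amp = c(theta = 0, alpha = 6, beta = 0),
                                   bg_sd = 0.05, line_amp = 0,
                                   artifact_per_min = 0))
  lat <- label_latent(generate_schedule(cfg_a), cfg_a)
  eeg <- synthesize_eeg(lat, electrode_layout(), cfg_a)
  bp <- band_power_welch(raw_window(eeg[, 257:512], 1,
                                    rownames(eeg), 256))
  expect_lt(mean(bp[, "theta"] / bp[, "alpha"]), 0.05)
  expect_lt(mean(bp[, "beta"] / bp[, "alpha"]), 0.05)
})

test_that("frontal theta power is higher in DA than CA windows", {
  cfg <- quick_config(seed = 7, duration_s = 120,
                      event_rates = list(secondary = 3, perturbation = 0,
                                         hazard = 0),
                      eeg = list(line_amp = 0, artifact_per_min = 0))
  ses <- generate_session(cfg)
  bp <- topogate:::session_band_powers(ses$eeg, 256,
                                       topogate:::window_start_times(120),
                                       ses$channel_names)
  lat <- ses$latent
  frontal <- c("AF3", "AF4", "F3", "F4", "F7", "F8")
  th <- rowMeans(bp$theta[, frontal])
  expect_gt(mean(th[lat$class == "DA"]), mean(th[lat$class == "CA"]))
})

test_that("sessions respect config validation", {
  expect_error(session_config(duration_s = 0), "positive")
  expect_error(session_config(duration_s = 100, warmup_s = 100), "warmup")
})

test_that("environment step semantics: open-loop forcing, RT model, episode end", {
  cfg <- quick_config(seed = 8, duration_s = 20, condition = "OPEN_LOOP")
  set.seed(1)
  st <- sim_env_init(cfg)
  tr <- sim_env_step(st, list(pilot = "HIGH", eng = "BLOCK"))
  expect_equal(tr$pilot, "OFF")
  expect_equal(tr$gate, "GREEN")
  while (st$k < st$n_steps) sim_env_step(st, list(pilot = "OFF", eng = "OPEN"))
  expect_error(sim_env_step(st, list(pilot = "OFF", eng = "OPEN")), "ended")
  # zero hazard rate -> no RT outcomes
  ses0 <- generate_session(quick_config(seed = 9, duration_s = 30,
                                        event_rates = list(hazard = 0)),
                           synthesize = FALSE)
  expect_equal(nrow(ses0$outcomes), 0)
})

test_that("haptics scale the reaction-time median by the configured multiplier", {
  draws <- function(cond) {
    cfg <- session_config(seed = 10, duration_s = 600, warmup_s = 0,
                          condition = cond,
                          event_rates = list(hazard = 12, secondary = 0,
                                             perturbation = 0))
    pol <- function(obs) list(pilot = "HIGH", eng = "OPEN")
    ses <- generate_session(cfg, pol, synthesize = FALSE)
    ses$outcomes$rt_ms
  }
  rt_off <- draws("OPEN_LOOP")       # haptics forced OFF
  rt_on <- draws("PILOT_ONLY")       # haptics active
  expect_gt(length(rt_off), 80)
  ratio <- median(rt_on) / median(rt_off)
  expect_lt(abs(ratio / 0.45 - 1), 0.12)   # log-normal median equivariance
})

test_that("session bundles round-trip through disk", {
  ses <- generate_session(quick_config(seed = 11, duration_s = 10,
                                       eeg = list(artifact_per_min = 0)))
  dir <- file.path(tempdir(), "tg_session_rt")
  write_session(ses, dir)
  back <- read_session(dir)
  expect_equal(back$eeg, ses$eeg, tolerance = 1e-12)
  expect_equal(back$steps$gate, ses$steps$gate)
  expect_equal(back$config$seed, ses$config$seed)
  expect_equal(nrow(back$outcomes), nrow(ses$outcomes))
  unlink(dir, recursive = TRUE)
})
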