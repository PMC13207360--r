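test_that("fused state keeps the fixed concatenation order and length", {
  s <- fuse_state(list(class = "CA", cli = 0.4),
                  list(tel = c(1, 0.9), gaze = c(0.2, 0.5), comm = c(0.1, 0),
                       gate = "YELLOW"))
  expect_length(s, 14)
  expect_equal(unname(s[2:4]), c(1, 0, 0))
  expect_equal(unname(s[12:14]), c(0, 1, 0))
  # missing gaze stream: zeros with presence flag 0
  s2 <- fuse_state(list(class = "SU", cli = 0.9),
                   list(tel = c(0, 1), comm = c(0, 0), gate = "GREEN"))
  expect_equal(unname(s2[7:9]), c(0, 0, 0))
  expect_error(fuse_state(list(class = "XX", cli = 0),
                          list(tel = c(0, 0), comm = c(0, 0))), "unknown")
})

test_that("semaphore mapping is the order-preserving bijection", {
  expect_equal(map_semaphore("OPEN"), "GREEN")
  expect_equal(map_semaphore("WARN"), "YELLOW")
  expect_equal(map_semaphore("BLOCK"), "RED")
  expect_error(map_semaphore("SHOUT"), "invalid")
})

test_that("safety override forces RED on SU or critical CLI (inclusive)", {
  expect_equal(safety_override("GREEN", "SU", 0.1, 0.9), "RED")
  expect_equal(safety_override("YELLOW", "CA", 0.9, 0.9), "RED")  # >= as defined
  expect_equal(safety_override("YELLOW", "CA", 0.89, 0.9), "YELLOW")
  expect_equal(safety_override("GREEN", "DA", 0.2, 0.9), "GREEN")
})

test_that("reward components and printed-constant arithmetic", {
  spec <- reward_spec()
  base <- list(hazard = FALSE, near_miss = FALSE, rt_ms = NA, dscore = 0,
               dtime = 0, attempt = 0L, gate = "YELLOW", pilot = "OFF",
               cli_norm = 0)
  # attempt during RED, nothing else: wc * (-beta) = -2.5
  tr <- modifyList(base, list(attempt = 1L, gate = "RED"))
  expect_equal(compute_reward(tr, spec)$reward, -2.5)
  # near miss with RT at target: ws * (-1) = -10
  tr <- modifyList(base, list(hazard = TRUE, near_miss = TRUE, rt_ms = 500))
  expect_equal(compute_reward(tr, spec)$reward, -10)
  # quiet step, CLI 0.5, pilot HIGH: -wl*0.5 - wh*1 = -0.15
  tr <- modifyList(base, list(cli_norm = 0.5, pilot = "HIGH"))
  expect_equal(compute_reward(tr, spec)$reward, -0.15)
  expect_error(compute_reward(modifyList(base, list(hazard = TRUE)), spec),
               "reaction time")
})

test_that("reward decomposition recombines exactly", {
  spec <- reward_spec()
  set.seed(10)
  for (i in 1:200) {
    tr <- list(hazard = runif(1) < 0.3, near_miss = runif(1) < 0.2,
               rt_ms = runif(1, 100, 1500), dscore = rnorm(1), dtime = 0.1,
               attempt = rbinom(1, 1, 0.5), gate = sample(c("GREEN", "YELLOW", "RED"), 1),
               pilot = sample(c("OFF", "LOW", "HIGH"), 1), cli_norm = runif(1))
    r <- compute_reward(tr, spec)
    manual <- spec$ws * r$components["safety"] + spec$wp * r$components["progress"] +
      spec$wc * r$components["comm"] - spec$wl * r$components["load"] -
      spec$wh * r$components["haptic"]
    expect_equal(unname(manual), r$reward, tolerance = 1e-12)
  }
})

test_that("cost signals and episodic aggregation follow mean/sum forms", {
  tau <- 0.5
  tr <- list(cli_norm = 0.6, attempt = 1L, gate = "RED")
  expect_equal(unname(cost_signals(tr, tau)), c(1, 1))
  d_load <- c(rep(1, 3), rep(0, 7))
  d_cbe <- c(1, 1, 0, 0, 1, rep(0, 5)) * c(1, 1, 0, 0, 0, rep(0, 5))
  ec <- episodic_costs(d_load, d_cbe)
  expect_equal(unname(ec["C_load"]), 0.3)
  expect_equal(unname(ec["C_cbe"]), 2)
  expect_equal(unname(episodic_costs(numeric(10), numeric(10))["C_cbe"]), 0)
})

test_that("GAE matches the brute-force oracle and its limits", {
  expect_equal(gae(1, 0, 0.99, 0.95, bootstrap = 0), 1)
  set.seed(11)
  r <- rnorm(20); v <- rnorm(20)
  expect_equal(gae(r, v, 0.99, 0.95), gae_oracle(r, v, 0.99, 0.95),
               tolerance = 1e-10)
  # lambda = 0: one-step TD errors
  expect_equal(gae(r, v, 0.9, 0), r + 0.9 * c(v[-1], 0) - v, tolerance = 1e-12)
  # lambda = 1: discounted return minus baseline
  ret <- rev(cumsum(rev(r * 0.9^(seq_along(r) - 1)))) / 0.9^(seq_along(r) - 1)
  expect_equal(gae(r, v, 0.9, 1), ret - v, tolerance = 1e-10)
  expect_error(gae(r, v[-1]), "equal length")
})

test_that("dual updates are projected ascent with monotone response", {
  cs <- constraint_state()
  up <- dual_update(cs, c(C_load = 0.20, C_cbe = 0))
  expect_equal(up$lambda_load, 0.001 * 0.05)
  expect_equal(up$lambda_cbe, 0)                       # projection at zero
  same <- dual_update(constraint_state(lambda_load = 0.01),
                      c(C_load = 0.15, C_cbe = 0.05))
  expect_equal(same$lambda_load, 0.01)                 # zero gradient
  a <- dual_update(cs, c(C_load = 0.3, C_cbe = 1))
  b <- dual_update(cs, c(C_load = 0.6, C_cbe = 2))
  expect_gte(b$lambda_load, a$lambda_load)
  expect_gte(b$lambda_cbe, a$lambda_cbe)
})

test_that("policy acts on states and updates keep entropy positive", {
  pcfg <- policy_config(rollout = 64L, minibatch = 16L, epochs = 2L, seed = 2)
  pol <- build_policy(5, pcfg)
  set.seed(2)
  s <- runif(5)
  a <- policy_act(pol, s)
  expect_true(a$pilot %in% c("OFF", "LOW", "HIGH"))
  expect_true(a$eng %in% c("OPEN", "WARN", "BLOCK"))
  expect_lt(a$logp, 0)
  ro <- list(X = matrix(runif(64 * 5), 64), ip = sample(1:3, 64, TRUE),
             ie = sample(1:3, 64, TRUE), logp = rep(log(1/9), 64),
             adv = rnorm(64), ret = rnorm(64),
             costs = c(C_load = 0.1, C_cbe = 0))
  up <- mappo_update(pol, ro, constraint_state())
  expect_gt(up$entropy, 0)
  expect_true(is.finite(up$loss))
})

test_that("with zero multipliers the shaped reward equals the raw reward", {
  cs <- constraint_state(lambda_load = 0, lambda_cbe = 0)
  r <- 1.7; dl <- 1; db <- 1
  expect_equal(r - cs$lambda_load * dl - cs$lambda_cbe * db, r)
})

test_that("determinism: same seed gives identical toy training curves", {
  run <- function() {
    pcfg <- policy_config(rollout = 256L, max_steps = 512, seed = 5,
                          stop_window = 1000L)
    train_controller(make_toy_gating_env(episode_steps = 64L, seed0 = 9), pcfg)
  }
  b1 <- run(); b2 <- run()
  expect_equal(b1$log, b2$log)
})
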