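# Dual-loop controller: fused control state, joint pilot/engineer action
# space, traffic-light semaphore with deterministic safety override, reward
# shaping, and constrained multi-agent PPO (clipped surrogate + centralized
# critic + projected dual ascent on the episodic cost budgets).

#' Reward specification
#'
#' Safety-first weighting: near-misses and RED-state speech attempts are
#' penalized far more strongly than task progress is rewarded, while
#' sustained overload and intrusive (HIGH) haptics act as low-weight
#' regularizers.
#'
#' @param ws,wp,wc,wl,wh component weights (safety, progress, communication,
#'   load cost, haptic cost).
#' @param alpha reaction-time overshoot scale (per second beyond `rt_star_s`).
#' @param beta RED-state speech attempt penalty scale.
#' @param eta withheld-communication penalty while the gate is GREEN.
#' @param rt_star_s target reaction time for critical hazards, seconds.
#' @return list of class `tg_reward_spec`.
#' @export
reward_spec <- function(ws = 10.0, wp = 1.0, wc = 0.5, wl = 0.1, wh = 0.1,
                        alpha = 1.0, beta = 5.0, eta = 0.1, rt_star_s = 0.5) {
  w <- c(ws, wp, wc, wl, wh)
  if (any(w < 0)) tg_stop("reward_spec: weights must be nonnegative")
  structure(list(ws = ws, wp = wp, wc = wc, wl = wl, wh = wh,
                 alpha = alpha, beta = beta, eta = eta, rt_star_s = rt_star_s),
            class = "tg_reward_spec")
}

#' Constraint state for the constrained MDP layer
#'
#' @param eps_load episodic budget on mean overload exposure.
#' @param eps_cbe episodic budget on summed RED-state speech attempts.
#' @param eta_lambda dual ascent learning rate.
#' @param lambda_load,lambda_cbe initial multipliers (nonnegative).
#' @param lambda_max upper bound on the multipliers (default unbounded, the
#'   plain projected-ascent form). Under a structurally infeasible budget
#'   the dual diverges and its shaped-reward spikes drown the remaining
#'   learning signal; capping is the standard mitigation.
#' @return list of class `tg_constraint_state`.
#' @export
constraint_state <- function(eps_load = 0.15, eps_cbe = 0.05,
                             eta_lambda = 0.001,
                             lambda_load = 0, lambda_cbe = 0,
                             lambda_max = Inf) {
  stopifnot(lambda_load >= 0, lambda_cbe >= 0, lambda_max > 0)
  structure(list(eps_load = eps_load, eps_cbe = eps_cbe,
                 eta_lambda = eta_lambda,
                 lambda_load = lambda_load, lambda_cbe = lambda_cbe,
                 lambda_max = lambda_max),
            class = "tg_constraint_state")
}

#' Policy optimization configuration
#'
#' @param gamma discount factor.
#' @param gae_lambda generalized advantage estimation parameter.
#' @param clip PPO clipping ratio.
#' @param entropy_coef entropy bonus coefficient.
#' @param rollout environment steps collected per update.
#' @param minibatch minibatch size.
#' @param epochs optimization epochs per update.
#' @param lr Adam learning rate for policy and critic.
#' @param max_steps environment-step cap (desk-scale default 2e5; the full
#'   protocol cap of 5e6 is available by configuration).
#' @param stop_window,stop_tol stop when the mean episodic reward varies by
#'   less than `stop_tol` (relative) over `stop_window` consecutive
#'   iterations.
#' @param seed integer seed.
#' @return list of class `tg_policy_config`.
#' @export
policy_config <- function(gamma = 0.99, gae_lambda = 0.95, clip = 0.2,
                          entropy_coef = 0.01, rollout = 2048L,
                          minibatch = 64L, epochs = 10L, lr = 3e-4,
                          max_steps = 2e5, stop_window = 100L, stop_tol = 0.05,
                          seed = 1L) {
  stopifnot(gamma > 0, gamma <= 1, gae_lambda >= 0, gae_lambda <= 1, clip > 0)
  structure(list(gamma = gamma, gae_lambda = gae_lambda, clip = clip,
                 entropy_coef = entropy_coef, rollout = as.integer(rollout),
                 minibatch = as.integer(minibatch), epochs = as.integer(epochs),
                 lr = lr, max_steps = max_steps,
                 stop_window = as.integer(stop_window), stop_tol = stop_tol,
                 seed = as.integer(seed)),
            class = "tg_policy_config")
}

#' Fuse decoder output and context into the control state
#'
#' Fixed concatenation order: normalized CLI, one-hot neurostate, telemetry
#' summary, gaze summary (zeros plus a presence flag when the auxiliary gaze
#' stream is absent), communication history (time since last attempt, recent
#' attempt density, one-hot current gate).
#'
#' @param decoder_out list with `class` (CA/DA/SU) and `cli` in \[0,1\].
#' @param context list with `tel` (length 2), optional `gaze` (length 2),
#'   `comm` (length 2), and `gate` (GREEN/YELLOW/RED).
#' @return named numeric state vector (length 14).
#' @export
fuse_state <- function(decoder_out, context) {
  oh <- as.numeric(NEUROSTATES == decoder_out$class)
  if (sum(oh) != 1) tg_stop("fuse_state: unknown neurostate")
  gaze <- context$gaze
  gz <- if (is.null(gaze)) c(0, 0, 0) else c(as.numeric(gaze[1:2]), 1)
  gh <- as.numeric(GATES == (context$gate %||% "GREEN"))
  out <- c(cli = as.numeric(decoder_out$cli),
           y_ca = oh[1], y_da = oh[2], y_su = oh[3],
           tel1 = as.numeric(context$tel[1]), tel2 = as.numeric(context$tel[2]),
           gaze1 = gz[1], gaze2 = gz[2], gaze_flag = gz[3],
           comm1 = as.numeric(context$comm[1]), comm2 = as.numeric(context$comm[2]),
           g_green = gh[1], g_yellow = gh[2], g_red = gh[3])
  out
}

#' Map the engineer action to the traffic-light semaphore
#'
#' Order-preserving bijection OPEN -> GREEN, WARN -> YELLOW, BLOCK -> RED.
#'
#' @param eng_action one of OPEN/WARN/BLOCK.
#' @return one of GREEN/YELLOW/RED.
#' @export
map_semaphore <- function(eng_action) {
  i <- match(eng_action, ENG_ACTIONS)
  if (any(is.na(i))) tg_stop("map_semaphore: invalid engineer action")
  GATES[i]
}

#' Deterministic safety override of the communication gate
#'
#' Forces RED during surprise/startle episodes or when the normalized CLI
#' reaches the critical threshold (`cli >= kappa_red`, inequality as
#' defined); otherwise passes the policy gate through.
#'
#' @param gate proposed gate (GREEN/YELLOW/RED).
#' @param y_hat decoded neurostate.
#' @param cli_norm normalized CLI.
#' @param kappa_red critical threshold from calibration.
#' @return the enforced gate.
#' @export
safety_override <- function(gate, y_hat, cli_norm, kappa_red) {
  if (!gate %in% GATES) tg_stop("safety_override: invalid gate")
  if (identical(y_hat, "SU") || cli_norm >= kappa_red) "RED" else gate
}

#' Instantaneous reward and its components
#'
#' `r = ws r_safety + wp r_progress + wc r_comm - wl c_load - wh c_haptic`
#' with `r_safety = -I[near miss] - alpha max(0, RT - RT*)` (RT in seconds),
#' `r_progress = dscore - dtime`, `r_comm = I[attempt, GREEN] -
#' beta I[attempt, RED] - eta I[silent, GREEN]`, `c_load = CLI`,
#' `c_haptic = I[haptics HIGH]`.
#'
#' @param transition step transition (from [sim_env_step()] or compatible):
#'   needs `near_miss`, `hazard`, `rt_ms`, `dscore`, `dtime`, `attempt`,
#'   `gate`, `pilot`, and `cli_norm` (falls back to `cli_est`).
#' @param spec a [reward_spec()].
#' @return list with `reward` and the unweighted `components`
#'   (safety, progress, comm, load, haptic).
#' @export
compute_reward <- function(transition, spec = reward_spec()) {
  tr <- transition
  cli <- tr$cli_norm %||% tr$cli_est
  if (isTRUE(tr$hazard) && (is.null(tr$rt_ms) || is.na(tr$rt_ms))) {
    tg_stop("compute_reward: hazard step without a reaction time")
  }
  overshoot <- if (isTRUE(tr$hazard)) max(0, tr$rt_ms / 1000 - spec$rt_star_s) else 0
  r_safety <- -as.numeric(isTRUE(tr$near_miss)) - spec$alpha * overshoot
  r_progress <- tr$dscore - tr$dtime
  ut <- as.numeric(tr$attempt == 1)
  r_comm <- ut * (tr$gate == "GREEN") - spec$beta * ut * (tr$gate == "RED") -
    spec$eta * (1 - ut) * (tr$gate == "GREEN")
  c_load <- cli
  c_haptic <- as.numeric(tr$pilot == "HIGH")
  comp <- c(safety = r_safety, progress = r_progress, comm = r_comm,
            load = c_load, haptic = c_haptic)
  reward <- spec$ws * r_safety + spec$wp * r_progress + spec$wc * r_comm -
    spec$wl * c_load - spec$wh * c_haptic
  list(reward = reward, components = comp)
}

#' Per-step constraint cost signals
#'
#' `d_load = I[CLI > tau]`, `d_cbe = I[attempt while RED]`.
#'
#' @param transition step transition (as in [compute_reward()]).
#' @param tau calibrated moderate-overload threshold.
#' @return numeric vector `(d_load, d_cbe)`.
#' @export
cost_signals <- function(transition, tau) {
  cli <- transition$cli_norm %||% transition$cli_est
  c(d_load = as.numeric(cli > tau),
    d_cbe = as.numeric(transition$attempt == 1 && transition$gate == "RED"))
}

#' Episodic constraint costs
#'
#' Overload cost is the time-average of `d_load`; the communication cost is
#' the episode sum of `d_cbe`.
#'
#' @param d_load,d_cbe per-step cost indicator vectors.
#' @return numeric vector `(C_load, C_cbe)`.
#' @export
episodic_costs <- function(d_load, d_cbe) {
  c(C_load = mean(d_load), C_cbe = sum(d_cbe))
}

#' Generalized advantage estimation
#'
#' Standard exponentially weighted sum of TD errors: `lambda = 0` reduces to
#' one-step TD residuals, `lambda = 1` to discounted return minus baseline.
#'
#' @param rewards per-step rewards.
#' @param values per-step state values (same length).
#' @param gamma discount factor.
#' @param lambda GAE parameter.
#' @param bootstrap value of the state after the last step (0 at terminal).
#' @return advantage vector.
#' @export
gae <- function(rewards, values, gamma = 0.99, lambda = 0.95, bootstrap = 0) {
  n <- length(rewards)
  if (length(values) != n) tg_stop("gae: rewards and values must have equal length")
  adv <- numeric(n)
  next_v <- bootstrap
  acc <- 0
  for (t in n:1) {
    delta <- rewards[t] + gamma * next_v - values[t]
    acc <- delta + gamma * lambda * acc
    adv[t] <- acc
    next_v <- values[t]
  }
  adv
}

#' Projected dual ascent on the Lagrange multipliers
#'
#' `lambda_i <- max(0, lambda_i + eta_lambda (C_i - eps_i))`: the projection
#' keeps multipliers nonnegative, and a larger measured cost never yields a
#' smaller multiplier.
#'
#' @param cs a [constraint_state()].
#' @param measured named costs `C_load`, `C_cbe` from the last batch.
#' @return updated constraint state.
#' @export
dual_update <- function(cs, measured) {
  stopifnot(inherits(cs, "tg_constraint_state"))
  cap <- cs$lambda_max %||% Inf
  cs$lambda_load <- min(cap, max(0, cs$lambda_load +
                          cs$eta_lambda * (measured[["C_load"]] - cs$eps_load)))
  cs$lambda_cbe <- min(cap, max(0, cs$lambda_cbe +
                         cs$eta_lambda * (measured[["C_cbe"]] - cs$eps_cbe)))
  cs
}

# --- policy network ------------------------------------------------------

mlp_heads_init <- function(d_in, h = 64L) {
  list(A1 = glorot(d_in, h), a1 = numeric(h),
       A2 = glorot(h, h), a2 = numeric(h),
       Hp = glorot(h, 3), hp = numeric(3),
       He = glorot(h, 3), he = numeric(3),
       C1 = glorot(d_in, h), c1 = numeric(h),
       C2 = glorot(h, h), c2 = numeric(h),
       Cv = glorot(h, 1), cv = numeric(1))
}

#' Build an untrained joint policy
#'
#' One shared two-layer tanh network with two categorical heads (pilot
#' haptics OFF/LOW/HIGH, engineer gate OPEN/WARN/BLOCK) and a separate
#' centralized critic over the fused state.
#'
#' @param d_in fused-state dimension.
#' @param config a [policy_config()].
#' @return object of class `tg_policy`.
#' @export
build_policy <- function(d_in, config = policy_config()) {
  set.seed(config$seed)
  structure(list(params = mlp_heads_init(d_in), d_in = d_in, config = config),
            class = "tg_policy")
}

policy_fwd <- function(p, X) {
  # X: [N, d]
  z1 <- tanh(X %*% p$A1 + rep(p$a1, each = nrow(X)))
  z2 <- tanh(z1 %*% p$A2 + rep(p$a2, each = nrow(X)))
  lp <- z2 %*% p$Hp + rep(p$hp, each = nrow(X))
  le <- z2 %*% p$He + rep(p$he, each = nrow(X))
  v1 <- tanh(X %*% p$C1 + rep(p$c1, each = nrow(X)))
  v2 <- tanh(v1 %*% p$C2 + rep(p$c2, each = nrow(X)))
  v <- as.vector(v2 %*% p$Cv) + as.numeric(p$cv)
  list(pp = softmax_rows(lp), pe = softmax_rows(le), v = v,
       z1 = z1, z2 = z2, v1 = v1, v2 = v2)
}

#' Sample a joint action from the policy
#'
#' @param policy a `tg_policy`.
#' @param state fused-state vector.
#' @param deterministic take the modal action of each head instead of
#'   sampling (evaluation-time execution).
#' @return list with `pilot`, `eng` (labels), indices, and the joint log
#'   probability.
#' @export
policy_act <- function(policy, state, deterministic = FALSE) {
  fw <- policy_fwd(policy$params, matrix(state, 1))
  if (deterministic) {
    ip <- which.max(fw$pp)
    ie <- which.max(fw$pe)
  } else {
    ip <- sample.int(3L, 1L, prob = fw$pp)
    ie <- sample.int(3L, 1L, prob = fw$pe)
  }
  list(pilot = names(HAPTIC_LEVELS)[ip], eng = ENG_ACTIONS[ie],
       ip = ip, ie = ie,
       logp = log(fw$pp[ip]) + log(fw$pe[ie]), value = fw$v)
}

# clipped-surrogate + entropy + value loss over one minibatch; returns grads
policy_grads <- function(p, X, ip, ie, logp_old, adv, ret, clip, ent_coef) {
  N <- nrow(X)
  fw <- policy_fwd(p, X)
  lp_new <- log(pmax(fw$pp[cbind(seq_len(N), ip)], 1e-12)) +
    log(pmax(fw$pe[cbind(seq_len(N), ie)], 1e-12))
  ratio <- exp(lp_new - logp_old)
  unclipped <- ratio * adv
  clipped <- pmin(pmax(ratio, 1 - clip), 1 + clip) * adv
  use <- as.numeric(unclipped <= clipped)   # gradient flows where min picks r*A
  gr_r <- use * adv * ratio / N             # d(-obj)/dlogp = -gr_r
  dlp <- -gr_r
  oh_p <- matrix(0, N, 3); oh_p[cbind(seq_len(N), ip)] <- 1
  oh_e <- matrix(0, N, 3); oh_e[cbind(seq_len(N), ie)] <- 1
  dLp <- dlp * (oh_p - fw$pp)
  dLe <- dlp * (oh_e - fw$pe)
  # entropy bonus gradients: dH/dz = -p (log p + H)
  Hp <- -rowSums(fw$pp * log(pmax(fw$pp, 1e-12)))
  He <- -rowSums(fw$pe * log(pmax(fw$pe, 1e-12)))
  dLp <- dLp - ent_coef * (-fw$pp * (log(pmax(fw$pp, 1e-12)) + Hp)) / N
  dLe <- dLe - ent_coef * (-fw$pe * (log(pmax(fw$pe, 1e-12)) + He)) / N
  g <- list()
  g$Hp <- crossprod(fw$z2, dLp); g$hp <- colSums(dLp)
  g$He <- crossprod(fw$z2, dLe); g$he <- colSums(dLe)
  dz2 <- (dLp %*% t(p$Hp) + dLe %*% t(p$He)) * (1 - fw$z2^2)
  g$A2 <- crossprod(fw$z1, dz2); g$a2 <- colSums(dz2)
  dz1 <- (dz2 %*% t(p$A2)) * (1 - fw$z1^2)
  g$A1 <- crossprod(X, dz1); g$a1 <- colSums(dz1)
  # critic
  dv <- (fw$v - ret) / N
  dv2 <- outer(dv, as.vector(p$Cv)) * (1 - fw$v2^2)
  g$Cv <- crossprod(fw$v2, matrix(dv, ncol = 1)); g$cv <- sum(dv)
  g$C2 <- crossprod(fw$v1, dv2); g$c2 <- colSums(dv2)
  dv1 <- (dv2 %*% t(p$C2)) * (1 - fw$v1^2)
  g$C1 <- crossprod(X, dv1); g$c1 <- colSums(dv1)
  loss <- -mean(pmin(unclipped, clipped)) + 0.5 * mean((fw$v - ret)^2) -
    ent_coef * mean(Hp + He)
  list(grads = g, loss = loss, entropy = mean(Hp + He))
}

#' One constrained MAPPO update from a collected rollout
#'
#' Clipped-surrogate optimization of the Lagrangian-shaped reward (the
#' episodic constraint penalties are distributed per step, the standard
#' primal-dual reduction), with projected dual ascent on the multipliers
#' after each policy minibatch step.
#'
#' @param policy a `tg_policy`.
#' @param rollout list with `X` (states, rows), `ip`, `ie` (action indices),
#'   `logp` (behavior log-probs), `adv`, `ret`, and `costs` (named measured
#'   episodic costs `C_load`, `C_cbe`).
#' @param cs a [constraint_state()].
#' @param adam_state optional persistent Adam state.
#' @return list with updated `policy`, `cs`, `adam_state`, mean `loss` and
#'   `entropy`.
#' @export
mappo_update <- function(policy, rollout, cs, adam_state = NULL) {
  cfg <- policy$config
  n <- nrow(rollout$X)
  adv <- rollout$adv
  adv <- (adv - mean(adv)) / (sd(adv) + 1e-8)
  if (is.null(adam_state)) adam_state <- adam_init(policy$params)
  losses <- ents <- c()
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    for (i in seq(1, n, by = cfg$minibatch)) {
      idx <- ord[i:min(n, i + cfg$minibatch - 1L)]
      pg <- policy_grads(policy$params, rollout$X[idx, , drop = FALSE],
                         rollout$ip[idx], rollout$ie[idx],
                         rollout$logp[idx], adv[idx], rollout$ret[idx],
                         cfg$clip, cfg$entropy_coef)
      if (!is.finite(pg$loss)) tg_stop("mappo_update: non-finite loss; diverged")
      upd <- adam_step(policy$params, pg$grads, adam_state,
                       lr = cfg$lr, weight_decay = 0)
      policy$params <- upd$params
      adam_state <- upd$state
      cs <- dual_update(cs, rollout$costs)   # projected step per policy step
      losses <- c(losses, pg$loss); ents <- c(ents, pg$entropy)
    }
  }
  list(policy = policy, cs = cs, adam_state = adam_state,
       loss = mean(losses), entropy = mean(ents))
}

#' Train the dual-loop controller against an environment
#'
#' Alternates rollout collection, constrained MAPPO updates, and dual
#' updates; stops when the mean episodic reward stabilizes (relative
#' variation below `stop_tol` over `stop_window` iterations) or at the step
#' cap.
#'
#' @param env_factory zero-argument function returning a fresh environment
#'   adapter: a list with `reset()` giving the initial state vector and
#'   `step(ip, ie)` giving `list(state, reward, done, d_load, d_cbe)`.
#' @param pcfg a [policy_config()].
#' @param cs a [constraint_state()].
#' @return `tg_policy_bundle`: list with `policy`, `cs`, and the per-iteration
#'   `log` (mean episodic reward, measured costs, multipliers, entropy).
#' @export
train_controller <- function(env_factory, pcfg = policy_config(),
                             cs = constraint_state()) {
  stopifnot(inherits(pcfg, "tg_policy_config"))
  set.seed(pcfg$seed)
  env <- env_factory()
  s <- env$reset()
  policy <- build_policy(length(s), pcfg)
  adam_state <- NULL
  total_steps <- 0
  log <- NULL
  ep_rewards <- c()       # completed-episode rewards (rolling)
  cur_ep_reward <- 0
  cur_costs <- c(0, 0); cur_len <- 0L
  done_costs <- NULL
  iter <- 0L
  while (total_steps < pcfg$max_steps) {
    iter <- iter + 1L
    Tn <- pcfg$rollout
    X <- matrix(0, Tn, length(s))
    ip <- ie <- integer(Tn)
    logp <- rew <- val <- numeric(Tn)
    done <- logical(Tn)
    dl <- db <- numeric(Tn)
    for (t in seq_len(Tn)) {
      a <- policy_act(policy, s)
      stp <- env$step(a$ip, a$ie)
      shaped <- stp$reward - cs$lambda_load * stp$d_load -
        cs$lambda_cbe * stp$d_cbe
      X[t, ] <- s; ip[t] <- a$ip; ie[t] <- a$ie
      logp[t] <- a$logp; val[t] <- a$value
      rew[t] <- shaped; done[t] <- stp$done
      dl[t] <- stp$d_load; db[t] <- stp$d_cbe
      cur_ep_reward <- cur_ep_reward + stp$reward
      cur_costs <- cur_costs + c(stp$d_load, stp$d_cbe)
      cur_len <- cur_len + 1L
      if (stp$done) {
        ep_rewards <- c(ep_rewards, cur_ep_reward)
        done_costs <- rbind(done_costs,
                            c(C_load = cur_costs[1] / cur_len,
                              C_cbe = cur_costs[2]))
        cur_ep_reward <- 0; cur_costs <- c(0, 0); cur_len <- 0L
        env <- env_factory()
        s <- env$reset()
      } else {
        s <- stp$state
      }
    }
    total_steps <- total_steps + Tn
    # GAE over episode segments within the rollout
    bounds <- c(0, which(done), Tn)
    bounds <- unique(bounds)
    adv <- numeric(Tn)
    for (bi in seq_len(length(bounds) - 1L)) {
      seg <- (bounds[bi] + 1L):bounds[bi + 1L]
      boot <- if (done[bounds[bi + 1L]]) 0 else
        policy_act(policy, s)$value  # value of the carried-over state
      adv[seg] <- gae(rew[seg], val[seg], pcfg$gamma, pcfg$gae_lambda, boot)
    }
    ret <- adv + val
    costs <- if (is.null(done_costs)) c(C_load = mean(dl), C_cbe = sum(db)) else
      c(C_load = mean(tail(done_costs[, 1], 10)),
        C_cbe = mean(tail(done_costs[, 2], 10)))
    upd <- mappo_update(policy, list(X = X, ip = ip, ie = ie, logp = logp,
                                     adv = adv, ret = ret, costs = costs), cs,
                        adam_state)
    policy <- upd$policy; cs <- upd$cs; adam_state <- upd$adam_state
    mean_ep <- if (length(ep_rewards)) mean(tail(ep_rewards, 10)) else NA_real_
    log <- rbind(log, data.frame(iter = iter, steps = total_steps,
                                 mean_ep_reward = mean_ep,
                                 C_load = costs[["C_load"]],
                                 C_cbe = costs[["C_cbe"]],
                                 lambda_load = cs$lambda_load,
                                 lambda_cbe = cs$lambda_cbe,
                                 entropy = upd$entropy, loss = upd$loss))
    # divergence guard
    if (iter >= 50 && all(diff(tail(log$mean_ep_reward, 50)) < 0) &&
        tail(log$mean_ep_reward, 1) < -1e6) {
      tg_stop("train_controller: reward diverging; aborting")
    }
    # stop rule: relative variation of the episodic reward
    if (nrow(log) >= pcfg$stop_window) {
      w <- tail(log$mean_ep_reward, pcfg$stop_window)
      if (all(is.finite(w)) &&
          (max(w) - min(w)) <= pcfg$stop_tol * max(abs(mean(w)), 1e-8)) break
    }
  }
  structure(list(policy = policy, cs = cs, log = log), class = "tg_policy_bundle")
}

#' @export
print.tg_policy_bundle <- function(x, ...) {
  n <- nrow(x$log)
  cat(sprintf("<tg_policy_bundle> %d iterations, %d steps, mean ep reward %.3f, lambda = (%.4g, %.4g)\n",
              n, x$log$steps[n], x$log$mean_ep_reward[n],
              x$cs$lambda_load, x$cs$lambda_cbe))
  invisible(x)
}

# --- environment adapters ------------------------------------------------

#' Adapter: simulator environment for controller training
#'
#' Serves fused states built from the environment's decoder-surrogate
#' observations (noisy latent load as CLI, ground-truth class with label
#' noise), applies the safety override to the policy gate, and returns the
#' reward and constraint signals.
#'
#' @param make_config function(seed) returning a [session_config()] (fresh
#'   seed per episode).
#' @param tau,kappa_red calibrated thresholds used for the override and the
#'   load cost.
#' @param rspec a [reward_spec()].
#' @param seed0 base seed; incremented per episode.
#' @return zero-argument environment factory for [train_controller()].
#' @export
make_sim_env_factory <- function(make_config, tau, kappa_red,
                                 rspec = reward_spec(), seed0 = 1L) {
  counter <- new.env(parent = emptyenv())
  counter$k <- 0L
  function() {
    counter$k <- counter$k + 1L
    cfg <- make_config(seed0 + counter$k)
    st <- NULL
    obs <- NULL
    gate_prev <- "GREEN"
    fuse <- function(o) {
      fuse_state(list(class = o$class_obs, cli = o$cli_est),
                 list(tel = o$tel, gaze = o$gaze, comm = o$comm,
                      gate = gate_prev))
    }
    list(
      reset = function() {
        st <<- sim_env_init(cfg)
        obs <<- sim_env_observe(st)
        fuse(obs)
      },
      step = function(ip, ie) {
        gate <- safety_override(map_semaphore(ENG_ACTIONS[ie]),
                                obs$class_obs, obs$cli_est, kappa_red)
        tr <- sim_env_step(st, list(pilot = names(HAPTIC_LEVELS)[ip],
                                    eng = ENG_ACTIONS[ie], gate = gate), obs)
        gate_prev <<- tr$gate
        rw <- compute_reward(tr, rspec)
        cost <- cost_signals(tr, tau)
        state <- NULL
        if (!tr$done) {
          obs <<- sim_env_observe(st)
          state <- fuse(obs)
        }
        list(state = state, reward = rw$reward, done = tr$done,
             d_load = cost[["d_load"]], d_cbe = cost[["d_cbe"]])
      })
  }
}

#' Toy communication-gating environment
#'
#' Two-state overload process; engineer speech attempts arrive with
#' gate-dependent compliance, an attempt while RED always incurs the beta
#' penalty (and counts toward the CBE budget), an attempt while the gate is
#' GREEN during overload causes interference, and an attempt under YELLOW
#' during overload causes milder delayed interference. Without the CBE
#' constraint, blocking during overload maximizes reward; the constraint
#' forces the learned policy toward WARN.
#'
#' @param episode_steps episode length.
#' @param seed0 base seed, incremented per episode.
#' @return environment factory for [train_controller()].
#' @export
make_toy_gating_env <- function(episode_steps = 200L, seed0 = 1L) {
  counter <- new.env(parent = emptyenv())
  counter$k <- 0L
  function() {
    counter$k <- counter$k + 1L
    seed <- seed0 + counter$k
    st <- new.env(parent = emptyenv())
    obsvec <- function() c(overload = st$o, bias = 1,
                           g = as.numeric(GATES == st$gate))
    list(
      reset = function() {
        set.seed(seed)
        st$o <- 0; st$t <- 0L; st$gate <- "GREEN"
        obsvec()
      },
      step = function(ip, ie) {
        gate <- map_semaphore(ENG_ACTIONS[ie])
        comp <- c(GREEN = 1, YELLOW = 0.4, RED = 0.12)[[gate]]
        attempt <- as.numeric(runif(1) < 0.25 * comp)
        r <- 0
        if (attempt == 1 && gate == "GREEN") r <- r + ifelse(st$o == 1, -2, 1)
        if (attempt == 1 && gate == "YELLOW" && st$o == 1) r <- r - 1
        if (attempt == 1 && gate == "RED") r <- r - 2.5
        d_cbe <- as.numeric(attempt == 1 && gate == "RED")
        # overload Markov chain
        st$o <- if (st$o == 1) as.numeric(runif(1) < 0.9) else
          as.numeric(runif(1) < 0.12)
        st$gate <- gate
        st$t <- st$t + 1L
        list(state = obsvec(), reward = r, done = st$t >= episode_steps,
             d_load = 0, d_cbe = d_cbe)
      })
  }
}
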