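# Session- and condition-level outcome metrics and repeated-measures
# statistics: communication breakdown errors (CBE), overload exposure,
# peak-load masking, percent reductions, one-way within-subject ANOVA with
# Greenhouse-Geisser correction, and Bonferroni-adjusted paired contrasts.

#' Count communication breakdown errors
#'
#' A CBE is an engineer speech attempt emitted while the semaphore is RED.
#'
#' @param comm data.frame of speech attempts with a `gate` column (the
#'   semaphore at emission), or a `tg_session` (its `comm` log is used).
#' @return integer count.
#' @export
count_cbe <- function(comm) {
  if (inherits(comm, "tg_session")) comm <- comm$comm
  if (is.null(comm$gate)) {
    tg_stop("count_cbe: attempts carry no semaphore annotation")
  }
  sum(comm$gate == "RED")
}

#' Counterfactual override-only gate
#'
#' The gate the deterministic safety override alone would have displayed
#' (RED during SU or when CLI >= kappa_red, GREEN otherwise). Used to score
#' CBE in conditions without gating, where the logged gate is identically
#' GREEN and the raw count would be trivially zero.
#'
#' @param class neurostate per step.
#' @param cli normalized CLI per step.
#' @param kappa_red critical threshold.
#' @return character vector of gates.
#' @export
counterfactual_gate <- function(class, cli, kappa_red) {
  ifelse(class == "SU" | cli >= kappa_red, "RED", "GREEN")
}

#' Overload exposure
#'
#' Percentage of windows with normalized CLI strictly above tau.
#'
#' @param cli_norm normalized CLI trace.
#' @param tau calibrated threshold.
#' @return percentage in \[0, 100\].
#' @export
overload_exposure <- function(cli_norm, tau) {
  100 * mean(cli_norm > tau)
}

#' Peak-load window mask
#'
#' Union of the overload criterion (CLI > tau) and the 2.5 s
#' post-perturbation interval applied to the window grid.
#'
#' @param times window start times (s).
#' @param cli_norm normalized CLI per window.
#' @param tau overload threshold.
#' @param perturbation_markers perturbation onset times (s).
#' @param su_window_s post-perturbation interval (default 2.5).
#' @return logical mask over windows.
#' @export
peak_load_mask <- function(times, cli_norm, tau, perturbation_markers,
                           su_window_s = 2.5) {
  over <- cli_norm > tau
  post <- rep(FALSE, length(times))
  for (m in perturbation_markers) {
    post <- post | (times >= m & times < m + su_window_s)
  }
  over | post
}

#' Percent reduction of an outcome
#'
#' @param baseline,treated outcome under baseline and treatment
#'   (`baseline > 0`).
#' @return `100 (baseline - treated) / baseline`, one decimal.
#' @export
percent_reduction <- function(baseline, treated) {
  if (baseline <= 0) tg_stop("percent_reduction: baseline must be positive")
  round(100 * (baseline - treated) / baseline, 1)
}

#' One-way repeated-measures ANOVA
#'
#' Within-subject decomposition (condition effect after subject removal),
#' partial eta-squared, and the Greenhouse-Geisser sphericity correction
#' estimated from the covariance of the condition scores.
#'
#' @param tab subjects x conditions numeric matrix (complete design).
#' @return list with `F`, `df` (numerator, denominator), `p`,
#'   `partial_eta2`, `gg_epsilon`, `p_gg`, and the sums of squares.
#' @export
rm_anova <- function(tab) {
  tab <- as.matrix(tab)
  if (anyNA(tab)) tg_stop("rm_anova: design has missing cells")
  n <- nrow(tab); k <- ncol(tab)
  if (k < 2 || n < 3) tg_stop("rm_anova: need >= 2 conditions and >= 3 subjects")
  grand <- mean(tab)
  ss_subj <- k * sum((rowMeans(tab) - grand)^2)
  ss_cond <- n * sum((colMeans(tab) - grand)^2)
  ss_tot <- sum((tab - grand)^2)
  ss_err <- ss_tot - ss_subj - ss_cond
  df1 <- k - 1
  df2 <- (n - 1) * (k - 1)
  Fv <- if (ss_err < .Machine$double.eps) {
    if (ss_cond < .Machine$double.eps) 0 else Inf
  } else (ss_cond / df1) / (ss_err / df2)
  p <- pf(Fv, df1, df2, lower.tail = FALSE)
  # Greenhouse-Geisser epsilon from the double-centered covariance
  S <- stats::cov(tab)
  Sc <- sweep(sweep(S, 1, rowMeans(S)), 2, colMeans(S)) + mean(S)
  eps <- if (sum(Sc^2) < .Machine$double.eps) 1 else
    sum(diag(Sc))^2 / ((k - 1) * sum(Sc^2))
  eps <- min(1, max(eps, 1 / (k - 1)))
  p_gg <- pf(Fv, eps * df1, eps * df2, lower.tail = FALSE)
  list(F = Fv, df = c(df1, df2), p = p,
       partial_eta2 = ss_cond / (ss_cond + ss_err),
       gg_epsilon = eps, p_gg = p_gg,
       ss = c(condition = ss_cond, subject = ss_subj, error = ss_err))
}

#' Bonferroni-adjusted paired contrast
#'
#' Paired t-test with Cohen's d for paired comparisons
#' (`d = mean(diff)/sd(diff)`) and the t-quantile confidence interval of the
#' mean difference; the Bonferroni factor defaults to the 6 pairwise
#' contrasts of a 4-condition design.
#'
#' @param tab subjects x conditions matrix.
#' @param pair length-2 vector of condition columns (names or indices);
#'   the difference is `pair[1] - pair[2]`.
#' @param n_contrasts Bonferroni multiplier.
#' @param conf_level confidence level.
#' @return list with `t`, `df`, `p`, `p_bonferroni`, `cohens_d`,
#'   `mean_diff`, `ci`.
#' @export
posthoc_paired <- function(tab, pair, n_contrasts = 6, conf_level = 0.95) {
  tab <- as.matrix(tab)
  d <- tab[, pair[1]] - tab[, pair[2]]
  if (sd(d) < .Machine$double.eps) {
    if (all(abs(d - d[1]) < .Machine$double.eps) && abs(d[1]) > 0) {
      tg_stop("posthoc_paired: degenerate differences (zero variance)")
    }
    if (all(d == 0)) {
      return(list(t = 0, df = length(d) - 1, p = 1, p_bonferroni = 1,
                  cohens_d = 0, mean_diff = 0, ci = c(0, 0)))
    }
  }
  tt <- t.test(d, conf.level = conf_level)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, p_bonferroni = min(1, tt$p.value * n_contrasts),
       cohens_d = mean(d) / sd(d), mean_diff = mean(d),
       ci = as.numeric(tt$conf.int))
}

#' Session-level outcome metrics
#'
#' Task-phase outcomes of one session: CBE (counterfactual override-only
#' gate when the condition never displayed a gate), reaction-time mean/SD,
#' near misses, overload exposure, message count, completion time, and the
#' peak-load mask summary.
#'
#' @param session a `tg_session`.
#' @param cli a [session_cli()] result (trace + profile) for the session.
#' @param target_score task score defining completion (default: the score a
#'   nominal zero-load run would reach, so completion time is in seconds).
#' @param cf counterfactual-gate rule for ungated conditions: list with
#'   `kappa` (threshold) and `source` (`"norm"` for the spectral-pipeline
#'   CLI, `"est"` for the runtime decoder-surrogate estimate). Defaults to
#'   the calibrated profile threshold on the pipeline CLI. Pass the
#'   runtime override's own threshold/source to score open-loop CBE against
#'   exactly the gate rule the gated conditions experienced.
#' @return one-row data.frame of class `tg_session_metrics`.
#' @export
session_metrics <- function(session, cli, target_score = NULL, cf = NULL) {
  stopifnot(inherits(session, "tg_session"))
  cfg <- session$config
  trace <- cli$trace[cli$trace$phase == "task", ]
  prof <- cli$profile
  steps <- session$steps
  # align per-step CLI with the spectral trace by window time
  idx <- match(round(steps$time_s, 6), round(trace$start_s, 6))
  cli_step <- trace$cli_norm[idx]
  cli_step[is.na(cli_step)] <- trace$cli_norm[nrow(trace)]
  gated <- cfg$condition %in% c("ENGINEER_ONLY", "DUAL_LOOP")
  if (gated) {
    cbe <- count_cbe(session$comm)
  } else {
    cf <- cf %||% list(kappa = prof$kappa_red, source = "norm")
    cf_cli <- if (identical(cf$source, "est")) steps$cli_est else cli_step
    gate_cf <- counterfactual_gate(steps$class_obs, cf_cli, cf$kappa)
    cbe <- sum(steps$attempt == 1L & gate_cf == "RED")
  }
  pert <- session$schedule$onset_s[session$schedule$type == "PERTURBATION"]
  peak <- peak_load_mask(trace$start_s, trace$cli_norm, prof$tau, pert,
                         cfg$latent$su_window_s)
  rate <- session$score / cfg$duration_s
  tgt <- target_score %||% (1.5 - 0.8 * cfg$latent$baseline) * cfg$duration_s
  out <- data.frame(
    condition = cfg$condition,
    cbe = cbe,
    rt_mean_ms = if (nrow(session$outcomes)) mean(session$outcomes$rt_ms) else NA_real_,
    rt_sd_ms = if (nrow(session$outcomes)) sd(session$outcomes$rt_ms) else NA_real_,
    near_misses = sum(session$outcomes$near_miss),
    overload_pct = overload_exposure(trace$cli_norm, prof$tau),
    messages = nrow(session$comm),
    completion_time_s = tgt / rate,
    peak_load_pct = 100 * mean(peak),
    attempts_per_min = nrow(session$comm) / cfg$duration_s * 60,
    iai_var = if (nrow(session$comm) > 2) var(diff(session$comm$time_s)) else NA_real_,
    stringsAsFactors = FALSE)
  class(out) <- c("tg_session_metrics", "data.frame")
  out
}

#' Condition-level report
#'
#' Descriptive mean +/- SD per condition for the joint outcomes (RT, CBE,
#' overload exposure, messages per session) and, when the design is complete
#' with at least two conditions, the one-way repeated-measures inferential
#' block with the dual-loop vs open-loop paired contrast.
#'
#' @param metrics data.frame with columns `pair`, `condition` and the
#'   outcome columns `rt_mean_ms`, `cbe`, `overload_pct`, `messages`
#'   (one row per session).
#' @return list of class `tg_condition_report` with `descriptives`,
#'   `inferential` (possibly NULL), and the wide outcome tables.
#' @export
condition_report <- function(metrics) {
  outs <- c("rt_mean_ms", "cbe", "overload_pct", "messages")
  conds <- unique(metrics$condition)
  desc <- do.call(rbind, lapply(split(metrics, metrics$condition), function(d) {
    row <- data.frame(condition = d$condition[1], n = nrow(d),
                      stringsAsFactors = FALSE)
    for (o in outs) {
      row[[paste0(o, "_mean")]] <- mean(d[[o]], na.rm = TRUE)
      row[[paste0(o, "_sd")]] <- sd(d[[o]], na.rm = TRUE)
    }
    row
  }))
  tables <- lapply(outs, function(o) {
    w <- tapply(metrics[[o]], list(metrics$pair, metrics$condition), mean)
    w[, intersect(c("OPEN_LOOP", "PILOT_ONLY", "ENGINEER_ONLY", "DUAL_LOOP"),
                  colnames(w)), drop = FALSE]
  })
  names(tables) <- outs
  inferential <- NULL
  tab1 <- tables[[1]]
  if (length(conds) >= 2 && nrow(tab1) >= 3 && !anyNA(tab1)) {
    inferential <- lapply(tables, function(tb) {
      res <- list(anova = rm_anova(tb))
      if (all(c("DUAL_LOOP", "OPEN_LOOP") %in% colnames(tb))) {
        res$dual_vs_open <- posthoc_paired(tb, c("OPEN_LOOP", "DUAL_LOOP"),
                                           n_contrasts = choose(ncol(tb), 2))
      }
      res
    })
  }
  structure(list(descriptives = desc, tables = tables,
                 inferential = inferential),
            class = "tg_condition_report")
}

#' @export
print.tg_condition_report <- function(x, ...) {
  cat("<tg_condition_report>\n")
  print(x$descriptives, row.names = FALSE)
  if (!is.null(x$inferential)) {
    for (o in names(x$inferential)) {
      a <- x$inferential[[o]]$anova
      cat(sprintf("%s: F(%g, %g) = %.2f, p = %.4g (GG p = %.4g), eta_p^2 = %.2f\n",
                  o, a$df[1], a$df[2], a$F, a$p, a$p_gg, a$partial_eta2))
    }
  }
  invisible(x)
}
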