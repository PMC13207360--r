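test_that("CBE counts RED-state attempts and is additive over partitions", {
  comm <- data.frame(time_s = c(1, 2, 3), gate = c("RED", "GREEN", "RED"))
  expect_equal(count_cbe(comm), 2)
  expect_equal(count_cbe(comm[0, ]), 0)
  expect_error(count_cbe(data.frame(time_s = 1)), "semaphore")
  set.seed(12)
  big <- data.frame(time_s = sort(runif(200, 0, 100)),
                    gate = sample(c("GREEN", "YELLOW", "RED"), 200, TRUE))
  cut <- big$time_s < 40
  expect_equal(count_cbe(big), count_cbe(big[cut, ]) + count_cbe(big[!cut, ]))
})

test_that("counterfactual override-only gate recovers open-loop CBE", {
  cls <- c("CA", "SU", "CA", "DA", "CA")
  cli <- c(0.1, 0.2, 0.95, 0.3, 0.5)
  g <- counterfactual_gate(cls, cli, 0.9)
  expect_equal(g, c("GREEN", "RED", "RED", "GREEN", "GREEN"))
})

test_that("overload exposure and peak-load mask behave on the window grid", {
  expect_equal(overload_exposure(c(rep(1, 3), rep(0, 7)), 0.5), 30)
  expect_equal(overload_exposure(rep(0, 5), 0.5), 0)
  expect_equal(overload_exposure(rep(1, 5), 0.5), 100)
  times <- seq(0, 9.9, by = 0.1)
  cli <- rep(0.2, length(times))
  expect_false(any(peak_load_mask(times, cli, 0.5, numeric(0))))
  m <- peak_load_mask(times, cli, 0.5, 4)
  expect_true(all(m[times >= 4 & times < 6.5]))
  expect_false(any(m[times < 4 | times >= 6.5]))
  cli[3] <- 0.9
  expect_true(peak_load_mask(times, cli, 0.5, 4)[3])
  # monotone: lowering tau never shrinks the mask
  m1 <- peak_load_mask(times, cli, 0.5, 4)
  m2 <- peak_load_mask(times, cli, 0.3, 4)
  expect_true(all(m2[m1]))
})

test_that("percent reduction reproduces the printed contrasts", {
  expect_equal(percent_reduction(487, 219), 55.0)
  expect_equal(percent_reduction(14.2, 7.6), 46.5)
  expect_equal(percent_reduction(5, 5), 0)
  expect_error(percent_reduction(0, 1), "positive")
})

test_that("repeated-measures ANOVA matches the SS oracle and the F = t^2 identity", {
  set.seed(13)
  tab <- matrix(rnorm(25 * 4, mean = rep(c(10, 8, 9, 7), each = 25)), 25, 4)
  res <- rm_anova(tab)
  ss <- ss_oracle(tab)
  expect_equal(unname(res$ss), unname(ss[c("condition", "subject", "error")]),
               tolerance = 1e-9)
  expect_equal(res$partial_eta2, ss["condition"] / (ss["condition"] + ss["error"]),
               ignore_attr = TRUE)
  # two-condition table: F equals the squared paired t statistic
  t2 <- matrix(rnorm(30), 15, 2)
  res2 <- rm_anova(t2)
  tt <- t.test(t2[, 1], t2[, 2], paired = TRUE)
  expect_equal(res2$F, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(res2$p, tt$p.value, tolerance = 1e-9)
  # flat table: F = 0
  expect_equal(rm_anova(matrix(5, 10, 3))$F, 0)
  expect_error(rm_anova(matrix(c(1, NA, 2, 3, 4, 5, 6, 7, 8), 3)), "missing")
})

test_that("Greenhouse-Geisser epsilon lies in its admissible range", {
  set.seed(14)
  tab <- matrix(rnorm(60), 15, 4)
  res <- rm_anova(tab)
  expect_gte(res$gg_epsilon, 1 / 3)
  expect_lte(res$gg_epsilon, 1)
  expect_gte(res$p_gg, res$p - 1e-12)  # correction never anti-conservative here
})

test_that("paired contrasts match the textbook formulas", {
  set.seed(15)
  a <- rnorm(20, 10); b <- rnorm(20, 9)
  tab <- cbind(A = a, B = b)
  res <- posthoc_paired(tab, c("A", "B"))
  d <- a - b
  expect_equal(res$t, mean(d) / (sd(d) / sqrt(20)), tolerance = 1e-10)
  expect_equal(res$cohens_d, mean(d) / sd(d), tolerance = 1e-12)
  ci <- mean(d) + qt(c(0.025, 0.975), 19) * sd(d) / sqrt(20)
  expect_equal(res$ci, ci, tolerance = 1e-10)
  expect_equal(res$p_bonferroni, min(1, res$p * 6))
  # identical columns: t = 0, d = 0
  same <- posthoc_paired(cbind(a, a), c(1, 2))
  expect_equal(same$t, 0); expect_equal(same$cohens_d, 0)
  # constant nonzero differences: degenerate
  expect_error(posthoc_paired(cbind(a, a - 1), c(1, 2)), "degenerate")
})

test_that("decoder metrics match a hand count and a tally oracle", {
  truth <- c("CA", "CA", "DA", "SU")
  pred <- c("CA", "DA", "DA", "SU")
  ev <- evaluate_decoder(pred, truth)
  expect_equal(ev$accuracy, 0.75)
  expect_equal(unname(ev$recall), c(0.5, 1, 1))
  expect_equal(ev$balanced_accuracy, mean(c(0.5, 1, 1)), tolerance = 1e-9)
  # balanced accuracy equals the mean row-normalized diagonal
  expect_equal(ev$balanced_accuracy, mean(diag(ev$confusion)), tolerance = 1e-12)
  perfect <- evaluate_decoder(truth, truth)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$macro_f1, 1)
  expect_equal(diag(perfect$confusion), rep(1, 3), ignore_attr = TRUE)
  # tally oracle on random labels
  set.seed(16)
  tr <- sample(NEUROSTATES, 1000, TRUE, prob = c(0.6, 0.3, 0.1))
  pr <- sample(NEUROSTATES, 1000, TRUE)
  ev2 <- evaluate_decoder(pr, tr)
  rec <- vapply(NEUROSTATES, function(k) sum(pr == k & tr == k) / sum(tr == k), 0)
  prec <- vapply(NEUROSTATES, function(k) sum(pr == k & tr == k) / sum(pr == k), 0)
  f1 <- 2 * prec * rec / (prec + rec)
  expect_equal(unname(ev2$recall), unname(rec), tolerance = 1e-12)
  expect_equal(ev2$macro_f1, mean(f1), tolerance = 1e-12)
  expect_warning(evaluate_decoder(c("CA", "CA"), c("CA", "DA")), "absent")
})

test_that("temporal stability summarizes adjacent agreement and CLI steps", {
  out <- list(labels = c("CA", "CA", "CA"), cli = c(0, 1, 0, 1))
  expect_equal(temporal_stability(out)$adjacent_agreement, 1)
  expect_equal(temporal_stability(out)$median_dcli, 1)
  expect_equal(temporal_stability(list(labels = c("CA", "DA", "CA"),
                                       cli = c(0, 0, 0)))$adjacent_agreement, 0)
  expect_error(temporal_stability(list(labels = "CA", cli = 0.5)), "at least 2")
})

test_that("condition reports carry descriptives and inferential blocks", {
  set.seed(17)
  conds <- c("OPEN_LOOP", "PILOT_ONLY", "ENGINEER_ONLY", "DUAL_LOOP")
  metrics <- do.call(rbind, lapply(1:8, function(p) {
    data.frame(pair = p, condition = conds,
               rt_mean_ms = rnorm(4, c(480, 220, 480, 230), 20),
               cbe = rpois(4, c(4, 4, 3, 2)),
               overload_pct = rnorm(4, c(14, 10, 14, 8)),
               messages = rpois(4, c(18, 19, 14, 13)))
  }))
  rep <- condition_report(metrics)
  expect_equal(nrow(rep$descriptives), 4)
  expect_false(is.null(rep$inferential))
  expect_true(rep$inferential$rt_mean_ms$anova$F > 0)
  expect_true(!is.null(rep$inferential$cbe$dual_vs_open))
  # single condition: descriptive block only
  rep1 <- condition_report(metrics[metrics$condition == "OPEN_LOOP", ])
  expect_null(rep1$inferential)
})
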