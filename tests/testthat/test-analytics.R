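# Performance indicators: exact formula checks against brute-force hand
# arithmetic, degenerate denominators, binning, chi-square, latencies.

fake_trials <- function(nc, ni, np, no) {
  n <- nc + ni + np + no
  data.frame(class = rep(c("correct", "incorrect", "premature", "omission"),
                         c(nc, ni, np, no)),
             response_latency_ms = rep(NA_real_, n),
             reward_latency_ms = rep(NA_real_, n))
}

test_that("the three percentage formulas match hand arithmetic exactly", {
  m <- compute_5csrtt_metrics(fake_trials(10, 5, 5, 5))
  expect_equal(m$accuracy, 100 * 10 / 15)       # 66.67
  expect_equal(m$pct_omissions, 20)
  expect_equal(m$pct_premature, 20)

  # 50 randomized fixture sessions against a brute-force recomputation
  set.seed(404)
  for (i in 1:50) {
    n <- sample(0:80, 4, replace = TRUE)
    tr <- fake_trials(n[1], n[2], n[3], n[4])
    tr <- tr[sample(nrow(tr)), , drop = FALSE]
    m <- compute_5csrtt_metrics(tr)
    total <- sum(n)
    expect_identical(m$n_trials, total)
    if (n[1] + n[2] > 0) {
      expect_identical(m$accuracy, 100 * n[1] / (n[1] + n[2]))
    } else {
      expect_true(is.na(m$accuracy))
    }
    if (total > 0) {
      expect_identical(m$pct_omissions, 100 * n[4] / total)
      expect_identical(m$pct_premature, 100 * n[3] / total)
    }
  }
})

test_that("degenerate denominators give NA markers, never 0 or 100", {
  m <- compute_5csrtt_metrics(fake_trials(0, 0, 0, 12))
  expect_true(is.na(m$accuracy))
  expect_equal(m$pct_omissions, 100)
  m2 <- compute_5csrtt_metrics(fake_trials(0, 0, 0, 0))
  expect_true(is.na(m2$accuracy))
  expect_true(is.na(m2$pct_omissions))
  expect_true(is.na(m2$mean_response_latency_ms))
})

test_that("accuracy complement identity holds when classes are swapped", {
  tr <- fake_trials(30, 12, 0, 0)
  sw <- tr
  sw$class <- ifelse(tr$class == "correct", "incorrect", "correct")
  expect_equal(compute_5csrtt_metrics(tr)$accuracy +
                 compute_5csrtt_metrics(sw)$accuracy, 100)
})

test_that("5-CSWM metrics separate phase denominators correctly", {
  tr <- data.frame(
    sp_class = c("correct", "correct", "correct", "incorrect", "omission"),
    cp_class = c("match", "nonmatch", "omission", NA, NA),
    sp_response_latency_ms = c(500, 700, 900, NA, NA),
    cp_response_latency_ms = c(400, 600, NA, NA, NA))
  m <- compute_5cswm_metrics(tr)
  expect_equal(m$sp_accuracy, 100 * 3 / 4)
  expect_equal(m$sp_pct_omissions, 20)
  expect_equal(m$cp_accuracy, 50)          # match / (match + nonmatch)
  expect_equal(m$n_cp_reached, 3)
  expect_equal(m$cp_pct_omissions, 100 / 3)
  # SP omissions contribute nothing to CP denominators
  m2 <- compute_5cswm_metrics(data.frame(sp_class = "omission",
                                         cp_class = NA,
                                         sp_response_latency_ms = NA,
                                         cp_response_latency_ms = NA))
  expect_true(is.na(m2$cp_accuracy))
  expect_equal(m2$sp_pct_omissions, 100)
})

test_that("a coin-flip choice-phase agent sits near 50% working-memory accuracy", {
  # always SP-correct; in the CP the target is matched with p = 0.5 so the
  # choice is uniform between the two lit holes
  # p_correct = 0.5 drives both phases with the same coin, so only
  # SP-correct trials reach the CP, where the choice is then 50/50
  log <- run_session(build_5cswm(),
                     stochastic_agent(agent_params(p_respond = 1,
                                                   p_correct = 0.5,
                                                   premature_hazard = 0)),
                     seed = 41, duration_ms = 2e8, max_trials = 600)
  m <- compute_5cswm_metrics(trials_5cswm(log))
  n <- m$n_cp_match + m$n_cp_nonmatch
  expect_gt(n, 100)
  ci <- 100 * 2.576 * sqrt(0.25 / n)
  expect_lt(abs(m$cp_accuracy - 50), ci)
})

test_that("a 30-min session splits into ten 3-min bins that partition trials", {
  log <- run_session(build_5csrtt(), stochastic_agent(agent_params()),
                     seed = 43, duration_ms = 1800000)
  tr <- trials_5csrtt(log)
  b <- time_binned_metrics(tr, duration_ms = 1800000)
  expect_equal(nrow(b), 10)
  expect_equal(b$t_start_ms, seq(0, 27, by = 3) * 60000)
  expect_equal(sum(b$n_trials), nrow(tr))
  # bin metrics recompute the same formulas per bin
  in_bin1 <- tr[ifelse(is.na(tr$stim_onset_ms), tr$t_start_ms,
                       tr$stim_onset_ms) < 180000, ]
  expect_equal(b$n_trials[1], nrow(in_bin1))
  nc <- sum(in_bin1$class == "correct"); ni <- sum(in_bin1$class == "incorrect")
  expect_equal(b$accuracy[1], 100 * nc / (nc + ni))
  expect_error(time_binned_metrics(tr, bin_width_ms = 0,
                                   duration_ms = 1800000), "positive")
})

test_that("near-uniform trial times spread roughly evenly over bins", {
  # omission-only sessions tile trials at a fixed cadence; counts per bin
  # differ by at most one
  log <- run_scripted_5csrtt(make_script(numeric(0), character(0)),
                             seed = 1, duration_ms = 1800000)
  b <- time_binned_metrics(trials_5csrtt(log), duration_ms = 1800000)
  expect_lte(diff(range(b$n_trials)), 1)
  expect_true(all(is.na(b$accuracy)))   # no responses anywhere
  expect_true(all(b$pct_omissions == 100))
})

test_that("the response-share chi-square matches brute force", {
  a <- c(10, 10, 10, 10); b <- c(40, 0, 0, 0)
  res <- response_share_test(a, b)
  # brute-force Pearson statistic on the 2x4 table
  tab <- rbind(a, b)
  exp_tab <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(res$statistic, sum((tab - exp_tab)^2 / exp_tab))
  expect_equal(res$df, 3)
  expect_equal(res$p_value,
               stats::pchisq(res$statistic, 3, lower.tail = FALSE))

  same <- response_share_test(c(5, 6, 7, 8), c(5, 6, 7, 8))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  pooled <- response_share_test(c(10, 5, 0, 5), c(8, 7, 0, 2))
  expect_equal(pooled$df, 2)
  expect_equal(pooled$pooled, 3L)

  expect_error(response_share_test(c(0, 0, 0, 0), c(0, 0, 0, 0)),
               "at least one")
  expect_error(response_share_test(c(1, 2), c(1, 2, 3)), "equal length")
  expect_error(response_share_test(c(-1, 2, 3, 4), c(1, 2, 3, 4)),
               "non-negative")
})

test_that("latency summaries report quantiles per class and drop omissions", {
  tr <- data.frame(class = c("correct", "omission"),
                   response_latency_ms = c(800, NA),
                   reward_latency_ms = c(900, NA))
  s <- latency_summary(tr)
  expect_equal(nrow(s), 1)
  expect_equal(s$class, "correct")
  expect_equal(unname(unlist(s[, c("mean", "median", "q25", "q75")])),
               rep(800, 4))

  # simulated log-normal latencies: sample mean within a CI of the
  # distribution mean (Monte-Carlo check through a real session)
  log <- run_session(build_5csrtt(), stochastic_agent(perfect_params()),
                     seed = 47, duration_ms = 2e8, max_trials = 400)
  tr2 <- trials_5csrtt(log)
  s2 <- latency_summary(tr2)
  mu <- exp(log(600) + 0.4^2 / 2)                     # lognormal mean
  sdv <- sqrt((exp(0.4^2) - 1)) * mu
  expect_lt(abs(s2$mean - mu), 2.576 * sdv / sqrt(s2$n) + 0.5)
  hist_counts <- attr(s2, "histogram")$correct
  expect_equal(sum(hist_counts), s2$n)

  empty <- latency_summary(data.frame(class = character(0),
                                      response_latency_ms = numeric(0)))
  expect_equal(nrow(empty), 0)
})
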