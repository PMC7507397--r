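# Task simulator and behavioural statistics.

test_that("compute_threshold applies the 1/8 rule and validates input", {
  expect_equal(compute_threshold(0.3, 0.3), 0.075)
  expect_equal(compute_threshold(0.83, 0.83), 0.2075)
  expect_error(compute_threshold(0.4, 0.0), class = "coopsync_invalid_input")
  expect_error(compute_threshold(-1, 0.3), class = "coopsync_invalid_input")
  # homogeneity: scaling both RTs scales the threshold
  for (a in c(0.5, 2, 7.3)) {
    expect_equal(compute_threshold(a * 0.4, a * 0.9),
                 a * compute_threshold(0.4, 0.9))
  }
})

test_that("score_trial implements the win rule with configurable ties", {
  expect_identical(score_trial(0.05, 0.075), 1L)
  expect_identical(score_trial(0.2, 0.075), -1L)
  expect_identical(score_trial(0.075, 0.075, "leq"), 1L)
  expect_identical(score_trial(0.075, 0.075, "lt"), -1L)
  expect_error(score_trial(-0.1, 0.075), class = "coopsync_invalid_input")
})

test_that("sessions have the block design and internal identities", {
  sess <- simulate_session("d1", "delayed", seed = 7)
  tr <- sess$trials
  expect_equal(nrow(tr), 40L)
  expect_equal(as.integer(table(tr$block_index)), c(20L, 20L))
  expect_true(all(tr$cue_delay >= 0.6 & tr$cue_delay <= 1.5))
  expect_true(all(tr$rt1 > 0 & tr$rt1 <= 4 & tr$rt2 > 0 & tr$rt2 <= 4))
  expect_equal(tr$threshold, (tr$rt1 + tr$rt2) / 8)
  expect_equal(tr$rtd, abs(tr$rt1 - tr$rt2))
  expect_equal(diff(c(0, sess$score_trajectory)), as.numeric(tr$outcome))
  # determinism
  expect_identical(sess, simulate_session("d1", "delayed", seed = 7))
})

test_that("win rule is monotone in a common RT shift", {
  sess <- simulate_session("d2", "immediate", seed = 11)
  tr <- sess$trials
  for (c_shift in c(0.1, 0.5, 1.0)) {
    rt1 <- pmin(tr$rt1 + c_shift, 4)
    rt2 <- pmin(tr$rt2 + c_shift, 4)
    shifted <- score_trial(abs(rt1 - rt2), compute_threshold(rt1, rt2))
    # wins never flip to losses (RTD unchanged, threshold grows)
    expect_true(all(shifted[tr$outcome == 1L] == 1L))
  }
})

test_that("summarize_behavior computes WR, CC and the score identity", {
  sess <- simulate_session("d3", "none", seed = 3)
  s <- summarize_behavior(sess)
  expect_equal(s$wr, sum(sess$trials$outcome == 1L) / 40)
  expect_equal(s$cc, s$mean_threshold - s$mean_rtd)
  # WR = (final score + N) / (2N)
  expect_equal(s$wr, (s$final_score + 40) / 80)
  sess$trials <- sess$trials[0, ]
  expect_error(summarize_behavior(sess), class = "coopsync_invalid_input")
})

test_that("score/WR identity holds across strategies and seeds", {
  for (seed in 1:10) {
    strat <- c("delayed", "immediate", "none")[(seed %% 3) + 1]
    s <- summarize_behavior(simulate_session("d", strat, seed = seed))
    expect_equal(s$wr, (s$final_score + s$n_trials) / (2 * s$n_trials))
  }
})

test_that("degenerate coupling collapses the RT difference", {
  params <- default_strategy_params("immediate")
  params$within_dyad_coupling <- 1
  params$trial_noise_sd <- 0
  params$inconsistency_rate <- 0
  params$trial_noise_cv_log <- 0
  sess <- simulate_session("d4", "immediate", params = params, seed = 2)
  expect_true(all(sess$trials$rtd == 0))
  expect_true(all(sess$trials$outcome == 1L))
  expect_equal(sess$score_trajectory[40], 40L)
})

test_that("immediate group mean RT matches the configured 0.30 s", {
  # Monte-Carlo against the configured generator; SE accounts for dyad
  # clustering (dyads are the independent unit)
  s <- summarize_cohort(simulate_cohort(c(immediate = 400), seed = 190))
  se <- sd(s$mean_rt) / sqrt(nrow(s))
  expect_lt(abs(mean(s$mean_rt) - 0.30), 3 * se)
})

test_that("delayed group between-dyad RT spread matches the configured 0.44 s", {
  s <- summarize_cohort(simulate_cohort(c(delayed = 400), seed = 191))
  expect_lt(abs(sd(s$mean_rt) - 0.44) / 0.44, 0.10)
})

test_that("group mean RTs are ordered delayed > none > immediate", {
  s <- summarize_cohort(simulate_cohort(
    c(delayed = 200, immediate = 200, none = 200), seed = 192))
  m <- tapply(s$mean_rt, s$strategy, mean)
  expect_gt(m[["delayed"]], m[["none"]])
  expect_gt(m[["none"]], m[["immediate"]])
})

test_that("cohorts are reproducible and sized correctly", {
  expect_length(simulate_cohort(seed = 5), 43L)
  expect_length(simulate_cohort(c(delayed = 0, immediate = 0, none = 0)), 0L)
  a <- simulate_cohort(c(delayed = 2, none = 1), seed = 9)
  b <- simulate_cohort(c(delayed = 2, none = 1), seed = 9)
  expect_identical(a, b)
  expect_error(simulate_cohort(c(delayed = -1)),
               class = "coopsync_invalid_input")
  expect_error(simulate_cohort(c(5, 5)), class = "coopsync_invalid_input")
})

test_that("CC correlates positively with WR across a cohort", {
  s <- summarize_cohort(simulate_cohort(
    c(delayed = 40, immediate = 40, none = 40), seed = 21))
  expect_gt(cor(s$cc, s$wr), 0)
})

test_that("behaviour tables round-trip through TSV", {
  sessions <- simulate_cohort(c(delayed = 2, immediate = 1), seed = 14)
  td <- withr::local_tempdir()
  trials_path <- file.path(td, "trials.tsv")
  summary_path <- file.path(td, "summary.tsv")
  write_behavior_tables(sessions, trials_path, summary_path)
  tr <- read.delim(trials_path)
  expect_equal(nrow(tr), 3 * 40)
  expect_equal(tr$threshold_s, (tr$rt1_s + tr$rt2_s) / 8, tolerance = 1e-8)
  s <- read.delim(summary_path)
  expect_equal(s$cc, s$mean_threshold - s$mean_rtd, tolerance = 1e-8)
})
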