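# Generative model of the cooperative keystroke task.
#
# Two partners each press a key as fast as they can after a visual go signal;
# the dyad wins the trial when the absolute difference of their reaction
# times (RTD) is within a threshold T = (RT1 + RT2) / 8 that the participants
# do not know.  Dyads approach the task with one of three strategies:
# a deliberate shared delay ("delayed"), pressing as fast as possible
# ("immediate"), or no consistent strategy ("none").

STRATEGY_LEVELS <- c("delayed", "immediate", "none")

#' Default generative parameters for a cooperation strategy
#'
#' Returns the parameter set that defines the simulated population for one
#' strategy group.  Group-level mean reaction times and their between-dyad
#' spreads are the published group statistics for this paradigm
#' (delayed 0.83 +/- 0.44 s, immediate 0.30 +/- 0.06 s, none 0.43 +/- 0.09 s);
#' the remaining parameters (trial noise, within-dyad coupling, dyad-level
#' noise heterogeneity, regime mismatch of the no-strategy group) are free
#' generator choices fixed once so that the simulated cohorts reproduce the
#' behavioural decomposition of the task: group thresholds differ strongly,
#' group RTDs do not, and winning ratio is ordered delayed > immediate > none.
#'
#' @param strategy one of `"delayed"`, `"immediate"`, `"none"`.
#' @return A list of class `"strategy_params"` with fields
#'   `dyad_mean_rt_mean`, `dyad_mean_rt_sd` (seconds; between-dyad spread),
#'   `intended_delay_median` (seconds; delayed only, `NA` otherwise),
#'   `within_dyad_coupling` (correlation of partners' trial RTs, in `[0,1]`),
#'   `trial_noise_sd` (seconds), `trial_noise_cv_log` (dyad-level log-SD of
#'   the trial noise scale), `inconsistency_rate` (probability of a
#'   mismatched-regime trial; no-strategy mode switching), `mismatch_sd`
#'   (seconds; size of a mismatch offset), and `timeout` (seconds).
#' @export
#' @examples
#' default_strategy_params("delayed")$dyad_mean_rt_mean  # 0.83
default_strategy_params <- function(strategy = STRATEGY_LEVELS) {
  strategy <- match.arg(strategy)
  base <- list(
    intended_delay_median = NA_real_,
    trial_noise_cv_log = 1.0,
    inconsistency_rate = 0,
    mismatch_sd = 0.28,
    timeout = 4.0
  )
  spec <- switch(strategy,
    delayed = list(
      dyad_mean_rt_mean = 0.83, dyad_mean_rt_sd = 0.44,
      intended_delay_median = 0.5,
      within_dyad_coupling = 0.8, trial_noise_sd = 0.18,
      inconsistency_rate = 0.2, mismatch_sd = 0.46
    ),
    immediate = list(
      dyad_mean_rt_mean = 0.30, dyad_mean_rt_sd = 0.06,
      within_dyad_coupling = 0.3, trial_noise_sd = 0.044,
      inconsistency_rate = 0.3, mismatch_sd = 0.50
    ),
    none = list(
      dyad_mean_rt_mean = 0.43, dyad_mean_rt_sd = 0.09,
      within_dyad_coupling = 0.3, trial_noise_sd = 0.09,
      inconsistency_rate = 0.5, mismatch_sd = 0.22
    )
  )
  out <- modifyList(base, spec)
  out$strategy <- strategy
  class(out) <- "strategy_params"
  out
}

validate_strategy_params <- function(params) {
  assert_scalar_num(params$dyad_mean_rt_mean, "dyad_mean_rt_mean", lo = 0,
                    strict_lo = TRUE)
  assert_scalar_num(params$dyad_mean_rt_sd, "dyad_mean_rt_sd", lo = 0)
  assert_scalar_num(params$within_dyad_coupling, "within_dyad_coupling",
                    lo = 0, hi = 1)
  assert_scalar_num(params$trial_noise_sd, "trial_noise_sd", lo = 0)
  assert_scalar_num(params$trial_noise_cv_log, "trial_noise_cv_log", lo = 0)
  assert_scalar_num(params$inconsistency_rate, "inconsistency_rate",
                    lo = 0, hi = 1)
  assert_scalar_num(params$mismatch_sd, "mismatch_sd", lo = 0)
  assert_scalar_num(params$timeout, "timeout", lo = 0, strict_lo = TRUE)
  invisible(params)
}

#' Trial win threshold
#'
#' The trial-specific criterion the dyad must beat: `T = (RT1 + RT2) / 8`.
#' The 1/8 factor keeps the task at a workable difficulty; slower joint
#' responses earn a proportionally more forgiving threshold.
#'
#' @param rt1,rt2 positive reaction times in seconds.
#' @return Threshold in seconds.  Homogeneous of degree 1: scaling both RTs
#'   by `a > 0` scales the threshold by `a`.
#' @export
#' @examples
#' compute_threshold(0.3, 0.3)  # 0.075
compute_threshold <- function(rt1, rt2) {
  if (!is.numeric(rt1) || !is.numeric(rt2) || length(rt1) != length(rt2)) {
    stop_invalid("rt1 and rt2 must be numeric vectors of equal length")
  }
  if (any(!is.finite(rt1)) || any(!is.finite(rt2)) ||
      any(rt1 <= 0) || any(rt2 <= 0)) {
    stop_invalid("reaction times must be finite and strictly positive")
  }
  (rt1 + rt2) / 8
}

#' Score one trial
#'
#' A trial is won (+1) when the response-time difference is within the
#' threshold, otherwise lost (-1).  Whether an exact tie `rtd == threshold`
#' wins is configurable; the default treats ties as wins.
#'
#' @param rtd nonnegative response-time difference (seconds).
#' @param threshold nonnegative threshold (seconds).
#' @param tie_rule `"leq"` (tie wins, default) or `"lt"` (tie loses).
#' @return Integer vector of +1 / -1.
#' @export
score_trial <- function(rtd, threshold, tie_rule = c("leq", "lt")) {
  tie_rule <- match.arg(tie_rule)
  if (!is.numeric(rtd) || !is.numeric(threshold)) {
    stop_invalid("rtd and threshold must be numeric")
  }
  if (any(!is.finite(rtd)) || any(!is.finite(threshold)) ||
      any(rtd < 0) || any(threshold < 0)) {
    stop_invalid("rtd and threshold must be finite and nonnegative")
  }
  win <- if (tie_rule == "leq") rtd <= threshold else rtd < threshold
  ifelse(win, 1L, -1L)
}

#' Draw dyad-level latent effects for one simulated couple
#'
#' Hierarchical layer of the generator: the dyad's mean reaction time is
#' drawn from the strategy group's (truncated) normal, and the dyad's trial
#' noise scale gets a mean-preserving log-normal perturbation so that
#' couples differ in how tightly they synchronise (this heterogeneity is
#' what keeps group RTD differences statistically unremarkable, as observed).
#'
#' @param strategy strategy label.
#' @param params a `strategy_params` list.
#' @return List with `mu` (dyad mean RT, s), `noise_sd` (dyad trial noise
#'   scale, s) and `intended_delay` (s; implied deliberate delay relative to
#'   the immediate-response baseline, 0 where not meaningful).
#' @export
draw_dyad_effects <- function(strategy, params = default_strategy_params(strategy)) {
  validate_strategy_params(params)
  # moment-matched lower-truncated normal: the *realized* dyad-mean RT
  # distribution has exactly the configured group mean and SD
  mm <- truncnorm_match_moments(params$dyad_mean_rt_mean,
                                params$dyad_mean_rt_sd, lower = 0.05)
  mu <- rtruncnorm_lower(1L, mm[["mean"]], mm[["sd"]], lower = 0.05)
  mu <- min(mu, params$timeout - 0.5)
  cv <- params$trial_noise_cv_log
  # mean-preserving log-normal sloppiness factor (couples differ widely in
  # how tightly they synchronise; extremes are the "failed strategy" dyads).
  # It enters the base trial noise with exponent 1/2 and the slip magnitude
  # with exponent 3/2 (floored and capped), so heterogeneity lands mostly in
  # the occasional large mismatches that dominate a dyad's mean RTD but,
  # being losses almost regardless of size, leave its winning ratio
  # comparatively untouched.
  f <- exp(rnorm(1L, -cv^2 / 2, cv))
  noise_sd <- params$trial_noise_sd * sqrt(f)
  slip_sd <- min(params$mismatch_sd * max(f^1.5, 1), 0.9)
  # compensate the expected inflation from clipping trial RTs at the floor,
  # so the population trial-RT mean matches the configured group mean
  r <- params$inconsistency_rate
  s_slip <- sqrt(noise_sd^2 + slip_sd^2 / 4)
  bias <- (1 - r) * clip_bias_lower(mu, noise_sd, RT_CLIP_LO) +
    r * clip_bias_lower(mu, s_slip, RT_CLIP_LO)
  mu_use <- max(mu - bias, 0.02)
  delay <- if (strategy == "delayed" && is.finite(params$intended_delay_median)) {
    baseline <- params$dyad_mean_rt_mean - params$intended_delay_median
    max(mu - baseline, 0)
  } else 0
  list(mu = mu_use, noise_sd = noise_sd, slip_sd = slip_sd,
       intended_delay = delay)
}

RT_CLIP_LO <- 0.01

#' Draw one trial's pair of reaction times
#'
#' Partner RTs share the dyad mean and a common trial-level component whose
#' weight is the within-dyad coupling `rho`: conditional on the dyad,
#' `cor(rt1, rt2) = rho` on regular trials.  With probability
#' `inconsistency_rate` a trial is a mismatched-regime "slip": the partners
#' drift apart by an antisymmetric offset (`+delta/2` to one, `-delta/2` to
#' the other, `delta ~ N(0, mismatch_sd)` scaled by the dyad's sloppiness),
#' which inflates the trial RTD without moving either partner's mean RT.
#' RTs are clipped to `(0, timeout]`.
#'
#' @param strategy strategy label.
#' @param params a `strategy_params` list.
#' @param dyad_effects latent draws from [draw_dyad_effects()].
#' @return Numeric vector `c(rt1, rt2)` in seconds.
#' @export
draw_trial_rts <- function(strategy, params, dyad_effects) {
  rho <- params$within_dyad_coupling
  s <- dyad_effects$noise_sd
  z_shared <- rnorm(1L)
  z <- rnorm(2L)
  rt <- dyad_effects$mu + s * (sqrt(rho) * z_shared + sqrt(1 - rho) * z)
  if (params$inconsistency_rate > 0 &&
      runif(1L) < params$inconsistency_rate) {
    delta <- rnorm(1L, 0, dyad_effects$slip_sd)
    rt <- rt + c(delta / 2, -delta / 2)
  }
  pmin(pmax(rt, RT_CLIP_LO), params$timeout)
}

#' Simulate a full cooperative keystroke session for one dyad
#'
#' Two blocks of 20 trials.  Each trial draws a cue delay uniform on
#' `[0.6, 1.5]` s, partner reaction times from the strategy's generative
#' model, the trial threshold, the response-time difference and the
#' win/loss outcome.  Deterministic given `seed`.
#'
#' @param dyad_id identifier for the dyad.
#' @param strategy one of `"delayed"`, `"immediate"`, `"none"`.
#' @param params a `strategy_params` list (defaults to the strategy's
#'   published group parameters).
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @param n_blocks,trials_per_block block design (defaults 2 x 20).
#' @param tie_rule tie handling passed to [score_trial()].
#' @return A list of class `"dyad_session"` with `dyad_id`, `strategy`,
#'   `effects` (latent dyad draws), `trials` (data frame with one row per
#'   trial: `block_index`, `trial_index`, `cue_delay`, `rt1`, `rt2`,
#'   `threshold`, `rtd`, `outcome`) and `score_trajectory` (cumulative).
#' @export
simulate_session <- function(dyad_id, strategy = STRATEGY_LEVELS,
                             params = default_strategy_params(strategy),
                             seed = NULL, n_blocks = 2L,
                             trials_per_block = 20L,
                             tie_rule = c("leq", "lt")) {
  strategy <- match.arg(strategy, STRATEGY_LEVELS)
  tie_rule <- match.arg(tie_rule)
  validate_strategy_params(params)
  with_seed(seed, {
    n <- n_blocks * trials_per_block
    effects <- draw_dyad_effects(strategy, params)
    cue <- runif(n, 0.6, 1.5)
    rts <- vapply(seq_len(n), function(i) {
      draw_trial_rts(strategy, params, effects)
    }, numeric(2L))
    rt1 <- rts[1L, ]
    rt2 <- rts[2L, ]
    threshold <- compute_threshold(rt1, rt2)
    rtd <- abs(rt1 - rt2)
    outcome <- score_trial(rtd, threshold, tie_rule)
    trials <- data.frame(
      block_index = rep(seq_len(n_blocks), each = trials_per_block),
      trial_index = rep(seq_len(trials_per_block), times = n_blocks),
      cue_delay = cue, rt1 = rt1, rt2 = rt2,
      threshold = threshold, rtd = rtd, outcome = outcome
    )
    structure(
      list(dyad_id = dyad_id, strategy = strategy, effects = effects,
           trials = trials, score_trajectory = cumsum(outcome)),
      class = "dyad_session"
    )
  })
}

#' Behavioural summary statistics of a session
#'
#' Computes the dyad's winning ratio (WR, wins / total trials), mean
#' reaction time across both partners, mean response-time difference
#' (RTD), mean threshold, and the cooperation coefficient
#' `CC = mean threshold - mean RTD`.  CC rewards dyads whose RTs are long
#' enough to earn slack (large threshold) *and* tightly matched (small RTD),
#' which is exactly what wins trials; unlike WR it is continuous in both.
#'
#' @param session a `dyad_session`.
#' @return A one-row data frame: `dyad_id`, `strategy`, `n_trials`, `wins`,
#'   `wr`, `mean_rt`, `mean_rtd`, `mean_threshold`, `cc`, `final_score`.
#' @export
summarize_behavior <- function(session) {
  tr <- session$trials
  if (is.null(tr) || nrow(tr) == 0L) {
    stop_invalid("session has no trials")
  }
  n <- nrow(tr)
  wins <- sum(tr$outcome == 1L)
  data.frame(
    dyad_id = session$dyad_id,
    strategy = session$strategy,
    n_trials = n,
    wins = wins,
    wr = wins / n,
    mean_rt = mean(c(tr$rt1, tr$rt2)),
    mean_rtd = mean(tr$rtd),
    mean_threshold = mean(tr$threshold),
    cc = mean(tr$threshold) - mean(tr$rtd),
    final_score = session$score_trajectory[n],
    stringsAsFactors = FALSE
  )
}

#' Simulate a cohort of dyads across strategy groups
#'
#' Default group sizes follow the published cohort: 17 delayed, 16
#' immediate, 10 with no obvious strategy (43 couples).  Each dyad gets a
#' counter-derived child seed from the master seed, so cohorts are
#' reproducible and dyads are independent.
#'
#' @param group_sizes named integer vector over strategies.
#' @param params named list of `strategy_params`, one per strategy.
#' @param seed master integer seed.
#' @param tie_rule passed to [simulate_session()].
#' @return List of `dyad_session` objects, `dyad_id`s `"d001"`, `"d002"`, ...
#' @export
#' @examples
#' cohort <- simulate_cohort(c(delayed = 2, immediate = 2, none = 1), seed = 1)
#' length(cohort)  # 5
simulate_cohort <- function(group_sizes = c(delayed = 17L, immediate = 16L,
                                            none = 10L),
                            params = NULL, seed = 1L,
                            tie_rule = c("leq", "lt")) {
  tie_rule <- match.arg(tie_rule)
  if (is.null(names(group_sizes)) ||
      !all(names(group_sizes) %in% STRATEGY_LEVELS)) {
    stop_invalid("group_sizes must be named with strategy labels")
  }
  if (any(group_sizes < 0)) stop_invalid("group sizes must be >= 0")
  if (is.null(params)) {
    params <- lapply(STRATEGY_LEVELS, default_strategy_params)
    names(params) <- STRATEGY_LEVELS
  }
  sessions <- list()
  counter <- 0L
  for (strategy in names(group_sizes)) {
    n_g <- group_sizes[[strategy]]
    if (n_g == 0L) next
    for (i in seq_len(n_g)) {
      counter <- counter + 1L
      sessions[[counter]] <- simulate_session(
        dyad_id = sprintf("d%03d", counter),
        strategy = strategy,
        params = params[[strategy]],
        seed = derive_seed(seed, counter),
        tie_rule = tie_rule
      )
    }
  }
  sessions
}

#' Summarise a whole cohort
#'
#' @param sessions list of `dyad_session` objects.
#' @return Data frame with one row per dyad (see [summarize_behavior()]).
#' @export
summarize_cohort <- function(sessions) {
  do.call(rbind, lapply(sessions, summarize_behavior))
}

#' Write behavioural tables to TSV
#'
#' Writes the trial-level table (one row per trial) and the per-dyad summary
#' in the package's documented TSV dialect.
#'
#' @param sessions list of `dyad_session` objects.
#' @param trials_path,summary_path output file paths.
#' @return Invisibly, the summary data frame.
#' @export
write_behavior_tables <- function(sessions, trials_path, summary_path) {
  trials <- do.call(rbind, lapply(sessions, function(s) {
    tr <- s$trials
    data.frame(
      dyad_id = s$dyad_id, strategy = s$strategy,
      block = tr$block_index, trial = tr$trial_index,
      cue_delay_s = tr$cue_delay, rt1_s = tr$rt1, rt2_s = tr$rt2,
      threshold_s = tr$threshold, rtd_s = tr$rtd, outcome = tr$outcome,
      cum_score = s$score_trajectory, stringsAsFactors = FALSE
    )
  }))
  summary <- summarize_cohort(sessions)
  write_tsv_pinned(trials, trials_path)
  write_tsv_pinned(summary, summary_path)
  invisible(summary)
}

# pinned float formatting so that identical runs give byte-identical tables
write_tsv_pinned <- function(df, path, digits = 10) {
  num <- vapply(df, is.double, logical(1L))
  df[num] <- lapply(df[num], function(x) formatC(x, digits = digits,
                                                 format = "g"))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
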