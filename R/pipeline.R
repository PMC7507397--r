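# End-to-end orchestration: behaviour simulation -> signal synthesis ->
# preprocessing -> channel-wise IBS -> group statistics -> Granger
# causality -> report, with per-stage seeding, structured logging and a
# run manifest.

#' Run the full synthetic replication pipeline
#'
#' Simulates a cohort of dyads, synthesizes and preprocesses their optical
#' recordings, computes channel-wise task-minus-rest IBS, performs the
#' group-level tests (per-group one-sample t per channel with BH-FDR,
#' between-group ANOVA per channel), runs directional coupling analysis at
#' the target channel for the delayed group, and writes all result tables
#' plus a manifest into `config$output_dir` (unless `write = FALSE`).
#'
#' @param config a `run_config` (see [default_config()]).
#' @param seed overrides `config$master_seed` when given.
#' @param write write output tables to disk (default TRUE).
#' @param verbose print per-stage progress.
#' @return List: `behavior` (per-dyad summary), `ibs` (per dyad/channel),
#'   `group_stats` (per group/channel t + FDR; per-channel ANOVA),
#'   `gca` (cohort GC at the target channel), `manifest`.
#' @export
run_full <- function(config = default_config(), seed = NULL, write = TRUE,
                     verbose = FALSE) {
  t_start <- Sys.time()
  if (!is.null(seed)) config$master_seed <- as.integer(seed)
  master <- config$master_seed
  obj <- config_objects(config)
  say <- function(...) if (verbose) message(sprintf(...))
  stage_times <- list()
  tick <- function(name, expr) {
    t0 <- Sys.time()
    val <- force(expr)
    stage_times[[name]] <<- as.numeric(difftime(Sys.time(), t0,
                                                units = "secs"))
    val
  }

  say("stage 1/5: behaviour (seed %d)", master)
  sessions <- tick("behavior", simulate_cohort(
    group_sizes = unlist(config$task$group_sizes),
    seed = master, tie_rule = config$task$tie_rule
  ))
  behavior <- summarize_cohort(sessions)

  say("stage 2/5: signal synthesis + preprocessing (%d dyads)",
      length(sessions))
  noise <- obj$noise
  recs <- tick("signals", lapply(seq_along(sessions), function(i) {
    rec <- synthesize_dyad_recording(
      sessions[[i]], layout = probe_layout(), acq = obj$acq,
      coupling = obj$coupling, noise = noise,
      seed = derive_seed(master, i, stream = 1L)
    )
    if (noise$artifact_rate > 0) {
      rec <- inject_motion_artifacts(rec, noise,
                                     seed = derive_seed(master, i, 2L))$rec
    }
    rec
  }))
  prep <- tick("preprocess", lapply(recs, function(r) {
    preprocess_recording(r, snr_threshold = config$preprocessing$snr_threshold,
                         artifacts = obj$artifacts)
  }))
  hb <- lapply(prep, `[[`, "rec")

  say("stage 3/5: channel-wise IBS")
  ibs <- tick("ibs", do.call(rbind, lapply(seq_along(hb), function(i) {
    out <- ibs_per_dyad(hb[[i]], dyad_id = sessions[[i]]$dyad_id,
                        wparams = obj$wparams, band = obj$band,
                        baseline = config$band$baseline)
    out$strategy <- sessions[[i]]$strategy
    out
  })))

  say("stage 4/5: group statistics")
  group_stats <- tick("stats", ibs_group_stats(ibs, q = config$stats$fdr_q,
                                               tail = config$stats$tail))

  say("stage 5/5: directional coupling")
  gc_channel <- config$gca$channel %||% probe_layout()$target_channel
  delayed_idx <- which(vapply(sessions, function(s) s$strategy == "delayed",
                              logical(1L)))
  gca <- tick("gca", tryCatch(
    cohort_gc(hb[delayed_idx], channel = gc_channel,
              dyad_ids = vapply(sessions[delayed_idx], `[[`, "",
                                "dyad_id"),
              order = config$gca$order,
              max_order = config$gca$max_order),
    coopsync_invalid_input = function(e) {
      warning("GCA skipped: ", conditionMessage(e))
      NULL
    }
  ))

  manifest <- list(
    package_version = as.character(utils::packageVersion("coopsync")),
    master_seed = master,
    n_dyads = length(sessions),
    gc_channel = gc_channel,
    stage_seconds = stage_times,
    started = format(t_start, "%Y-%m-%dT%H:%M:%S"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  )
  result <- list(behavior = behavior, ibs = ibs, group_stats = group_stats,
                 gca = gca, manifest = manifest)
  if (write) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    out <- function(f) file.path(config$output_dir, f)
    write_behavior_tables(sessions, out("trials.tsv"), out("behavior.tsv"))
    write_tsv_pinned(ibs, out("ibs.tsv"))
    write_tsv_pinned(group_stats$per_channel, out("ibs_group_tests.tsv"))
    report <- list(
      anova = group_stats$anova,
      fdr_passed = group_stats$fdr_passed,
      gca = if (!is.null(gca)) list(
        order = gca$order,
        x_to_y = unclass(gca$tests$x_to_y),
        y_to_x = unclass(gca$tests$y_to_x),
        direction_diff = unclass(gca$tests$direction_diff)
      ) else NULL,
      manifest = manifest
    )
    jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA, null = "null",
                         force = TRUE)
    write_config(config, out("config.json"))
    manifest$files <- list.files(config$output_dir)
    result$manifest <- manifest
  }
  result
}

#' Group-level IBS statistics
#'
#' Per strategy group and channel: one-sample t on `ibs_z` (one-tailed,
#' positive, by default) with Benjamini-Hochberg correction across the
#' group's valid channels.  Per channel: one-way ANOVA of `ibs_z` across
#' the three groups.
#'
#' @param ibs per-dyad/channel IBS table (with `strategy` column).
#' @param q FDR level.
#' @param tail t-test tail.
#' @param min_n minimum dyads per group/channel to test (default 3).
#' @return List: `per_channel` (group x channel t table with adjusted p),
#'   `fdr_passed` (named list of channels passing per group), `anova`
#'   (per-channel F/p/eta_p2 data frame).
#' @export
ibs_group_stats <- function(ibs, q = 0.05, tail = "one", min_n = 3L) {
  groups <- unique(ibs$strategy)
  rows <- list()
  fdr_passed <- list()
  for (g in groups) {
    sub <- ibs[ibs$strategy == g & ibs$valid, ]
    chs <- sort(unique(sub$channel))
    stats <- lapply(chs, function(ch) {
      v <- sub$ibs_z[sub$channel == ch]
      if (length(v) < min_n || sd(v) == 0) return(NULL)
      tt <- one_sample_t(v, 0, tail = tail)
      data.frame(strategy = g, channel = ch, n = length(v),
                 mean_ibs_z = tt$estimate, t = tt$t, df = tt$df, p = tt$p)
    })
    stats <- do.call(rbind, stats)
    if (is.null(stats)) next
    fdr <- bh_fdr(stats::setNames(stats$p, stats$channel), q = q)
    stats$p_adj <- fdr$adjusted_p[as.character(stats$channel)]
    stats$fdr_passed <- as.character(stats$channel) %in% fdr$passed
    fdr_passed[[g]] <- as.integer(fdr$passed)
    rows[[g]] <- stats
  }
  per_channel <- do.call(rbind, rows)
  rownames(per_channel) <- NULL
  anova_rows <- list()
  for (ch in sort(unique(ibs$channel[ibs$valid]))) {
    by_group <- split(ibs$ibs_z[ibs$valid & ibs$channel == ch],
                      ibs$strategy[ibs$valid & ibs$channel == ch])
    by_group <- by_group[vapply(by_group, length, integer(1L)) >= 2L]
    if (length(by_group) < 2L) next
    an <- tryCatch(one_way_anova(by_group), error = function(e) NULL)
    if (is.null(an)) next
    anova_rows[[as.character(ch)]] <- data.frame(
      channel = ch, f = an$f, df1 = an$df1, df2 = an$df2, p = an$p,
      eta_p2 = an$eta_p2
    )
  }
  anova <- do.call(rbind, anova_rows)
  rownames(anova) <- NULL
  list(per_channel = per_channel, fdr_passed = fdr_passed, anova = anova)
}
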