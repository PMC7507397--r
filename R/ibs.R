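# Interpersonal brain synchronization (IBS): band-averaged wavelet
# coherence of the partners' oxyhemoglobin series, contrasted between task
# blocks and the rest interval between them.

#' Analysis period band
#'
#' @param period_lo,period_hi band limits in seconds (defaults 3.2 and
#'   12.8), endpoints inclusive.
#' @return List of class `"band_spec"`.
#' @export
band_spec <- function(period_lo = 3.2, period_hi = 12.8) {
  if (period_lo >= period_hi) stop_config("period_lo must be < period_hi")
  structure(list(period_lo = period_lo, period_hi = period_hi),
            class = "band_spec")
}

#' Mean coherence over a period band and set of timeline segments
#'
#' Averages the coherence map over all times falling inside the named
#' segments and all periods inside the band (endpoints inclusive).  With
#' `coi_policy = "exclude"` (the map's default), time-period points outside
#' the cone of influence contribute nothing.
#'
#' @param map a `coherence_map`.
#' @param band a [band_spec()].
#' @param segments character vector of timeline labels.
#' @param timeline timeline data frame ([make_timeline()]).
#' @return Mean coherence (scalar); `NA` with a warning when every point is
#'   excluded.
#' @export
band_segment_mean <- function(map, band = band_spec(), segments, timeline) {
  validate_timeline(timeline)
  n <- length(map$times)
  idx_t <- segment_sample_index(timeline, segments, map$fs, n)
  idx_p <- which(map$periods >= band$period_lo - 1e-9 &
                   map$periods <= band$period_hi + 1e-9)
  if (length(idx_p) == 0L) stop_invalid("no periods inside band")
  vals <- map$values[idx_t, idx_p, drop = FALSE]
  if (identical(map$params$coi_policy, "exclude")) {
    keep <- outer(map$coi[idx_t], map$periods[idx_p], `>=`)
    vals[!keep] <- NA_real_
  }
  if (all(is.na(vals))) {
    warning("selection empty after COI exclusion")
    return(NA_real_)
  }
  mean(vals, na.rm = TRUE)
}

#' Task-minus-rest IBS statistic
#'
#' `IBS = mean band coherence over task blocks - mean band coherence over
#' the baseline interval` (default: the rest between the two task blocks).
#' The Fisher-Z version applies `atanh` to each interval mean before
#' differencing; inference downstream runs on `ibs_z`.
#'
#' @param map a `coherence_map` for one channel pair.
#' @param timeline session timeline.
#' @param band a [band_spec()].
#' @param task_segments labels of task blocks (default `task1`, `task2`).
#' @param baseline baseline segment labels (default `rest2`).
#' @return List: `coh_task`, `coh_rest`, `ibs`, `ibs_z`, `valid`.
#' @export
compute_ibs <- function(map, timeline, band = band_spec(),
                        task_segments = c("task1", "task2"),
                        baseline = "rest2") {
  coh_task <- band_segment_mean(map, band, task_segments, timeline)
  coh_rest <- band_segment_mean(map, band, baseline, timeline)
  valid <- is.finite(coh_task) && is.finite(coh_rest)
  list(coh_task = coh_task, coh_rest = coh_rest,
       ibs = if (valid) coh_task - coh_rest else NA_real_,
       ibs_z = if (valid) fisher_z(coh_task) - fisher_z(coh_rest)
       else NA_real_,
       valid = valid)
}

#' Fisher Z transform
#'
#' `z = atanh(r)` for coherence/correlation values; inputs at or above 1
#' are clipped to `1 - 1e-10`.
#'
#' @param r values in `[0, 1)` (coherence) or `(-1, 1)` when
#'   `allow_negative = TRUE` (correlations).
#' @param allow_negative permit negative input (default FALSE).
#' @return `atanh(r)`.
#' @export
fisher_z <- function(r, allow_negative = FALSE) {
  if (any(!is.finite(r))) stop_invalid("r must be finite")
  if (!allow_negative && any(r < 0)) stop_invalid("r must be >= 0")
  r <- pmin(r, 1 - 1e-10)
  if (allow_negative) r <- pmax(r, -1 + 1e-10)
  atanh(r)
}

#' Channel-wise IBS for one dyad
#'
#' For every channel valid in both partners, computes the wavelet coherence
#' of the two oxyhemoglobin series (per-segment mean removed first - the
#' only detrending in the chain) and the task-minus-rest IBS.  Channels
#' missing for either partner yield `valid = FALSE` rows.
#'
#' @param rec preprocessed recording at stage `"hb"`.
#' @param dyad_id identifier copied into the output.
#' @param wparams a [wavelet_params()].
#' @param band a [band_spec()].
#' @param baseline baseline segment labels (default `rest2`).
#' @return Data frame: `dyad_id`, `channel`, `coh_task`, `coh_rest`, `ibs`,
#'   `ibs_z`, `valid`.
#' @export
ibs_per_dyad <- function(rec, dyad_id = "dyad", wparams = wavelet_params(),
                         band = band_spec(), baseline = "rest2") {
  if (rec$stage != "hb") stop_invalid("expected hb stage recording")
  nch <- dim(rec$data)[2L]
  n <- n_samples(rec)
  timeline <- rec$timeline
  missing <- union(rec$missing[[1L]], rec$missing[[2L]])
  rows <- vector("list", nch)
  for (ch in seq_len(nch)) {
    if (ch %in% missing) {
      rows[[ch]] <- data.frame(dyad_id = dyad_id, channel = ch,
                               coh_task = NA_real_, coh_rest = NA_real_,
                               ibs = NA_real_, ibs_z = NA_real_,
                               valid = FALSE)
      next
    }
    x <- demean_segments(rec$data[1L, ch, 1L, ], timeline, rec$fs)
    y <- demean_segments(rec$data[2L, ch, 1L, ], timeline, rec$fs)
    map <- wavelet_coherence(x, y, rec$fs, wparams)
    r <- compute_ibs(map, timeline, band, baseline = baseline)
    rows[[ch]] <- data.frame(dyad_id = dyad_id, channel = ch,
                             coh_task = r$coh_task, coh_rest = r$coh_rest,
                             ibs = r$ibs, ibs_z = r$ibs_z, valid = r$valid)
  }
  do.call(rbind, rows)
}

# remove the mean of each timeline segment (no other detrending / filtering)
demean_segments <- function(x, timeline, fs) {
  n <- length(x)
  out <- x
  for (i in seq_len(nrow(timeline))) {
    idx <- segment_sample_index(timeline[i, , drop = FALSE],
                                timeline$label[i], fs, n)
    out[idx] <- x[idx] - mean(x[idx])
  }
  out
}
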