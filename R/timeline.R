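# Session timeline: the canonical five-segment block design
# rest1 (30 s) - task1 (~150 s) - rest2 (30 s) - task2 (150 s) - rest3 (30 s),
# with per-trial onset markers inside the task blocks.

SEGMENT_LABELS <- c("rest1", "task1", "rest2", "task2", "rest3")

#' Acquisition configuration
#'
#' Sampling and timing parameters of the simulated optical recording.
#'
#' @param fs sampling frequency in Hz (default 10).
#' @param wavelengths nm pair (default 690, 830).
#' @param rest_duration rest segment duration in seconds (default 30).
#' @param task_duration nominal task block duration in seconds (default 150);
#'   trial-driven timing is padded up to this value.
#' @param source_detector_distance cm (default 3).
#' @param feedback_s,iti_s per-trial feedback display and inter-trial
#'   interval in seconds (defaults 2.0 and 1.5, chosen so 20 trials fill
#'   roughly 150 s).
#' @return List of class `"acquisition_config"`.
#' @export
acquisition_config <- function(fs = 10, wavelengths = c(690, 830),
                               rest_duration = 30, task_duration = 150,
                               source_detector_distance = 3.0,
                               feedback_s = 2.0, iti_s = 1.5) {
  assert_scalar_num(fs, "fs", lo = 0, strict_lo = TRUE)
  assert_scalar_num(rest_duration, "rest_duration", lo = 0, strict_lo = TRUE)
  assert_scalar_num(task_duration, "task_duration", lo = 0, strict_lo = TRUE)
  structure(list(fs = fs, wavelengths = wavelengths,
                 rest_duration = rest_duration,
                 task_duration = task_duration,
                 source_detector_distance = source_detector_distance,
                 feedback_s = feedback_s, iti_s = iti_s),
            class = "acquisition_config")
}

#' Build the session timeline
#'
#' Returns the five canonical segments with onsets and durations, plus
#' per-trial onset markers (attribute `"trials"`) when a simulated session
#' is supplied.  A trial occupies cue delay + slower partner's RT +
#' feedback + inter-trial interval; the task block is padded to the nominal
#' duration.  Trials that would overflow the block raise a config error.
#'
#' @param acq an [acquisition_config()].
#' @param session optional `dyad_session`; `NULL` gives the fixed nominal
#'   timeline with no trial markers.
#' @return Data frame with columns `label`, `onset`, `duration` (seconds)
#'   and, if a session was given, attribute `"trials"`: a data frame with
#'   `block`, `trial`, `onset`, `duration`.
#' @export
make_timeline <- function(acq = acquisition_config(), session = NULL) {
  durs <- c(acq$rest_duration, acq$task_duration, acq$rest_duration,
            acq$task_duration, acq$rest_duration)
  timeline <- data.frame(
    label = SEGMENT_LABELS,
    onset = cumsum(c(0, durs[-5L])),
    duration = durs,
    stringsAsFactors = FALSE
  )
  if (!is.null(session)) {
    tr <- session$trials
    blocks <- sort(unique(tr$block_index))
    if (length(blocks) > 2L) {
      stop_config("timeline supports at most 2 task blocks, got ",
                  length(blocks))
    }
    rows <- lapply(blocks, function(b) {
      sub <- tr[tr$block_index == b, ]
      tdur <- sub$cue_delay + pmax(sub$rt1, sub$rt2) + acq$feedback_s +
        acq$iti_s
      onset_in_block <- cumsum(c(0, tdur[-length(tdur)]))
      if (length(tdur) &&
          onset_in_block[length(tdur)] + tdur[length(tdur)] >
            acq$task_duration) {
        stop_config("trials of block ", b, " overflow the ",
                    acq$task_duration, " s task segment")
      }
      block_onset <- timeline$onset[timeline$label == paste0("task", b)]
      data.frame(block = b, trial = sub$trial_index,
                 onset = block_onset + onset_in_block, duration = tdur)
    })
    attr(timeline, "trials") <- do.call(rbind, rows)
  }
  timeline
}

#' Total timeline duration in seconds
#' @param timeline a timeline data frame from [make_timeline()].
#' @return Numeric scalar.
#' @export
timeline_duration <- function(timeline) {
  with(timeline, max(onset + duration))
}

# indices of the samples belonging to the named segments
segment_sample_index <- function(timeline, labels, fs, n) {
  sel <- timeline[timeline$label %in% labels, , drop = FALSE]
  if (nrow(sel) == 0L) stop_invalid("segments not found: ",
                                    paste(labels, collapse = ", "))
  idx <- integer(0)
  for (i in seq_len(nrow(sel))) {
    from <- floor(sel$onset[i] * fs) + 1L
    to <- min(ceiling((sel$onset[i] + sel$duration[i]) * fs), n)
    idx <- c(idx, seq.int(from, to))
  }
  sort(unique(idx))
}

validate_timeline <- function(timeline) {
  if (!all(c("label", "onset", "duration") %in% names(timeline))) {
    stop_invalid("timeline must have label, onset, duration columns")
  }
  tl <- timeline[order(timeline$onset), ]
  ends <- tl$onset + tl$duration
  if (any(tl$onset[-1L] < ends[-nrow(tl)] - 1e-9)) {
    stop_invalid("timeline segments overlap")
  }
  invisible(timeline)
}
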