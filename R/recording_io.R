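# Plain-text recording I/O.
#
# A recording is stored as one wide TSV per participant (column `time_s`
# followed by `ch<index>_<slice>` columns, where <slice> is the wavelength
# in nm or the chromophore name), a BIDS-style `events.tsv` (onset,
# duration, trial_type) and a `meta.json` with stage, sampling rate,
# wavelengths and missing-channel sets.  Everything round-trips losslessly
# to within float formatting (16 significant digits).

slice_names <- function(rec) {
  if (rec$stage == "hb") c("HbO", "HbR") else paste0(rec$wavelengths, "nm")
}

#' Write a recording to a directory of TSV/JSON files
#'
#' @param rec a `hyperscan_recording`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_recording <- function(rec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- n_samples(rec)
  nch <- dim(rec$data)[2L]
  sl <- slice_names(rec)
  for (p in 1:2) {
    cols <- list(time_s = (seq_len(n) - 1) / rec$fs)
    for (ch in seq_len(nch)) {
      for (s in 1:2) {
        cols[[sprintf("ch%02d_%s", ch, sl[s])]] <- rec$data[p, ch, s, ]
      }
    }
    df <- as.data.frame(cols, check.names = FALSE)
    path <- file.path(dir, sprintf("participant%d.tsv", p))
    num <- vapply(df, is.double, logical(1L))
    df[num] <- lapply(df[num], function(x) formatC(x, digits = 16,
                                                   format = "g"))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  ev <- data.frame(onset = rec$timeline$onset,
                   duration = rec$timeline$duration,
                   trial_type = rec$timeline$label)
  write.table(ev, file.path(dir, "events.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  meta <- list(stage = rec$stage, fs = rec$fs,
               wavelengths = rec$wavelengths,
               n_channels = nch,
               missing = rec$missing,
               distance = rec$constants$distance %||% 3.0,
               dpf = rec$constants$dpf %||% c(6, 6))
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a recording written by [write_recording()]
#'
#' @param dir directory containing `participant1.tsv`, `participant2.tsv`,
#'   `events.tsv` and `meta.json`.
#' @return A `hyperscan_recording`.
#' @export
read_recording <- function(dir) {
  meta_path <- file.path(dir, "meta.json")
  if (!file.exists(meta_path)) stop_invalid("missing meta.json in ", dir)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  timeline <- read_events(file.path(dir, "events.tsv"))
  nch <- meta$n_channels
  datas <- lapply(1:2, function(p) {
    path <- file.path(dir, sprintf("participant%d.tsv", p))
    if (!file.exists(path)) stop_invalid("missing ", path)
    read.delim(path, check.names = FALSE)
  })
  n <- nrow(datas[[1L]])
  sl <- if (meta$stage == "hb") c("HbO", "HbR") else
    paste0(meta$wavelengths, "nm")
  arr <- array(NA_real_, c(2L, nch, 2L, n))
  for (p in 1:2) {
    df <- datas[[p]]
    for (ch in seq_len(nch)) {
      for (s in 1:2) {
        col <- sprintf("ch%02d_%s", ch, sl[s])
        if (!col %in% names(df)) {
          stop_invalid("participant ", p, " file lacks column '", col, "'")
        }
        arr[p, ch, s, ] <- df[[col]]
      }
    }
  }
  constants <- beer_lambert_constants(meta$wavelengths,
                                      dpf = meta$dpf %||% 6,
                                      distance = meta$distance %||% 3)
  missing <- meta$missing %||% list(integer(0), integer(0))
  missing <- lapply(missing, function(m) as.integer(unlist(m)))
  if (length(missing) < 2L) missing <- list(integer(0), integer(0))
  new_recording(stage = meta$stage, data = arr, fs = meta$fs,
                timeline = timeline, wavelengths = meta$wavelengths,
                constants = constants, missing = missing)
}

#' Read a BIDS-style events table
#'
#' Validates the five canonical segments and rejects overlapping segments.
#'
#' @param path path to `events.tsv` (columns onset, duration, trial_type).
#' @return Timeline data frame (`label`, `onset`, `duration`).
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop_invalid("missing events file ", path)
  ev <- read.delim(path)
  need <- c("onset", "duration", "trial_type")
  if (!all(need %in% names(ev))) {
    stop_invalid("events file must have columns ",
                 paste(need, collapse = ", "))
  }
  timeline <- data.frame(label = ev$trial_type, onset = ev$onset,
                         duration = ev$duration, stringsAsFactors = FALSE)
  validate_timeline(timeline)
  timeline
}
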