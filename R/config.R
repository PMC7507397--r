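# Hierarchical run configuration (JSON on disk).  Unknown keys are
# rejected so typos cannot silently fall back to defaults.

#' Default run configuration
#'
#' All defaults mirror the paradigm's printed constants: 10 Hz sampling,
#' 22 channels, 30/150/30/150/30 s block design, 3.2-12.8 s analysis band,
#' FDR q = 0.05, group sizes 17/16/10.
#'
#' @return Nested list of class `"run_config"`.
#' @export
default_config <- function() {
  structure(list(
    master_seed = 1L,
    output_dir = "coopsync-run",
    task = list(
      group_sizes = list(delayed = 17L, immediate = 16L, none = 10L),
      tie_rule = "leq"
    ),
    signals = list(
      fs = 10, rest_duration = 30, task_duration = 150,
      wavelengths = c(690, 830), source_detector_distance = 3.0,
      coupling_channel = 19L, coupling_period = 6.4,
      coupling_strengths = list(delayed = 5, immediate = 0, none = 0.8),
      coupling_lag = 0, artifact_rate = 0.5
    ),
    preprocessing = list(
      snr_threshold = 2, artifact_window = 1.0, amp_threshold = 5,
      slope_threshold = 80, correction = "spline", dpf = 6.0
    ),
    wavelet = list(
      omega0 = 6, voices_per_octave = 12L, period_min = 2, period_max = 64,
      coi_policy = "exclude"
    ),
    band = list(period_lo = 3.2, period_hi = 12.8, baseline = "rest2"),
    gca = list(channel = NULL, max_order = 20L, order = NULL),
    stats = list(fdr_q = 0.05, tail = "one")
  ), class = "run_config")
}

#' Load a run configuration from JSON
#'
#' Values present in the file override the defaults; unknown keys raise a
#' config error.
#'
#' @param path JSON file, or `NULL` for pure defaults.
#' @return A `run_config`.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  merge_config(cfg, user, "")
}

merge_config <- function(base, user, prefix) {
  for (key in names(user)) {
    full <- if (nzchar(prefix)) paste0(prefix, ".", key) else key
    if (!key %in% names(base)) stop_config("unknown config key: ", full)
    if (is.list(base[[key]]) && !is.null(names(base[[key]]))) {
      if (!is.list(user[[key]])) {
        stop_config("config key ", full, " must be a mapping")
      }
      base[[key]] <- merge_config(base[[key]], user[[key]], full)
    } else {
      base[[key]] <- user[[key]]
    }
  }
  base
}

#' Write a configuration to JSON
#' @param config a `run_config`.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(path)
}

config_objects <- function(cfg) {
  acq <- acquisition_config(
    fs = cfg$signals$fs, wavelengths = unlist(cfg$signals$wavelengths),
    rest_duration = cfg$signals$rest_duration,
    task_duration = cfg$signals$task_duration,
    source_detector_distance = cfg$signals$source_detector_distance
  )
  coupling <- coupling_spec(
    coupled_channels = cfg$signals$coupling_channel,
    period = cfg$signals$coupling_period,
    strength_by_strategy = unlist(cfg$signals$coupling_strengths),
    lag = cfg$signals$coupling_lag
  )
  noise <- noise_spec(artifact_rate = cfg$signals$artifact_rate)
  wparams <- wavelet_params(
    omega0 = cfg$wavelet$omega0,
    voices_per_octave = cfg$wavelet$voices_per_octave,
    period_min = cfg$wavelet$period_min,
    period_max = cfg$wavelet$period_max,
    coi_policy = cfg$wavelet$coi_policy
  )
  band <- band_spec(cfg$band$period_lo, cfg$band$period_hi)
  artifacts <- artifact_params(
    window = cfg$preprocessing$artifact_window,
    amp_threshold = cfg$preprocessing$amp_threshold,
    slope_threshold = cfg$preprocessing$slope_threshold,
    correction = cfg$preprocessing$correction
  )
  list(acq = acq, coupling = coupling, noise = noise, wparams = wparams,
       band = band, artifacts = artifacts)
}
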