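# Forward model for two-brain fNIRS recordings.
#
# Each participant x channel gets a "true" oxyhemoglobin series built from
# standard physiological confounds (1/f drift, cardiac, respiratory and
# Mayer-wave oscillations, white noise).  During the chosen task segments,
# channels listed in the coupling spec additionally receive a shared
# narrowband stochastic oscillation whose amplitude depends on the dyad's
# strategy - this is the planted inter-brain synchronization the analysis
# chain is supposed to recover.  Hemoglobin is pushed through the modified
# Beer-Lambert law to optical density and raw intensity so that
# preprocessing has to invert a realistic forward chain.

#' Optode / channel layout
#'
#' Channel positions are labels only (no 3-D geometry).  The default mirrors
#' a 3x5 optode holder with 22 measurement channels per participant, a
#' right frontal-parietal region of interest, and channel 19 as the
#' canonical coupling target.
#'
#' @param n_channels channels per participant (default 22).
#' @param roi_channels integer set of ROI channels.
#' @param target_channel the channel where planted coupling concentrates.
#' @return List of class `"probe_layout"`.
#' @export
probe_layout <- function(n_channels = 22L, roi_channels = 12:22,
                         target_channel = 19L) {
  if (any(roi_channels < 1L) || any(roi_channels > n_channels)) {
    stop_config("roi_channels out of 1..", n_channels)
  }
  if (!(target_channel %in% roi_channels)) {
    stop_config("target_channel must belong to roi_channels")
  }
  structure(list(n_channels = as.integer(n_channels),
                 grid = "3x5", roi_channels = as.integer(roi_channels),
                 target_channel = as.integer(target_channel)),
            class = "probe_layout")
}

#' Inter-brain coupling specification
#'
#' @param coupled_channels channels carrying the shared oscillation.
#' @param period oscillation period in seconds (default 6.4, centre of the
#'   3.2-12.8 s analysis band).
#' @param strength_by_strategy named amplitudes (ratio to the 1/f noise SD)
#'   per strategy; default delayed 5 > none 0.8 > immediate 0.  The delayed
#'   default is deliberately strong: the 30 s rest baseline makes the
#'   task-minus-rest contrast noisy (see the methods vignette), and the
#'   planted effect is meant to be reliably detectable by the channel-wise
#'   group tests, as a strong planted effect should be.
#' @param lag seconds by which participant 2's copy trails participant 1's
#'   (negative values lead); nonzero lags create directional ground truth
#'   for causality analysis.
#' @param active_segments timeline labels during which coupling is on.
#' @param bandwidth_octaves half-bandwidth of the narrowband oscillation in
#'   octaves (default 0.5); a stochastic band-limited process rather than a
#'   sinusoid, so coherence stays below the degenerate value of 1.
#' @return List of class `"coupling_spec"`.
#' @export
coupling_spec <- function(coupled_channels = 19L, period = 6.4,
                          strength_by_strategy = c(delayed = 5,
                                                   immediate = 0,
                                                   none = 0.8),
                          lag = 0, active_segments = c("task1", "task2"),
                          bandwidth_octaves = 0.5) {
  assert_scalar_num(period, "period", lo = 0, strict_lo = TRUE)
  if (any(strength_by_strategy < 0)) stop_config("strengths must be >= 0")
  structure(list(coupled_channels = as.integer(coupled_channels),
                 period = period,
                 strength_by_strategy = strength_by_strategy,
                 lag = lag, active_segments = active_segments,
                 bandwidth_octaves = bandwidth_octaves),
            class = "coupling_spec")
}

#' Physiological noise specification
#'
#' Amplitudes are in the generator's hemoglobin units (micromolar).  The
#' Mayer wave sits at 0.1 Hz, deliberately inside the 3.2-12.8 s analysis
#' band, so the task-minus-rest contrast is stress-tested against a
#' coherent-looking confound present in rest and task alike.
#'
#' @param pink_exponent spectral exponent alpha of the 1/f^alpha drift.
#' @param pink_sd SD of the 1/f component (the generator's reference
#'   amplitude unit).
#' @param cardiac,respiration,mayer `c(freq_hz, amplitude)` pairs.
#' @param white_sd white noise SD.
#' @param artifact_rate motion artifact events per minute (per participant).
#' @param artifact_kinds subset of `"spike"`, `"baseline_shift"`.
#' @param shot_noise_od SD of instrument noise added in optical-density
#'   units at the intensity stage.
#' @return List of class `"noise_spec"`.
#' @export
noise_spec <- function(pink_exponent = 1, pink_sd = 1.0,
                       cardiac = c(1.0, 0.5), respiration = c(0.25, 0.6),
                       mayer = c(0.1, 0.8), white_sd = 0.3,
                       artifact_rate = 0,
                       artifact_kinds = c("spike", "baseline_shift"),
                       shot_noise_od = 3e-4) {
  for (p in list(cardiac, respiration, mayer)) {
    if (length(p) != 2L || p[1L] < 0 || p[2L] < 0) {
      stop_config("oscillation specs must be c(freq >= 0, amp >= 0)")
    }
  }
  if (pink_sd < 0 || white_sd < 0 || artifact_rate < 0) {
    stop_config("noise amplitudes and rates must be >= 0")
  }
  structure(list(pink_exponent = pink_exponent, pink_sd = pink_sd,
                 cardiac = cardiac, respiration = respiration,
                 mayer = mayer, white_sd = white_sd,
                 artifact_rate = artifact_rate,
                 artifact_kinds = artifact_kinds,
                 shot_noise_od = shot_noise_od),
            class = "noise_spec")
}

# --- elementary generators ------------------------------------------------

# 1/f^alpha noise via spectral shaping, unit SD
pink_noise <- function(n, fs, alpha = 1) {
  if (n < 4L) return(rnorm(n))
  m <- stats::nextn(n, 2)
  freqs <- c(0, seq_len(m - 1)) / m * fs
  freqs[freqs > fs / 2] <- fs - freqs[freqs > fs / 2]
  amp <- c(0, 1 / freqs[-1L]^(alpha / 2))
  phase <- runif(m, 0, 2 * pi)
  spec <- amp * exp(1i * phase)
  # hermitian symmetry for a real series
  half <- 2:(m / 2)
  spec[m + 2 - half] <- Conj(spec[half])
  spec[m / 2 + 1] <- Re(spec[m / 2 + 1])
  x <- Re(fft(spec, inverse = TRUE))[seq_len(n)]
  x <- x - mean(x)
  s <- sd(x)
  if (s > 0) x / s else x
}

# narrowband stochastic oscillation: white noise shaped by a Gaussian
# profile in log2-frequency around 1/period, unit SD
narrowband_noise <- function(n, fs, period, bandwidth_octaves = 0.5) {
  if (period <= 2 / fs) stop_config("period ", period,
                                    " s not resolvable at fs ", fs)
  m <- stats::nextn(max(n, 16L), 2)
  f0 <- 1 / period
  k <- seq_len(m / 2 - 1)
  f <- k / m * fs
  w <- exp(-(log2(f / f0))^2 / (2 * (bandwidth_octaves / 2)^2))
  phase <- runif(length(k), 0, 2 * pi)
  spec <- complex(modulus = 0, argument = 0, length.out = m)
  spec[k + 1] <- w * exp(1i * phase)
  spec[m + 1 - k] <- Conj(spec[k + 1])
  x <- Re(fft(spec, inverse = TRUE))[seq_len(n)]
  x <- x - mean(x)
  s <- sd(x)
  if (s > 0) x / s else x
}

sinusoid <- function(n, fs, freq, amp, jitter = 0.02) {
  t <- (seq_len(n) - 1) / fs
  f <- freq * (1 + runif(1L, -jitter, jitter))
  amp * sin(2 * pi * f * t + runif(1L, 0, 2 * pi))
}

# cosine-ramped 0/1 mask over the active segments
segment_mask <- function(timeline, labels, fs, n, ramp = 2) {
  mask <- numeric(n)
  sel <- timeline[timeline$label %in% labels, , drop = FALSE]
  t <- (seq_len(n) - 1) / fs
  for (i in seq_len(nrow(sel))) {
    a <- sel$onset[i]
    b <- a + sel$duration[i]
    inside <- t >= a & t < b
    m <- numeric(n)
    m[inside] <- 1
    up <- t >= a & t < a + ramp
    m[up] <- 0.5 * (1 - cos(pi * (t[up] - a) / ramp))
    down <- t >= b - ramp & t < b
    m[down] <- 0.5 * (1 - cos(pi * (b - t[down]) / ramp))
    mask <- pmax(mask, m)
  }
  mask
}

# --- recording object -----------------------------------------------------

new_recording <- function(stage, data, fs, timeline, wavelengths, constants,
                          ground_truth = NULL, missing = NULL) {
  structure(list(stage = stage, data = data, fs = fs, timeline = timeline,
                 wavelengths = wavelengths, constants = constants,
                 ground_truth = ground_truth,
                 missing = missing %||%
                   list(integer(0), integer(0))),
            class = "hyperscan_recording")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.hyperscan_recording <- function(x, ...) {
  d <- dim(x$data)
  cat("<hyperscan_recording> stage=", x$stage, ", ", d[1L], " participants x ",
      d[2L], " channels x ", d[3L], " x ", d[4L], " samples @ ", x$fs,
      " Hz\n", sep = "")
  invisible(x)
}

n_samples <- function(rec) dim(rec$data)[4L]

#' Synthesize a dyad's raw two-participant recording
#'
#' Builds true HbO/HbR series for every participant and channel, plants the
#' strategy-dependent shared oscillation on the coupled channels during the
#' active segments (participant 2 lagged by `coupling$lag` seconds), and
#' converts hemoglobin to optical density and raw intensity through the
#' modified Beer-Lambert forward model.  The true hemoglobin arrays, the
#' coupling waveform and the segment mask are retained as ground truth.
#'
#' @param session a `dyad_session` (provides strategy and trial timing).
#' @param layout a [probe_layout()].
#' @param acq an [acquisition_config()].
#' @param coupling a [coupling_spec()].
#' @param noise a [noise_spec()].
#' @param seed integer seed.
#' @param constants Beer-Lambert constants; defaults derive from `acq`.
#' @return A `hyperscan_recording` at stage `"intensity"` with data array
#'   `[participant(2), channel, wavelength(2), time]`.
#' @export
synthesize_dyad_recording <- function(session, layout = probe_layout(),
                                      acq = acquisition_config(),
                                      coupling = coupling_spec(),
                                      noise = noise_spec(), seed = NULL,
                                      constants = NULL) {
  constants <- constants %||%
    beer_lambert_constants(acq$wavelengths,
                           distance = acq$source_detector_distance)
  timeline <- make_timeline(acq, session)
  fs <- acq$fs
  n <- round(timeline_duration(timeline) * fs)
  if (coupling$period <= 2 / fs ||
      coupling$period >= min(timeline$duration)) {
    stop_config("coupling period ", coupling$period,
                " s outside resolvable range")
  }
  strength <- coupling$strength_by_strategy[[session$strategy]]
  if (is.null(strength)) stop_config("no coupling strength for strategy ",
                                     session$strategy)
  nch <- layout$n_channels
  with_seed(seed, {
    lag_samp <- round(coupling$lag * fs)
    u <- narrowband_noise(n + abs(lag_samp), fs, coupling$period,
                          coupling$bandwidth_octaves)
    off <- max(lag_samp, 0L)
    u1 <- u[off + seq_len(n)]
    u2 <- u[off - lag_samp + seq_len(n)]
    mask <- segment_mask(timeline, coupling$active_segments, fs, n)

    hbo <- array(0, c(2L, nch, n))
    hbr <- array(0, c(2L, nch, n))
    for (p in 1:2) {
      shared <- if (p == 1L) u1 else u2
      for (ch in seq_len(nch)) {
        x <- noise$pink_sd * pink_noise(n, fs, noise$pink_exponent) +
          sinusoid(n, fs, noise$cardiac[1L], noise$cardiac[2L]) +
          sinusoid(n, fs, noise$respiration[1L], noise$respiration[2L]) +
          sinusoid(n, fs, noise$mayer[1L], noise$mayer[2L]) +
          rnorm(n, 0, noise$white_sd)
        if (ch %in% coupling$coupled_channels && strength > 0) {
          x <- x + strength * noise$pink_sd * shared * mask
        }
        hbo[p, ch, ] <- x
        hbr[p, ch, ] <- -x / 3 +
          rnorm(n, 0, max(noise$pink_sd, noise$white_sd) / 3)
      }
    }
    # forward modified Beer-Lambert: uM -> mM -> delta-OD -> intensity
    intens <- array(NA_real_, c(2L, nch, 2L, n))
    for (p in 1:2) {
      for (ch in seq_len(nch)) {
        od <- hb_to_od_matrix(hbo[p, ch, ] / 1000, hbr[p, ch, ] / 1000,
                              constants)
        od <- od + matrix(rnorm(2L * n, 0, noise$shot_noise_od), n, 2L)
        intens[p, ch, 1L, ] <- exp(-od[, 1L])
        intens[p, ch, 2L, ] <- exp(-od[, 2L])
      }
    }
    new_recording(
      stage = "intensity", data = intens, fs = fs, timeline = timeline,
      wavelengths = acq$wavelengths, constants = constants,
      ground_truth = list(hbo = hbo, hbr = hbr, coupling_waveform = u1,
                          mask = mask, strength = strength,
                          lag = coupling$lag,
                          coupled_channels = coupling$coupled_channels)
    )
  })
}

#' Inject motion artifacts
#'
#' Adds spike and transient baseline-shift artifacts at Poisson-distributed
#' times (rate `noise$artifact_rate` per minute per participant).  Both
#' kinds are applied in optical-density units to all channels of the moving
#' participant (scaled per channel/wavelength), as head movement affects the
#' whole probe.  Baseline shifts are boxcars of 4-10 s that return to
#' baseline: a persistent step could not be corrected later without touching
#' samples outside the flagged span.  The ground-truth mask
#' (participant x time) covers the full extent of every artifact.
#'
#' @param rec recording at stage `"intensity"` or `"od"`.
#' @param noise a [noise_spec()] (rate and kinds are read from it).
#' @param seed integer seed.
#' @return List with `rec` (corrupted recording) and `mask`
#'   (2 x time logical matrix).
#' @export
inject_motion_artifacts <- function(rec, noise = noise_spec(artifact_rate = 1),
                                    seed = NULL) {
  if (!rec$stage %in% c("intensity", "od")) {
    stop_invalid("artifact injection requires intensity or od stage")
  }
  n <- n_samples(rec)
  fs <- rec$fs
  nch <- dim(rec$data)[2L]
  mask <- matrix(FALSE, 2L, n)
  if (noise$artifact_rate <= 0) {
    return(list(rec = rec, mask = mask))
  }
  with_seed(seed, {
    dur_min <- n / fs / 60
    for (p in 1:2) {
      k <- rpois(1L, noise$artifact_rate * dur_min)
      if (k == 0L) next
      onsets <- sort(runif(k, 0, n / fs))
      for (ev in seq_len(k)) {
        kind <- sample(noise$artifact_kinds, 1L)
        t0 <- onsets[ev]
        i0 <- max(1L, round(t0 * fs))
        if (kind == "spike") {
          len <- max(3L, round(runif(1L, 0.3, 0.8) * fs))
          idx <- i0:min(i0 + len - 1L, n)
          shape <- exp(-((seq_along(idx) - length(idx) / 2)^2) /
                         (2 * (length(idx) / 6)^2))
        } else {
          len <- round(runif(1L, 4, 10) * fs)
          idx <- i0:min(i0 + len - 1L, n)
          shape <- rep(1, length(idx))
        }
        sign_ev <- sample(c(-1, 1), 1L)
        for (ch in seq_len(nch)) {
          for (wl in 1:2) {
            x <- rec$data[p, ch, wl, ]
            od_sd <- mad(diff(x) / x[-1L]) / sqrt(2) + 1e-6
            amp <- sign_ev * runif(1L, 8, 16) * od_sd
            a <- numeric(n)
            a[idx] <- amp * shape
            rec$data[p, ch, wl, ] <- if (rec$stage == "intensity") {
              x * exp(-a)
            } else {
              x + a
            }
          }
        }
        mask[p, idx] <- TRUE
      }
    }
    list(rec = rec, mask = mask)
  })
}

#' Degrade the signal-to-noise ratio of selected channels
#'
#' Scales the optical-density fluctuations of the listed channels by
#' `factor` (both participants unless restricted), e.g. to emulate poor
#' optode contact; `factor = 1` is the identity.  Operating in OD space
#' keeps intensity strictly positive and makes the SNR ratio scale as
#' `1/factor`.
#'
#' @param rec recording at stage `"intensity"`.
#' @param channels channel indices to degrade.
#' @param factor fluctuation inflation factor (>= 0).
#' @param participants which participants to touch (default both).
#' @param seed seed for the added noise component.
#' @return The degraded recording.
#' @export
degrade_channel_snr <- function(rec, channels, factor, participants = 1:2,
                                seed = NULL) {
  if (rec$stage != "intensity") stop_invalid("requires intensity stage")
  nch <- dim(rec$data)[2L]
  if (length(channels) == 0L) return(rec)
  if (any(channels < 1L) || any(channels > nch)) {
    stop_invalid("unknown channel index in ", paste(channels, collapse = ","))
  }
  assert_scalar_num(factor, "factor", lo = 0)
  with_seed(seed, {
    for (p in participants) {
      for (ch in channels) {
        for (wl in 1:2) {
          logi <- log(rec$data[p, ch, wl, ])
          m <- mean(logi)
          rec$data[p, ch, wl, ] <- exp(m + (logi - m) * factor)
        }
      }
    }
    rec
  })
}
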