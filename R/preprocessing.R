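# Preprocessing chain for raw two-participant optical recordings:
# SNR-based channel rejection -> optical density -> motion-artifact
# detection and spline correction -> modified Beer-Lambert inversion.
# Deliberately NO band-pass filtering: the downstream analysis is wavelet
# based and supplies its own frequency selectivity.

#' Motion-artifact detection/correction parameters
#'
#' @param window dilation window in seconds applied around detections.
#' @param amp_threshold amplitude criterion: a sample is flagged when its
#'   deviation from a 20 s running-median baseline exceeds this many robust
#'   SDs of that deviation signal.
#' @param slope_threshold slope criterion in robust SDs per second
#'   (sample-to-sample difference times the sampling rate).
#' @param baseline_s running-median baseline length in seconds; artifacts
#'   shorter than this stand out from the baseline, so it bounds the
#'   longest correctable event.
#' @param correction `"spline"` (default) or `"none"`.
#' @return List of class `"artifact_params"`.
#' @export
artifact_params <- function(window = 1.0, amp_threshold = 5,
                            slope_threshold = 80, baseline_s = 20,
                            correction = c("spline", "none")) {
  correction <- match.arg(correction)
  if (window <= 0 || amp_threshold <= 0 || slope_threshold <= 0 ||
      baseline_s <= 0) {
    stop_invalid("artifact parameters must be positive")
  }
  structure(list(window = window, amp_threshold = amp_threshold,
                 slope_threshold = slope_threshold, baseline_s = baseline_s,
                 correction = correction),
            class = "artifact_params")
}

#' Reject channels with poor signal-to-noise ratio
#'
#' Computes, per participant/channel, the ratio of mean raw intensity to its
#' standard deviation (the worse of the two wavelengths) and flags channels
#' with a ratio below `threshold`.  The ratio is computed on raw intensity
#' over the whole recording and is invariant to a positive per-channel gain.
#'
#' @param rec recording at stage `"intensity"`.
#' @param threshold rejection threshold (default 2).
#' @return Data frame with `participant`, `channel`, `snr_ratio`,
#'   `rejected`.
#' @export
reject_low_snr <- function(rec, threshold = 2) {
  if (rec$stage != "intensity") {
    stop_invalid("SNR rejection operates on the intensity stage, got ",
                 rec$stage)
  }
  if (any(rec$data <= 0)) stop_invalid("intensity must be positive")
  nch <- dim(rec$data)[2L]
  out <- expand.grid(participant = 1:2, channel = seq_len(nch))
  out <- out[order(out$participant, out$channel), ]
  rownames(out) <- NULL
  eps <- 1e-12
  out$snr_ratio <- mapply(function(p, ch) {
    min(vapply(1:2, function(wl) {
      x <- rec$data[p, ch, wl, ]
      mean(x) / (sd(x) + eps)
    }, numeric(1L)))
  }, out$participant, out$channel)
  out$rejected <- out$snr_ratio < threshold
  out
}

#' Apply a channel-quality report to a recording
#'
#' Marks rejected channels missing; they are dropped from all downstream
#' per-channel outputs (a dyad's channel is analysed only when valid for
#' both partners).
#'
#' @param rec a recording.
#' @param quality data frame from [reject_low_snr()].
#' @return The recording with its `missing` channel sets updated.
#' @export
apply_channel_rejection <- function(rec, quality) {
  for (p in 1:2) {
    bad <- quality$channel[quality$participant == p & quality$rejected]
    rec$missing[[p]] <- sort(unique(c(rec$missing[[p]], bad)))
  }
  rec
}

#' Convert raw intensity to optical density changes
#'
#' `OD(t) = -log(I(t) / mean(I))` per participant, channel and wavelength;
#' invariant to constant gain changes.
#'
#' @param rec recording at stage `"intensity"` with positive data.
#' @return Recording at stage `"od"`.
#' @export
intensity_to_od <- function(rec) {
  if (rec$stage != "intensity") stop_invalid("expected intensity stage")
  bad <- which(rec$data <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    chs <- unique(paste0("p", bad[, 1L], "/ch", bad[, 2L]))
    stop_invalid("non-positive intensity in channel(s): ",
                 paste(chs, collapse = ", "))
  }
  out <- rec
  nch <- dim(rec$data)[2L]
  for (p in 1:2) {
    for (ch in seq_len(nch)) {
      for (wl in 1:2) {
        x <- rec$data[p, ch, wl, ]
        out$data[p, ch, wl, ] <- -log(x / mean(x))
      }
    }
  }
  out$stage <- "od"
  out
}

# robust SD of a baseline-corrected series (running-median detrended)
robust_sd_detrended <- function(x, fs, baseline_s = 20) {
  k <- max(3L, round(baseline_s * fs))
  if (k %% 2L == 0L) k <- k + 1L
  k <- min(k, if (length(x) %% 2L == 0L) length(x) - 1L else length(x))
  z <- x - stats::runmed(x, k)
  list(z = z, sd = max(mad(z), 1e-12))
}

#' Detect motion artifacts in optical-density data
#'
#' A sample is flagged when, on any channel/wavelength of a participant,
#' its deviation from a slow running-median baseline exceeds
#' `amp_threshold x robust SD` of that deviation, or the sample-to-sample
#' slope exceeds `slope_threshold x robust SD` per second.  The deviation
#' criterion catches both brief spikes and multi-second baseline-shift
#' plateaus (the 20 s baseline does not absorb them); the slope criterion
#' catches fast transients.  The resulting mask is dilated by one window.
#'
#' @param rec recording at stage `"od"`.
#' @param params an [artifact_params()].
#' @return Logical matrix (participant x time).
#' @export
detect_motion_artifacts <- function(rec, params = artifact_params()) {
  if (rec$stage != "od") stop_invalid("artifact detection expects od stage")
  n <- n_samples(rec)
  fs <- rec$fs
  nch <- dim(rec$data)[2L]
  w <- max(2L, round(params$window * fs))
  mask <- matrix(FALSE, 2L, n)
  for (p in 1:2) {
    flagged <- logical(n)
    for (ch in seq_len(nch)) {
      for (wl in 1:2) {
        x <- rec$data[p, ch, wl, ]
        rb <- robust_sd_detrended(x, fs, params$baseline_s)
        amp_bad <- abs(rb$z) > params$amp_threshold * rb$sd
        slope_bad <- c(FALSE,
                       abs(diff(x)) * fs > params$slope_threshold * rb$sd)
        flagged <- flagged | amp_bad | slope_bad
      }
    }
    mask[p, ] <- dilate_mask(flagged, w)
  }
  mask
}

dilate_mask <- function(flagged, w) {
  n <- length(flagged)
  idx <- which(flagged)
  if (length(idx) == 0L) return(flagged)
  out <- logical(n)
  for (i in idx) {
    out[max(1L, i - w):min(n, i + w)] <- TRUE
  }
  out
}

#' Correct flagged motion-artifact segments
#'
#' Replaces every flagged run with a smooth cubic-spline bridge estimated
#' from flanking clean data (plus the local high-frequency detail of the
#' flanks' robust SD is *not* reintroduced - the bridge is the baseline
#' estimate).  Unflagged samples are returned bit-identical.  If a
#' participant's entire recording is flagged, all their channels are marked
#' missing.
#'
#' @param rec recording at stage `"od"`.
#' @param mask logical participant x time matrix.
#' @param params an [artifact_params()]; `correction = "none"` returns the
#'   input unchanged.
#' @return The corrected recording.
#' @export
correct_motion <- function(rec, mask, params = artifact_params()) {
  if (rec$stage != "od") stop_invalid("motion correction expects od stage")
  if (!all(dim(mask) == c(2L, n_samples(rec)))) {
    stop_invalid("mask not aligned to recording")
  }
  if (params$correction == "none") return(rec)
  n <- n_samples(rec)
  fs <- rec$fs
  nch <- dim(rec$data)[2L]
  flank <- max(3L, round(2 * fs))
  for (p in 1:2) {
    bad <- mask[p, ]
    if (!any(bad)) next
    if (all(bad)) {
      rec$missing[[p]] <- seq_len(nch)
      next
    }
    runs <- rle(bad)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (r in which(runs$values)) {
      i0 <- starts[r]
      i1 <- ends[r]
      pre <- max(1L, i0 - flank):max(1L, i0 - 1L)
      post <- min(n, i1 + 1L):min(n, i1 + flank)
      pre <- pre[!bad[pre]]
      post <- post[!bad[post]]
      if (length(pre) < 2L || length(post) < 2L) {
        anchors <- c(pre, post)
        if (length(anchors) < 2L) next
      }
      for (ch in seq_len(nch)) {
        for (wl in 1:2) {
          x <- rec$data[p, ch, wl, ]
          # spline through robust knots (medians of flank thirds) rather
          # than raw samples: interpolating noisy anchors directly lets the
          # cubic swing wildly across multi-second gaps
          kx <- ky <- numeric(0)
          for (flank in list(pre, post)) {
            if (length(flank) == 0L) next
            parts <- split(flank, cut(seq_along(flank), 3, labels = FALSE))
            kx <- c(kx, vapply(parts, median, numeric(1L)))
            ky <- c(ky, vapply(parts, function(ii) median(x[ii]),
                               numeric(1L)))
          }
          keep <- !duplicated(kx)
          fit <- spline(x = kx[keep], y = ky[keep], xout = i0:i1,
                        method = "natural")
          rec$data[p, ch, wl, i0:i1] <- fit$y
        }
      }
    }
  }
  rec
}

#' Convert optical density to hemoglobin concentration changes
#'
#' Inverts the modified Beer-Lambert relation per channel and sample: a 2x2
#' linear solve of `dOD_lambda = sum_c eps[c, lambda] * dC_c * d * DPF_lambda`
#' for `dC = (HbO, HbR)`.  Output is in micromolar.
#'
#' @param rec recording at stage `"od"`.
#' @param constants a [beer_lambert_constants()]; defaults to those carried
#'   by the recording.
#' @return Recording at stage `"hb"`, slice 1 of dimension 3 = HbO, slice 2
#'   = HbR.
#' @export
od_to_hb <- function(rec, constants = NULL) {
  if (rec$stage != "od") stop_invalid("expected od stage")
  constants <- constants %||% rec$constants
  e <- constants$extinction
  d <- constants$distance
  dpf <- constants$dpf
  # dOD = A %*% dC with A[wl, c] = eps[c, wl] * d * dpf[wl]; dC in mM
  a <- rbind(e[, 1L] * d * dpf[1L], e[, 2L] * d * dpf[2L])
  if (abs(det(a)) < 1e-10) stop_config("singular extinction system")
  ainv <- solve(a)
  out <- rec
  nch <- dim(rec$data)[2L]
  for (p in 1:2) {
    for (ch in seq_len(nch)) {
      od <- rbind(rec$data[p, ch, 1L, ], rec$data[p, ch, 2L, ])
      hb <- ainv %*% od * 1000  # mM -> uM
      out$data[p, ch, 1L, ] <- hb[1L, ]
      out$data[p, ch, 2L, ] <- hb[2L, ]
    }
  }
  out$stage <- "hb"
  out
}

#' Full preprocessing chain
#'
#' SNR rejection on raw intensity, optical-density conversion, motion
#' detection + spline correction, Beer-Lambert inversion.
#'
#' @param rec recording at stage `"intensity"`.
#' @param snr_threshold channel rejection threshold (default 2).
#' @param artifacts an [artifact_params()].
#' @return List with `rec` (stage `"hb"`), `quality` (channel report) and
#'   `artifact_mask`.
#' @export
preprocess_recording <- function(rec, snr_threshold = 2,
                                 artifacts = artifact_params()) {
  quality <- reject_low_snr(rec, snr_threshold)
  rec <- apply_channel_rejection(rec, quality)
  od <- intensity_to_od(rec)
  mask <- detect_motion_artifacts(od, artifacts)
  od <- correct_motion(od, mask, artifacts)
  hb <- od_to_hb(od)
  list(rec = hb, quality = quality, artifact_mask = mask)
}
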