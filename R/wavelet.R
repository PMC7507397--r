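# Morlet continuous wavelet transform and wavelet transform coherence (WTC).
#
# Coherence follows the standard hyperscanning recipe: squared modulus of
# the smoothed cross-spectrum over the product of the smoothed
# auto-spectra, with smoothing in time (Gaussian, SD tied to scale) and in
# scale (boxcar over 0.6 octave).  Values live in [0, 1]; a cone of
# influence (COI) marks where record edges contaminate coefficients.
#
# Everything is computed in the frequency domain on the zero-padded series:
#   psi_hat(s*w) = pi^(-1/4) sqrt(2 pi s / dt) exp(-(s*w - omega0)^2 / 2)
# for w > 0 (analytic wavelet), and the time smoother has transfer
# exp(-(s*w)^2 / 4) (a Gaussian with SD = s / sqrt(2), unit DC gain).
# The frequency-domain wavelet/transfer matrices depend only on the series
# length and parameters, so they are cached across the many channel pairs
# of a cohort run.

#' Wavelet analysis parameters
#'
#' @param omega0 Morlet centre frequency (default 6; values below ~5 violate
#'   the admissibility approximation).
#' @param voices_per_octave scales per octave (default 12, minimum 4).
#' @param period_min,period_max analysed period range in seconds (defaults
#'   2 and 64).
#' @param coi_policy `"exclude"` (default) drops points outside the COI from
#'   band/segment means; `"include"` keeps them.
#' @return List of class `"wavelet_params"`.
#' @export
wavelet_params <- function(omega0 = 6, voices_per_octave = 12L,
                           period_min = 2, period_max = 64,
                           coi_policy = c("exclude", "include")) {
  coi_policy <- match.arg(coi_policy)
  if (omega0 < 5) stop_config("omega0 must be >= 5")
  if (voices_per_octave < 4L) stop_config("voices_per_octave must be >= 4")
  if (period_min <= 0 || period_max <= period_min) {
    stop_config("need 0 < period_min < period_max")
  }
  structure(list(omega0 = omega0,
                 voices_per_octave = as.integer(voices_per_octave),
                 period_min = period_min, period_max = period_max,
                 coi_policy = coi_policy),
            class = "wavelet_params")
}

# Fourier factor: period = fourier_factor * scale for the Morlet wavelet
fourier_factor <- function(omega0) 4 * pi / (omega0 + sqrt(2 + omega0^2))

morlet_scales <- function(params, fs, n) {
  ff <- fourier_factor(params$omega0)
  pmax_eff <- params$period_max
  limit <- n / fs / 2
  if (pmax_eff > limit) {
    warning("series too short for period_max = ", params$period_max,
            " s; truncating to ", signif(limit, 4), " s")
    pmax_eff <- limit
  }
  s0 <- params$period_min / ff
  dj <- 1 / params$voices_per_octave
  n_scales <- floor(log2(pmax_eff / params$period_min) / dj) + 1L
  s0 * 2^((seq_len(n_scales) - 1L) * dj)
}

# half-width of the 0.6-octave boxcar smoother along the scale axis
scale_smooth_half_width <- function(voices_per_octave) {
  max(1L, floor(0.6 * voices_per_octave / 2))
}

.wavelet_cache <- new.env(parent = emptyenv())

# frequency-domain machinery for a given (n, fs, params); cached
wavelet_engine <- function(n, fs, params) {
  key <- paste(n, fs, params$omega0, params$voices_per_octave,
               params$period_min, params$period_max, sep = "|")
  hit <- .wavelet_cache[[key]]
  if (!is.null(hit)) return(hit)
  scales <- morlet_scales(params, fs, n)
  k <- length(scales)
  npad <- stats::nextn(n, 2)
  dt <- 1 / fs
  freq_idx <- c(0:(npad / 2), -((npad / 2 - 1):1))
  omega <- 2 * pi * freq_idx / (npad * dt)
  sw <- outer(omega, scales)                       # npad x k
  psi <- matrix(0, npad, k)
  pos <- omega > 0
  psi[pos, ] <- pi^(-1 / 4) * sqrt(2 * pi / dt) *
    rep(sqrt(scales), each = sum(pos)) *
    exp(-0.5 * (sw[pos, , drop = FALSE] -
                  rep(params$omega0, sum(pos) * k))^2)
  transfer <- exp(-0.25 * sw^2)
  # scale-axis boxcar (0.6 octave), edge-renormalised, as a k x k matrix
  h <- scale_smooth_half_width(params$voices_per_octave)
  boxcar <- matrix(0, k, k)
  for (j in seq_len(k)) {
    lo <- max(1L, j - h)
    hi <- min(k, j + h)
    boxcar[lo:hi, j] <- 1 / (hi - lo + 1)
  }
  ff <- fourier_factor(params$omega0)
  times <- (seq_len(n) - 1) / fs
  eng <- list(scales = scales, periods = scales * ff, npad = npad,
              psi = psi, transfer = transfer, boxcar = boxcar,
              times = times,
              coi = ff * pmin(times, times[n] - times) / sqrt(2))
  if (length(ls(.wavelet_cache)) > 16L) {
    rm(list = ls(.wavelet_cache), envir = .wavelet_cache)
  }
  .wavelet_cache[[key]] <- eng
  eng
}

cwt_with_engine <- function(x, eng) {
  npad <- eng$npad
  n <- length(x)
  xf <- fft(c(x, numeric(npad - n)))
  w <- mvfft(eng$psi * xf, inverse = TRUE) / npad
  w[seq_len(n), , drop = FALSE]
}

smooth_time_with_engine <- function(a, eng) {
  n <- nrow(a)
  apad <- rbind(a, matrix(0, eng$npad - n, ncol(a)))
  s <- mvfft(mvfft(apad) * eng$transfer, inverse = TRUE) / eng$npad
  s[seq_len(n), , drop = FALSE]
}

#' Continuous Morlet wavelet transform
#'
#' Frequency-domain implementation on the zero-padded series with
#' log-spaced scales.  The COI is the e-folding time of the wavelet,
#' `sqrt(2) * scale`, expressed as the longest trustworthy period per time
#' point.
#'
#' @param x numeric series (demeaned internally).
#' @param fs sampling frequency in Hz.
#' @param params a [wavelet_params()].
#' @return List of class `"morlet_cwt"`: `w` (time x scale complex matrix),
#'   `periods`, `scales` (seconds), `times`, `coi` (max valid period per
#'   time), `fs`, `params`.
#' @export
cwt_morlet <- function(x, fs, params = wavelet_params()) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop_invalid("x must be finite numeric")
  }
  n <- length(x)
  if (n < 8L) stop_invalid("series too short")
  eng <- wavelet_engine(n, fs, params)
  w <- cwt_with_engine(x - mean(x), eng)
  structure(list(w = w, periods = eng$periods, scales = eng$scales,
                 times = eng$times, coi = eng$coi, fs = fs,
                 params = params),
            class = "morlet_cwt")
}

#' Wavelet transform coherence of two series
#'
#' `R2(t, s) = |S(W_xy / s)|^2 / (S(|W_x|^2 / s) * S(|W_y|^2 / s))` with
#' smoothing `S` in time (Gaussian, SD = scale/sqrt(2)) and scale (0.6
#' octave boxcar).  Both series are demeaned; amplitude scaling and offsets
#' of either series leave the map unchanged.
#'
#' @param x,y equal-length numeric series.
#' @param fs sampling frequency in Hz.
#' @param params a [wavelet_params()].
#' @return List of class `"coherence_map"`: `values` (time x period matrix
#'   in `[0, 1]`), `periods`, `times`, `coi`, `fs`, `params`.
#' @export
wavelet_coherence <- function(x, y, fs, params = wavelet_params()) {
  if (length(x) != length(y)) stop_invalid("series length mismatch")
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop_invalid("series must be finite")
  }
  n <- length(x)
  if (n < 8L) stop_invalid("series too short")
  eng <- wavelet_engine(n, fs, params)
  wx <- cwt_with_engine(x - mean(x), eng)
  wy <- cwt_with_engine(y - mean(y), eng)
  inv_s <- rep(1 / eng$scales, each = n)
  sxx <- Re(smooth_time_with_engine(Mod(wx)^2 * inv_s, eng)) %*% eng$boxcar
  syy <- Re(smooth_time_with_engine(Mod(wy)^2 * inv_s, eng)) %*% eng$boxcar
  sxy <- smooth_time_with_engine(wx * Conj(wy) * inv_s, eng) %*% eng$boxcar
  r2 <- Mod(sxy)^2 / (pmax(sxx, 1e-300) * pmax(syy, 1e-300))
  r2 <- pmin(pmax(r2, 0), 1)
  structure(list(values = r2, periods = eng$periods, times = eng$times,
                 coi = eng$coi, fs = fs, params = params),
            class = "coherence_map")
}
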