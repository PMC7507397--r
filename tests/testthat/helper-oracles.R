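# Independent reference implementations used as oracles.  They are written
# naively and directly from the documented definitions - explicit DFT sums,
# explicit normal equations, a literal BH step-up loop - and must never
# call into the code paths they check.

# --- literal, loop-based wavelet coherence ---------------------------------

reference_wtc <- function(x, y, fs, params) {
  n <- length(x)
  dt <- 1 / fs
  ff <- 4 * pi / (params$omega0 + sqrt(2 + params$omega0^2))
  dj <- 1 / params$voices_per_octave
  pmax_eff <- min(params$period_max, n / fs / 2)
  k <- floor(log2(pmax_eff / params$period_min) / dj) + 1
  scales <- (params$period_min / ff) * 2^((0:(k - 1)) * dj)
  npad <- 2^ceiling(log2(n))
  # direct DFT / inverse DFT from the definition (roots-of-unity matrix)
  wmat <- exp(-2i * pi * outer(0:(npad - 1), 0:(npad - 1)) / npad)
  dft <- function(v) as.vector(wmat %*% v)
  idft <- function(v) as.vector(Conj(wmat) %*% v) / npad
  freq <- c(0:(npad / 2), -((npad / 2 - 1):1))
  omega <- 2 * pi * freq / (npad * dt)
  cwt_ref <- function(z) {
    xf <- dft(c(z - mean(z), rep(0, npad - n)))
    w <- matrix(0i, n, k)
    for (j in 1:k) {
      s <- scales[j]
      psi <- ifelse(omega > 0,
                    pi^(-0.25) * sqrt(2 * pi * s / dt) *
                      exp(-0.5 * (s * omega - params$omega0)^2),
                    0)
      w[, j] <- idft(xf * psi)[1:n]
    }
    w
  }
  smooth_ref <- function(a) {
    st <- matrix(0i, n, k)
    for (j in 1:k) {
      s <- scales[j]
      f <- dft(c(a[, j], rep(0, npad - n)))
      st[, j] <- idft(f * exp(-0.25 * (s * omega)^2))[1:n]
    }
    h <- max(1, floor(0.6 * params$voices_per_octave / 2))
    out <- matrix(0i, n, k)
    for (j in 1:k) {
      lo <- max(1, j - h)
      hi <- min(k, j + h)
      acc <- 0i
      for (m in lo:hi) acc <- acc + st[, m]
      out[, j] <- acc / (hi - lo + 1)
    }
    out
  }
  wx <- cwt_ref(x)
  wy <- cwt_ref(y)
  invs <- matrix(rep(1 / scales, each = n), n, k)
  sxx <- Re(smooth_ref(Mod(wx)^2 * invs))
  syy <- Re(smooth_ref(Mod(wy)^2 * invs))
  sxy <- smooth_ref(wx * Conj(wy) * invs)
  r2 <- Mod(sxy)^2 / (pmax(sxx, 1e-300) * pmax(syy, 1e-300))
  pmin(pmax(r2, 0), 1)
}

# --- brute-force Benjamini-Hochberg step-up --------------------------------

reference_bh_passed <- function(p, q = 0.05) {
  m <- length(p)
  ord <- order(p)
  cutoff <- 0L
  for (i in seq_len(m)) {
    if (p[ord[i]] <= i / m * q) cutoff <- i
  }
  if (cutoff == 0L) integer(0) else sort(ord[seq_len(cutoff)])
}

# --- two-regression Granger causality via explicit normal equations --------

reference_gc <- function(x, y, p) {
  n <- length(y)
  idx <- (p + 1):n
  own <- sapply(1:p, function(l) y[idx - l])
  oth <- sapply(1:p, function(l) x[idx - l])
  rss <- function(xmat) {
    xmat <- cbind(1, xmat)
    beta <- solve(t(xmat) %*% xmat, t(xmat) %*% y[idx])
    sum((y[idx] - xmat %*% beta)^2)
  }
  rss_r <- rss(own)
  rss_f <- rss(cbind(own, oth))
  log(rss_r / rss_f)
}

# --- small fixtures --------------------------------------------------------

# fast single-channel layout/coupling for tests that only need the target
tiny_layout <- function() probe_layout(n_channels = 1L, roi_channels = 1L,
                                       target_channel = 1L)

tiny_coupling <- function(strength = 1, lag = 0,
                          strategies = c(delayed = 1, immediate = 0,
                                         none = 0.4)) {
  strategies[] <- strength * strategies / max(strategies)
  coupling_spec(coupled_channels = 1L, lag = lag,
                strength_by_strategy = strategies)
}

# narrow-band wavelet parameters covering the analysis band plus smoothing
# margin; used in simulation-heavy tests to keep runtime sane
narrow_wparams <- function() wavelet_params(period_min = 2.2,
                                            period_max = 17)

# an independent-noise dyad recording, single channel, preprocessed to hb
null_hb_pair <- function(seed) {
  sess <- simulate_session("null", "immediate", seed = seed)
  rec <- synthesize_dyad_recording(
    sess, layout = tiny_layout(),
    coupling = tiny_coupling(strength = 0), seed = seed + 1L
  )
  od_to_hb(intensity_to_od(rec))
}
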