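#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded helpers do not disturb
#' the caller's RNG stream.
#'
#' @param seed integer seed, or `NULL` to leave the RNG alone.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a reproducible child seed from a master seed
#'
#' Counter-based substream derivation: child streams for dyads, channels or
#' replicates are decorrelated from the master stream and from each other,
#' and the result always fits in a 32-bit signed integer.
#'
#' @param master integer master seed.
#' @param index nonnegative integer counter (e.g. dyad index).
#' @param stream optional small integer distinguishing independent uses of
#'   the same counter (default 0).
#' @return An integer seed in `[0, 2^31 - 1]`.
#' @export
derive_seed <- function(master, index, stream = 0L) {
  stopifnot(is.numeric(master), is.numeric(index))
  # splitmix-style integer hash, done in double precision (exact below 2^53)
  x <- (as.double(master) %% 2147483647) * 2654435761 +
    as.double(index) * 40503 + as.double(stream) * 69427 + 1013904223
  as.integer(x %% 2147483647)
}

stop_invalid <- function(...) {
  stop(structure(
    class = c("coopsync_invalid_input", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

stop_config <- function(...) {
  stop(structure(
    class = c("coopsync_config_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

assert_scalar_num <- function(x, name, lo = -Inf, hi = Inf,
                              strict_lo = FALSE, strict_hi = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_invalid(name, " must be a finite numeric scalar")
  }
  if (strict_lo && x <= lo) stop_invalid(name, " must be > ", lo)
  if (!strict_lo && x < lo) stop_invalid(name, " must be >= ", lo)
  if (strict_hi && x >= hi) stop_invalid(name, " must be < ", hi)
  if (!strict_hi && x > hi) stop_invalid(name, " must be <= ", hi)
  invisible(x)
}

# truncated-normal draw by rejection (lower bound only); vectorised
rtruncnorm_lower <- function(n, mean, sd, lower) {
  if (sd <= 0) return(pmax(rep(mean, n), lower))
  out <- rnorm(n, mean, sd)
  bad <- which(out < lower)
  guard <- 0L
  while (length(bad) > 0L && guard < 1000L) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lower]
    guard <- guard + 1L
  }
  out[out < lower] <- lower
  out
}

# mean / sd of a lower-truncated normal
truncnorm_moments <- function(mean, sd, lower) {
  z <- (lower - mean) / sd
  lam <- dnorm(z) / pnorm(z, lower.tail = FALSE)
  m <- mean + sd * lam
  v <- sd^2 * (1 + z * lam - lam^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

# parameters (m0, s0) such that the lower-truncated normal has the target
# mean and sd; damped fixed-point iteration
truncnorm_match_moments <- function(mean, sd, lower) {
  m0 <- mean
  s0 <- sd
  for (i in 1:200) {
    mo <- truncnorm_moments(m0, s0, lower)
    dm <- mean - mo[["mean"]]
    ds <- sd / max(mo[["sd"]], 1e-12)
    m0 <- m0 + 0.8 * dm
    s0 <- s0 * ds^0.8
    if (abs(dm) < 1e-10 && abs(ds - 1) < 1e-10) break
  }
  c(mean = m0, sd = s0)
}

# E[max(X, a)] - E[X] for X ~ N(mean, sd): expected inflation caused by
# clipping at a lower bound a
clip_bias_lower <- function(mean, sd, a) {
  if (sd <= 0) return(max(a - mean, 0))
  z <- (a - mean) / sd
  (a - mean) * pnorm(z) + sd * dnorm(z)
}
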