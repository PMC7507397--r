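# Time-domain bivariate Granger causality between the two partners' signals
# at one channel.  Direction x -> y is the log ratio of the residual
# variance of y's own-lags-only autoregression to that of the model that
# additionally includes x's lags; the standard nested-model F test
# accompanies it.  Lag rows never straddle block boundaries: task blocks
# are detrended separately and concatenated only in the design matrix.

# build lagged design for series list (list of equal-role segments)
lag_design <- function(segs_x, segs_y, p) {
  ylist <- list(); Xown <- list(); Xoth <- list()
  for (k in seq_along(segs_x)) {
    x <- segs_x[[k]]
    y <- segs_y[[k]]
    n <- length(y)
    if (n <= p) next
    idx <- (p + 1L):n
    ylist[[k]] <- y[idx]
    own <- sapply(seq_len(p), function(l) y[idx - l])
    oth <- sapply(seq_len(p), function(l) x[idx - l])
    Xown[[k]] <- matrix(own, ncol = p)
    Xoth[[k]] <- matrix(oth, ncol = p)
  }
  if (length(ylist) == 0L) stop_invalid("series too short for order ", p)
  list(y = unlist(ylist), own = do.call(rbind, Xown),
       other = do.call(rbind, Xoth))
}

ols_rss <- function(y, X) {
  X <- cbind(1, X)
  fit <- tryCatch(qr.coef(qr(X), y), error = function(e) NULL)
  if (is.null(fit) || any(is.na(fit))) stop_invalid("singular regression")
  res <- y - X %*% fit
  sum(res^2)
}

gc_one_direction <- function(segs_x, segs_y, p) {
  d <- lag_design(segs_x, segs_y, p)
  n_eff <- length(d$y)
  rss_r <- ols_rss(d$y, d$own)
  rss_f <- ols_rss(d$y, cbind(d$own, d$other))
  df2 <- n_eff - 2L * p - 1L
  if (df2 <= 0) stop_invalid("not enough samples for order ", p)
  gc <- max(log(rss_r / rss_f), 0)
  f <- ((rss_r - rss_f) / p) / (rss_f / df2)
  list(gc = gc, f = max(f, 0), p_value = pf(max(f, 0), p, df2,
                                            lower.tail = FALSE),
       n_effective = n_eff)
}

as_segment_list <- function(x) if (is.list(x)) x else list(x)

#' Select VAR order by BIC
#'
#' Fits the joint bivariate VAR for each candidate order and returns the
#' BIC-minimising order.
#'
#' @param x,y numeric series (or lists of segments).
#' @param max_order largest order tried (default 20; 2 s at 10 Hz).
#' @param min_order smallest order tried.
#' @return Integer order.
#' @export
select_order <- function(x, y, max_order = 20L, min_order = 1L) {
  segs_x <- as_segment_list(x)
  segs_y <- as_segment_list(y)
  n_tot <- sum(lengths(segs_x))
  if (n_tot <= 10L * max_order) {
    stop_invalid("series too short for max_order = ", max_order)
  }
  best <- NA_integer_
  best_bic <- Inf
  for (p in min_order:max_order) {
    dx <- lag_design(segs_y, segs_x, p)  # x equation: own = x lags
    dy <- lag_design(segs_x, segs_y, p)
    n_eff <- length(dx$y)
    rss_x <- ols_rss(dx$y, cbind(dx$own, dx$other))
    rss_y <- ols_rss(dy$y, cbind(dy$own, dy$other))
    # diagonal approximation of the innovation covariance
    ll <- n_eff * (log(rss_x / n_eff) + log(rss_y / n_eff))
    k <- 2 * (2 * p + 1)
    bic <- ll + k * log(n_eff)
    if (bic < best_bic) {
      best_bic <- bic
      best <- p
    }
  }
  best
}

#' Bivariate Granger causality, both directions
#'
#' @param x,y numeric series or lists of per-block segments (lags never
#'   cross a segment boundary).
#' @param p VAR order (see [select_order()]).
#' @param dyad_id,channel identifiers copied into the result.
#' @return Data frame of class `"gc_result"`: `gc_x_to_y`, `gc_y_to_x`
#'   (log variance ratios, >= 0), `f_x_to_y`, `p_x_to_y`, `f_y_to_x`,
#'   `p_y_to_x`, `order`, `n_effective`.
#' @export
granger_causality <- function(x, y, p, dyad_id = NA_character_,
                              channel = NA_integer_) {
  if (p < 1L) stop_invalid("order must be >= 1")
  segs_x <- as_segment_list(x)
  segs_y <- as_segment_list(y)
  if (!identical(lengths(segs_x), lengths(segs_y))) {
    stop_invalid("x and y segment lengths differ")
  }
  xy <- gc_one_direction(segs_x, segs_y, p)
  yx <- gc_one_direction(segs_y, segs_x, p)
  out <- data.frame(dyad_id = dyad_id, channel = channel, order = p,
                    gc_x_to_y = xy$gc, f_x_to_y = xy$f,
                    p_x_to_y = xy$p_value,
                    gc_y_to_x = yx$gc, f_y_to_x = yx$f,
                    p_y_to_x = yx$p_value,
                    n_effective = xy$n_effective)
  class(out) <- c("gc_result", class(out))
  out
}

# linear detrend of one segment
detrend_linear <- function(x) {
  t <- seq_along(x)
  stats::lm.fit(cbind(1, t), x)$residuals
}

# extract per-task-block detrended oxy-Hb segments for one channel
task_segments_hb <- function(rec, channel, participant,
                             segments = c("task1", "task2")) {
  n <- n_samples(rec)
  lapply(segments, function(lab) {
    idx <- segment_sample_index(rec$timeline, lab, rec$fs, n)
    detrend_linear(rec$data[participant, channel, 1L, idx])
  })
}

#' Cohort-level Granger causality at one channel
#'
#' Per dyad: task-block oxyhemoglobin at `channel`, per-block linear
#' detrend, GC in both directions at a common BIC-selected order (selected
#' on the first dyad unless given).  Group level: one-sample t per
#' direction (one-tailed, positive) and a paired t between directions
#' (two-tailed).
#'
#' @param recordings list of stage-`"hb"` recordings, one per dyad.
#' @param channel channel index (must be valid for every included dyad).
#' @param dyad_ids optional identifiers.
#' @param order VAR order; `NULL` selects by BIC.
#' @param max_order cap for order selection.
#' @return List: `per_dyad` (data frame of [granger_causality()] rows,
#'   participant 1 = x, participant 2 = y), `tests` (one-sample and paired
#'   t results), `order`.
#' @export
cohort_gc <- function(recordings, channel, dyad_ids = NULL, order = NULL,
                      max_order = 20L) {
  if (length(recordings) == 0L) stop_invalid("empty cohort")
  keep <- vapply(recordings, function(r) {
    !(channel %in% union(r$missing[[1L]], r$missing[[2L]]))
  }, logical(1L))
  recordings <- recordings[keep]
  if (length(recordings) < 3L) {
    stop_invalid("fewer than 3 dyads with channel ", channel, " valid")
  }
  if (is.null(dyad_ids)) dyad_ids <- sprintf("d%03d", seq_along(recordings))
  else dyad_ids <- dyad_ids[keep]
  segs <- lapply(recordings, function(r) {
    list(x = task_segments_hb(r, channel, 1L),
         y = task_segments_hb(r, channel, 2L))
  })
  if (is.null(order)) {
    order <- select_order(segs[[1L]]$x, segs[[1L]]$y, max_order = max_order)
  }
  per_dyad <- do.call(rbind, lapply(seq_along(segs), function(i) {
    granger_causality(segs[[i]]$x, segs[[i]]$y, order,
                      dyad_id = dyad_ids[i], channel = channel)
  }))
  tests <- list(
    x_to_y = one_sample_t(per_dyad$gc_x_to_y, mu0 = 0, tail = "one"),
    y_to_x = one_sample_t(per_dyad$gc_y_to_x, mu0 = 0, tail = "one"),
    direction_diff = paired_t(per_dyad$gc_x_to_y, per_dyad$gc_y_to_x,
                              tail = "two")
  )
  list(per_dyad = per_dyad, tests = tests, order = order)
}
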