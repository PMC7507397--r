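# Group-level inference: t tests (one-sample, paired, independent, with
# explicit one- or two-tailed p values), one-way ANOVA with partial eta
# squared and Tukey HSD post hocs, Pearson correlation, and the
# Benjamini-Hochberg step-up FDR over channels.  Implemented from the
# closed-form expressions so tails and effect sizes are explicit.

tt_result <- function(t, df, p, tail, estimate) {
  structure(list(t = t, df = df, p = p, tail = tail, estimate = estimate),
            class = "ttest_result")
}

#' @export
print.ttest_result <- function(x, ...) {
  cat(sprintf("t(%s) = %.3f, p = %.4g (%s-tailed), estimate = %.4g\n",
              format(x$df), x$t, x$p, x$tail, x$estimate))
  invisible(x)
}

#' One-sample t test
#'
#' One-tailed (default) tests the positive direction: H1 `mean > mu0`.
#'
#' @param values numeric sample (n >= 2, nonzero variance).
#' @param mu0 null mean (default 0).
#' @param tail `"one"` or `"two"`.
#' @return A `ttest_result`: `t`, `df`, `p`, `tail`, `estimate` (sample
#'   mean).
#' @export
one_sample_t <- function(values, mu0 = 0, tail = c("one", "two")) {
  tail <- match.arg(tail)
  values <- as.numeric(values)
  if (length(values) < 2L || any(!is.finite(values))) {
    stop_invalid("need >= 2 finite values")
  }
  s <- sd(values)
  if (s == 0) stop_invalid("zero variance sample")
  n <- length(values)
  t <- (mean(values) - mu0) / (s / sqrt(n))
  df <- n - 1L
  p <- if (tail == "one") pt(t, df, lower.tail = FALSE) else
    2 * pt(abs(t), df, lower.tail = FALSE)
  tt_result(t, df, p, tail, mean(values))
}

#' Paired-samples t test
#'
#' @param a,b matched samples.
#' @param tail `"two"` (default) or `"one"` (H1: mean(a) > mean(b)).
#' @return A `ttest_result`; `estimate` is the mean difference `a - b`.
#' @export
paired_t <- function(a, b, tail = c("two", "one")) {
  tail <- match.arg(tail)
  if (length(a) != length(b)) stop_invalid("paired samples differ in length")
  d <- a - b
  if (sd(d) == 0) stop_invalid("zero-variance differences")
  r <- one_sample_t(d, 0, tail = if (tail == "one") "one" else "two")
  r$tail <- tail
  r
}

#' Independent-samples t test (pooled variance)
#'
#' Classical equal-variance form, matching the reported degrees of freedom
#' conventions of small-group neuroimaging studies.
#'
#' @param a,b samples.
#' @param tail `"two"` (default) or `"one"` (H1: mean(a) > mean(b)).
#' @return A `ttest_result`; `estimate` is `mean(a) - mean(b)`.
#' @export
independent_t <- function(a, b, tail = c("two", "one")) {
  tail <- match.arg(tail)
  n1 <- length(a); n2 <- length(b)
  if (n1 < 2L || n2 < 2L) stop_invalid("need n >= 2 per group")
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  if (sp2 == 0) stop_invalid("zero pooled variance")
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2L
  p <- if (tail == "one") pt(t, df, lower.tail = FALSE) else
    2 * pt(abs(t), df, lower.tail = FALSE)
  tt_result(t, df, p, tail, mean(a) - mean(b))
}

#' Partial eta squared from a one-way ANOVA's F and degrees of freedom
#'
#' For the one-way design, `eta_p^2 = df1 * F / (df1 * F + df2)`.
#'
#' @param f F statistic.
#' @param df1,df2 numerator / denominator degrees of freedom.
#' @return Partial eta squared in `[0, 1]`.
#' @export
eta_p2_from_f <- function(f, df1, df2) {
  (df1 * f) / (df1 * f + df2)
}

#' One-way ANOVA with partial eta squared and Tukey HSD post hocs
#'
#' @param groups list of numeric samples (>= 2 groups, each n >= 2).
#' @return List of class `"anova_result"`: `f`, `df1`, `df2`, `p`,
#'   `eta_p2`, `group_means`, `posthoc` (data frame of pairwise Tukey HSD
#'   comparisons: difference, studentised q-based adjusted p).
#' @export
one_way_anova <- function(groups) {
  if (length(groups) < 2L) stop_invalid("need >= 2 groups")
  if (any(vapply(groups, length, integer(1L)) < 2L)) {
    stop_invalid("each group needs n >= 2")
  }
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  k <- length(groups)
  ns <- vapply(groups, length, integer(1L))
  n_tot <- sum(ns)
  means <- vapply(groups, mean, numeric(1L))
  grand <- sum(ns * means) / n_tot
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1L)))
  df1 <- k - 1L
  df2 <- n_tot - k
  if (ssw == 0) stop_invalid("zero within-group variance")
  f <- (ssb / df1) / (ssw / df2)
  mse <- ssw / df2
  pairs <- utils::combn(k, 2L)
  posthoc <- data.frame(
    a = names(groups)[pairs[1L, ]], b = names(groups)[pairs[2L, ]],
    diff = means[pairs[1L, ]] - means[pairs[2L, ]],
    p_adj = vapply(seq_len(ncol(pairs)), function(j) {
      i1 <- pairs[1L, j]; i2 <- pairs[2L, j]
      se <- sqrt(mse / 2 * (1 / ns[i1] + 1 / ns[i2]))
      q <- abs(means[i1] - means[i2]) / se
      ptukey(q, k, df2, lower.tail = FALSE)
    }, numeric(1L)),
    row.names = NULL
  )
  structure(list(f = f, df1 = df1, df2 = df2,
                 p = pf(f, df1, df2, lower.tail = FALSE),
                 eta_p2 = eta_p2_from_f(f, df1, df2),
                 group_means = means, posthoc = posthoc),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("F(%d, %d) = %.3f, p = %.4g, eta_p2 = %.3f\n",
              x$df1, x$df2, x$f, x$p, x$eta_p2))
  invisible(x)
}

#' Benjamini-Hochberg FDR across channels
#'
#' Literal step-up rule: order the m raw p values, find the largest i with
#' `p_(i) <= i/m * q`, reject all hypotheses up to it.  Adjusted p values
#' are the usual monotone `min_{j >= i} (m / j) p_(j)`.
#'
#' @param p_values named (or plain) numeric vector of raw p values.
#' @param q FDR level (default 0.05).
#' @return List of class `"fdr_report"`: `raw_p`, `adjusted_p`,
#'   `q_threshold`, `passed` (names/indices of rejected channels).
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  if (length(p_values) == 0L) stop_invalid("empty p value set")
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop_invalid("p values must lie in [0, 1]")
  }
  m <- length(p_values)
  if (is.null(names(p_values))) names(p_values) <- as.character(seq_len(m))
  ord <- order(p_values)
  ps <- p_values[ord]
  crit <- seq_len(m) / m * q
  below <- which(ps <= crit)
  passed <- if (length(below)) names(ps)[seq_len(max(below))] else character(0)
  adj <- rev(cummin(rev(ps * m / seq_len(m))))
  adj <- pmin(adj, 1)
  adjusted <- numeric(m)
  adjusted[ord] <- adj
  names(adjusted) <- names(p_values)
  structure(list(raw_p = p_values, adjusted_p = adjusted, q_threshold = q,
                 passed = passed),
            class = "fdr_report")
}

#' Pearson correlation with two-tailed test
#'
#' @param x,y numeric vectors (n >= 3, nonzero variance).
#' @return List of class `"correlation_result"`: `r`, `n`, `p`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop_invalid("length mismatch")
  if (length(x) < 3L) stop_invalid("need n >= 3")
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop_invalid("inputs must be finite")
  }
  if (sd(x) == 0 || sd(y) == 0) stop_invalid("constant input")
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    ((n - 1) * sd(x) * sd(y))
  r <- max(min(r, 1), -1)
  df <- n - 2L
  t <- r * sqrt(df / max(1 - r^2, 1e-300))
  structure(list(r = r, n = n, p = 2 * pt(abs(t), df, lower.tail = FALSE)),
            class = "correlation_result")
}
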