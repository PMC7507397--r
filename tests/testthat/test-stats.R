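# Group-level statistics.

test_that("one_sample_t matches the closed form and base R", {
  # hand-computable example: {2.1, 2.5, 1.9, 2.4} vs mu0 = 2
  v <- c(2.1, 2.5, 1.9, 2.4)
  r <- one_sample_t(v, mu0 = 2, tail = "two")
  expect_equal(r$t, (mean(v) - 2) / (sd(v) / 2), tolerance = 1e-12)
  expect_equal(r$t, 1.6341, tolerance = 1e-4)
  base <- t.test(v, mu = 2)
  expect_equal(r$p, base$p.value, tolerance = 1e-12)
  expect_equal(r$df, 3)
  # one-tailed halves the two-tailed p when the effect is positive
  expect_equal(one_sample_t(v, 2, "one")$p, r$p / 2, tolerance = 1e-12)
  # symmetric-around-zero sample -> p ~ 0.5 (one-tailed)
  set.seed(1)
  big <- rnorm(4000)
  expect_lt(abs(one_sample_t(big)$p - 0.5), 0.05)
  expect_error(one_sample_t(rep(1, 5)), class = "coopsync_invalid_input")
  v3 <- c(1, 1, 1) + c(1e-9, -1e-9, 0)
  expect_lt(one_sample_t(v3)$p, 0.001)
})

test_that("paired_t and independent_t match base R", {
  a <- c(1, 2, 3, 4, 5)
  b <- c(1.2, 1.9, 3.4, 3.9, 5.1)
  r <- paired_t(a, b)
  expect_equal(r$t, -1.054093, tolerance = 1e-5)  # hand-computed
  expect_equal(r$p, t.test(a, b, paired = TRUE)$p.value, tolerance = 1e-12)
  expect_equal(paired_t(a, a + c(1e-9, -1e-9, 0, 0, 0))$p, 1,
               tolerance = 1e-3)
  set.seed(2)
  jit <- rnorm(20, 0, 0.01)
  expect_lt(paired_t(1:20 + 1 + jit, 1:20)$p, 0.001)
  expect_error(paired_t(a, a), class = "coopsync_invalid_input")
  x <- rnorm(15); y <- rnorm(12, 1)
  ri <- independent_t(x, y)
  expect_equal(ri$p, t.test(x, y, var.equal = TRUE)$p.value,
               tolerance = 1e-12)
  expect_equal(ri$df, 25)
})

test_that("one_way_anova reproduces base aov and the eta_p2 identity", {
  set.seed(3)
  groups <- list(a = rnorm(17, 1), b = rnorm(16, 0.3), c = rnorm(10))
  r <- one_way_anova(groups)
  df <- data.frame(y = unlist(groups),
                   g = rep(names(groups), times = lengths(groups)))
  ref <- summary(aov(y ~ g, df))[[1]]
  expect_equal(r$f, ref[["F value"]][1], tolerance = 1e-10)
  expect_equal(r$p, ref[["Pr(>F)"]][1], tolerance = 1e-10)
  expect_equal(r$df1, 2L)
  expect_equal(r$df2, 40L)
  expect_equal(r$eta_p2, (2 * r$f) / (2 * r$f + 40), tolerance = 1e-12)
  # Tukey HSD against base TukeyHSD
  tk <- TukeyHSD(aov(y ~ g, df))$g
  ours <- r$posthoc
  for (i in seq_len(nrow(ours))) {
    key <- paste(ours$b[i], ours$a[i], sep = "-")
    expect_equal(ours$p_adj[i], tk[key, "p adj"], tolerance = 1e-6)
  }
  near_id <- list(a = c(1, 1 + 1e-9, 1 - 1e-9), b = c(1, 1 + 2e-9, 1 - 2e-9))
  expect_lt(one_way_anova(near_id)$eta_p2, 0.5)
  expect_error(one_way_anova(list(a = 1:3)),
               class = "coopsync_invalid_input")
  expect_error(one_way_anova(list(a = 1:3, b = 2)),
               class = "coopsync_invalid_input")
})

test_that("partial eta squared recovers the published values", {
  expect_equal(round(eta_p2_from_f(15.83, 2, 40), 3), 0.442)
  expect_equal(round(eta_p2_from_f(11.77, 2, 40), 3), 0.370)
  expect_equal(round(eta_p2_from_f(15.97, 2, 40), 3), 0.444)
  expect_equal(round(eta_p2_from_f(6.04, 2, 40), 3), 0.232)
})

test_that("bh_fdr equals the brute-force step-up on fuzzed inputs", {
  expect_error(bh_fdr(numeric(0)), class = "coopsync_invalid_input")
  expect_error(bh_fdr(c(0.5, 1.2)), class = "coopsync_invalid_input")
  # all equal small p -> all pass; single p -> raw threshold
  expect_length(bh_fdr(rep(0.01, 22))$passed, 22L)
  expect_length(bh_fdr(c(ch1 = 0.03))$passed, 1L)
  expect_length(bh_fdr(c(ch1 = 0.06))$passed, 0L)
  set.seed(4)
  for (i in 1:300) {
    m <- sample(1:30, 1)
    p <- round(runif(m), 3)
    names(p) <- seq_len(m)
    rep_ours <- bh_fdr(p)
    expect_setequal(as.integer(rep_ours$passed), reference_bh_passed(p))
    # adjusted p agree with p.adjust and are monotone in rank
    expect_equal(unname(rep_ours$adjusted_p), unname(p.adjust(p, "BH")),
                 tolerance = 1e-12)
  }
})

test_that("pearson_r matches cor.test and handles degeneracies", {
  expect_equal(pearson_r(1:10, 2 * (1:10) + 3)$r, 1)
  expect_equal(pearson_r(1:10, -(1:10))$r, -1)
  set.seed(5)
  x <- rnorm(30); y <- 0.4 * x + rnorm(30)
  r <- pearson_r(x, y)
  ref <- cor.test(x, y)
  expect_equal(r$r, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(r$p, ref$p.value, tolerance = 1e-10)
  expect_error(pearson_r(rep(1, 5), 1:5), class = "coopsync_invalid_input")
  expect_error(pearson_r(1:2, 1:2), class = "coopsync_invalid_input")
})

test_that("p values are uniform under the null (calibration)", {
  set.seed(6)
  p_t <- sapply(1:1000, function(i) one_sample_t(rnorm(12), tail = "two")$p)
  expect_gt(ks.test(p_t, "punif")$p.value, 0.01)
  p_f <- sapply(1:1000, function(i) {
    one_way_anova(list(rnorm(8), rnorm(8), rnorm(8)))$p
  })
  expect_gt(ks.test(p_f, "punif")$p.value, 0.01)
})
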