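# Preprocessing chain: SNR rejection, OD conversion, motion artifacts,
# Beer-Lambert inversion.

make_intensity_rec <- function(arr, fs = 10) {
  tl <- make_timeline(acquisition_config(
    rest_duration = dim(arr)[4] / fs / 13,
    task_duration = dim(arr)[4] / fs * 5 / 13))
  coopsync:::new_recording("intensity", arr, fs, tl, c(690, 830),
                           beer_lambert_constants())
}

test_that("reject_low_snr follows the mean/SD < 2 rule", {
  n <- 260
  arr <- array(10, c(2, 3, 2, n))
  # bounded unit-SD shape keeps intensity positive at any gain below ~7
  shape <- as.numeric(scale(sin(0.13 * seq_len(n))))
  # channel 1: constant -> huge ratio, kept; channel 2: mean 10 sd 4 ->
  # 2.5 kept; channel 3: mean 10 sd 6 -> 1.67 rejected
  for (p in 1:2) for (wl in 1:2) {
    arr[p, 2, wl, ] <- 10 + shape * 4
    arr[p, 3, wl, ] <- 10 + shape * 6
  }
  q <- reject_low_snr(make_intensity_rec(arr))
  expect_false(any(q$rejected[q$channel == 1]))
  expect_false(any(q$rejected[q$channel == 2]))
  expect_true(all(q$rejected[q$channel == 3]))
  expect_equal(q$snr_ratio[q$participant == 1 & q$channel == 2], 2.5,
               tolerance = 1e-6)
  # scale invariance: per-channel gain leaves ratios unchanged
  arr2 <- arr
  arr2[, 2, , ] <- arr2[, 2, , ] * 37
  q2 <- reject_low_snr(make_intensity_rec(arr2))
  expect_equal(q2$snr_ratio, q$snr_ratio, tolerance = 1e-9)
})

test_that("intensity_to_od matches its definition and invariances", {
  n <- 260
  arr <- array(5, c(2, 1, 2, n))
  rec <- make_intensity_rec(arr)
  od <- intensity_to_od(rec)
  expect_true(all(od$data == 0))  # constant intensity -> OD 0
  # I = mean * exp(-1) at one sample -> OD = 1 there, up to the small shift
  # the outlier itself induces in the record mean (exact value asserted)
  arr[1, 1, 1, 130] <- 5 * exp(-1)
  od <- intensity_to_od(make_intensity_rec(arr))
  exact <- -log(arr[1, 1, 1, 130] / mean(arr[1, 1, 1, ]))
  expect_equal(od$data[1, 1, 1, 130], exact, tolerance = 1e-12)
  expect_equal(od$data[1, 1, 1, 130], 1, tolerance = 5e-3)
  # gain invariance
  od2 <- intensity_to_od(make_intensity_rec(arr * 2))
  expect_equal(od2$data, od$data, tolerance = 1e-12)
  arr[2, 1, 2, 7] <- -1
  expect_error(intensity_to_od(make_intensity_rec(arr)),
               class = "coopsync_invalid_input")
})

test_that("od_to_hb inverts the forward Beer-Lambert model exactly", {
  bl <- beer_lambert_constants()
  n <- 260
  # known concentrations: HbO = 1 uM sinusoid, HbR = 0
  hbo <- sin(seq_len(n) / 9)
  od <- coopsync:::hb_to_od_matrix(hbo / 1000, 0 * hbo, bl)
  arr <- array(0, c(2, 1, 2, n))
  arr[1, 1, 1, ] <- od[, 1]; arr[1, 1, 2, ] <- od[, 2]
  rec <- make_intensity_rec(arr)
  rec$stage <- "od"
  hb <- od_to_hb(rec, bl)
  expect_equal(hb$data[1, 1, 1, ], hbo, tolerance = 1e-9)
  expect_equal(hb$data[1, 1, 2, ], 0 * hbo, tolerance = 1e-9)
  expect_true(all(hb$data[2, , , ] == 0))  # zero OD -> zero Hb
})

test_that("no band-pass filtering: out-of-band power is preserved", {
  sess <- simulate_session("d1", "immediate", seed = 41)
  ns <- noise_spec(shot_noise_od = 0)
  rec <- synthesize_dyad_recording(sess, layout = tiny_layout(),
                                   coupling = tiny_coupling(0),
                                   noise = ns, seed = 42)
  hb <- od_to_hb(intensity_to_od(rec))
  true_hbo <- rec$ground_truth$hbo[1, 1, ]
  got_hbo <- hb$data[1, 1, 1, ]
  # out-of-band = above the 3.2-12.8 s analysis band (f > 0.3125 Hz)
  pow_hi <- function(x) {
    spec <- Mod(fft(x - mean(x)))^2
    f <- (seq_along(x) - 1) / length(x) * 10
    sum(spec[f > 0.3125 & f < 5])
  }
  expect_lt(abs(pow_hi(got_hbo) / pow_hi(true_hbo) - 1), 0.01)
})

test_that("clean recordings trigger few or no artifact flags", {
  sess <- simulate_session("d1", "delayed", seed = 15)
  rec <- synthesize_dyad_recording(sess, seed = 16)
  mask <- detect_motion_artifacts(intensity_to_od(rec))
  # nominal false-alarm allowance: <= 2% of samples flagged per participant
  expect_lt(mean(mask), 0.02)
})

test_that("injected spikes are flagged and overlap the true mask", {
  sess <- simulate_session("d1", "none", seed = 17)
  rec <- synthesize_dyad_recording(sess, layout = tiny_layout(),
                                   coupling = tiny_coupling(0), seed = 18)
  inj <- inject_motion_artifacts(rec, noise_spec(artifact_rate = 1.5),
                                 seed = 19)
  expect_true(any(inj$mask))
  detected <- detect_motion_artifacts(intensity_to_od(inj$rec))
  overlap <- detected & inj$mask
  expect_gt(sum(overlap), 0)
  # most injected artifact mass is found (events are 8-16 robust SDs)
  expect_gt(sum(overlap) / sum(inj$mask), 0.5)
})

test_that("all-zero OD yields an empty artifact mask", {
  arr <- array(0, c(2, 1, 2, 260))
  rec <- make_intensity_rec(array(1, c(2, 1, 2, 260)))
  rec$stage <- "od"
  rec$data <- arr
  expect_false(any(detect_motion_artifacts(rec)))
})

test_that("motion correction bridges flagged runs and touches nothing else", {
  sess <- simulate_session("d1", "immediate", seed = 20)
  rec <- synthesize_dyad_recording(sess, layout = tiny_layout(),
                                   coupling = tiny_coupling(0), seed = 21)
  od <- intensity_to_od(rec)
  n <- dim(od$data)[4]
  # empty mask -> identity
  empty <- matrix(FALSE, 2, n)
  expect_identical(correct_motion(od, empty)$data, od$data)
  # boxcar baseline shift on participant 1, gross against the total SD
  x <- od$data[1, 1, 1, ]
  amp <- 25 * sd(x)
  span <- 1200:1280
  bad <- od
  bad$data[1, 1, , span] <- bad$data[1, 1, , span] + amp
  mask <- matrix(FALSE, 2, n)
  mask[1, span] <- TRUE
  # correction = "none" -> identity regardless of mask
  expect_identical(
    correct_motion(bad, mask, artifact_params(correction = "none"))$data,
    bad$data)
  fixed <- correct_motion(bad, mask)
  # unflagged samples bit-identical
  expect_identical(fixed$data[1, 1, 1, -span], bad$data[1, 1, 1, -span])
  expect_identical(fixed$data[2, , , ], bad$data[2, , , ])
  # step amplitude reduced >= 90% against the pre-injection series
  err_before <- abs(mean(bad$data[1, 1, 1, span] - x[span]))
  err_after <- abs(mean(fixed$data[1, 1, 1, span] - x[span]))
  expect_lt(err_after, 0.1 * err_before)
})

test_that("fully flagged participants lose their channels", {
  arr <- array(1, c(2, 2, 2, 260))
  rec <- make_intensity_rec(arr)
  od <- intensity_to_od(rec)
  mask <- matrix(c(TRUE, FALSE), 2, 260)
  mask[1, ] <- TRUE
  mask[2, ] <- FALSE
  out <- correct_motion(od, mask)
  expect_equal(out$missing[[1]], 1:2)
  expect_length(out$missing[[2]], 0)
})

test_that("full preprocessing recovers ground truth on a realistic recording", {
  sess <- simulate_session("d1", "delayed", seed = 22)
  rec <- synthesize_dyad_recording(sess, seed = 23)
  inj <- inject_motion_artifacts(rec, noise_spec(artifact_rate = 0.5),
                                 seed = 24)
  pp <- preprocess_recording(inj$rec)
  expect_equal(pp$rec$stage, "hb")
  clean <- !(inj$mask[1, ] | pp$artifact_mask[1, ])
  r <- cor(pp$rec$data[1, 5, 1, clean], rec$ground_truth$hbo[1, 5, clean])
  expect_gt(r, 0.99)
})
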