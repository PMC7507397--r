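# Forward model: timeline, synthetic recordings, artifacts, SNR degradation.

test_that("make_timeline produces the canonical five-segment design", {
  tl <- make_timeline()
  expect_equal(tl$label, c("rest1", "task1", "rest2", "task2", "rest3"))
  expect_equal(tl$duration, c(30, 150, 30, 150, 30))
  expect_equal(timeline_duration(tl), 390)
  sess <- simulate_session("d1", "immediate", seed = 4)
  tl2 <- make_timeline(session = sess)
  trials <- attr(tl2, "trials")
  expect_equal(nrow(trials), 40L)
  expect_true(all(trials$onset[trials$block == 1] >= 30))
  expect_true(all(trials$onset[trials$block == 1] +
                    trials$duration[trials$block == 1] <= 180 + 1e-9))
  expect_identical(tl2, make_timeline(session = sess))
})

test_that("trials overflowing the task block raise a config error", {
  sess <- simulate_session("d1", "immediate", seed = 4)
  acq <- acquisition_config(task_duration = 50)
  expect_error(make_timeline(acq, sess), class = "coopsync_config_error")
})

test_that("synthetic recordings have positive intensity and ground truth", {
  sess <- simulate_session("d1", "delayed", seed = 5)
  rec <- synthesize_dyad_recording(sess, seed = 6)
  expect_s3_class(rec, "hyperscan_recording")
  expect_equal(dim(rec$data), c(2L, 22L, 2L, 3900L))
  expect_true(all(rec$data > 0))
  expect_true(all(is.finite(rec$data)))
  expect_equal(dim(rec$ground_truth$hbo), c(2L, 22L, 3900L))
  # determinism of stored ground truth and data
  rec2 <- synthesize_dyad_recording(sess, seed = 6)
  expect_identical(rec$data, rec2$data)
  expect_identical(rec$ground_truth$mask, rec2$ground_truth$mask)
})

test_that("unresolvable coupling periods are rejected", {
  sess <- simulate_session("d1", "delayed", seed = 5)
  expect_error(
    synthesize_dyad_recording(sess, coupling = coupling_spec(period = 40),
                              seed = 1),
    class = "coopsync_config_error"
  )
})

test_that("forward/inverse round trip recovers the true HbO series", {
  sess <- simulate_session("d1", "delayed", seed = 5)
  rec <- synthesize_dyad_recording(sess, seed = 11)
  hb <- od_to_hb(intensity_to_od(rec))
  for (ch in c(1L, 10L, 19L)) {
    for (p in 1:2) {
      expect_gt(cor(hb$data[p, ch, 1L, ], rec$ground_truth$hbo[p, ch, ]),
                0.99)
    }
  }
})

test_that("coupling strength raises task-band coherence monotonically", {
  # scaled down from the spec's 20 seeds per strength to fit the time
  # budget; averaged over 5 seeds per strength level
  strengths <- c(0, 0.5, 1, 2)
  band <- band_spec()
  wp <- narrow_wparams()
  mean_coh <- sapply(strengths, function(str) {
    mean(sapply(1:5, function(seed) {
      sess <- simulate_session("d", "delayed", seed = 100 + seed)
      rec <- synthesize_dyad_recording(
        sess, layout = tiny_layout(),
        coupling = tiny_coupling(strength = str), seed = 200 + seed)
      hb <- od_to_hb(intensity_to_od(rec))
      m <- wavelet_coherence(hb$data[1, 1, 1, ], hb$data[2, 1, 1, ],
                             hb$fs, wp)
      band_segment_mean(m, band, c("task1", "task2"), hb$timeline)
    }))
  })
  expect_true(all(diff(mean_coh) > 0))
})

test_that("task-only coupling yields positive IBS; always-on coupling cancels", {
  wp <- narrow_wparams()
  ibs_for <- function(segments, seed) {
    sess <- simulate_session("d", "delayed", seed = seed)
    cp <- tiny_coupling(strength = 2)
    cp$active_segments <- segments
    rec <- synthesize_dyad_recording(sess, layout = tiny_layout(),
                                     coupling = cp, seed = seed + 50)
    hb <- od_to_hb(intensity_to_od(rec))
    m <- wavelet_coherence(hb$data[1, 1, 1, ], hb$data[2, 1, 1, ], hb$fs, wp)
    compute_ibs(m, hb$timeline)$ibs
  }
  task_only <- mean(sapply(1:5, function(s) ibs_for(c("task1", "task2"), s)))
  always_on <- mean(sapply(1:5, function(s)
    ibs_for(c("rest1", "task1", "rest2", "task2", "rest3"), s)))
  expect_gt(task_only, 0.05)
  expect_lt(abs(always_on), abs(task_only) / 2)
})

test_that("artifact injection is seeded, masked, and off at rate zero", {
  sess <- simulate_session("d1", "none", seed = 8)
  rec <- synthesize_dyad_recording(sess, layout = tiny_layout(),
                                   coupling = tiny_coupling(0), seed = 9)
  off <- inject_motion_artifacts(rec, noise_spec(artifact_rate = 0), seed = 1)
  expect_identical(off$rec$data, rec$data)
  expect_false(any(off$mask))
  ns <- noise_spec(artifact_rate = 2)
  a <- inject_motion_artifacts(rec, ns, seed = 33)
  b <- inject_motion_artifacts(rec, ns, seed = 33)
  expect_identical(a$rec$data, b$rec$data)
  expect_identical(a$mask, b$mask)
  expect_true(any(a$mask))
  # data changed only under the mask
  changed <- apply(abs(a$rec$data - rec$data) > 1e-12, c(1, 4), any)
  expect_true(all(which(changed[1, ]) %in% which(a$mask[1, ])))
})

test_that("degrade_channel_snr drives channels below the rejection bar", {
  sess <- simulate_session("d1", "immediate", seed = 12)
  rec <- synthesize_dyad_recording(sess, seed = 13)
  expect_identical(degrade_channel_snr(rec, integer(0), 50), rec)
  same <- degrade_channel_snr(rec, 7L, 1)
  expect_equal(same$data, rec$data, tolerance = 1e-12)
  expect_error(degrade_channel_snr(rec, 99L, 2),
               class = "coopsync_invalid_input")
  deg <- degrade_channel_snr(rec, 7L, 200)
  q <- reject_low_snr(deg)
  expect_setequal(q$channel[q$rejected], 7L)
})
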