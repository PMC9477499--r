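test_that("conditioning downsamples exactly and shapes the passband", {
  # 512 Hz, 40 s -> 128 Hz, length / 4
  set.seed(1)
  rec <- eeg_recording(matrix(rnorm(512 * 40), nrow = 1), fs = 512)
  out <- condition_signal(rec)
  expect_equal(out$fs, 128)
  expect_equal(ncol(out$samples), 512 * 40 / 4)

  # 0.05 Hz drift attenuated by >= 20 dB
  slow <- eeg_recording(matrix(sine_wave(0.05, 120, amp = 100), nrow = 1),
                        fs = 128)
  y <- condition_signal(slow)$samples[1, ]
  expect_lt(sqrt(mean(y^2)), 0.1 * sqrt(mean(slow$samples[1, ]^2)))

  # 10 Hz content preserved within 5%
  fast <- eeg_recording(matrix(sine_wave(10, 120, amp = 50), nrow = 1),
                        fs = 128)
  y2 <- condition_signal(fast)$samples[1, ]
  expect_equal(sqrt(mean(y2^2)), sqrt(mean(fast$samples[1, ]^2)),
               tolerance = 0.05)

  expect_error(condition_signal(eeg_recording(matrix(0, 1, 100), fs = 64)),
               "sampling rate")
})

test_that("Hjorth parameters match their closed forms", {
  expect_error(hjorth(rep(3, 100)), "constant")
  # pure sinusoid: mobility = 2 sin(omega / 2); the finite-sample
  # variance denominators (n-1 vs n-2) leave an O(1/n) residual
  for (f in c(2, 10, 30)) {
    x <- sine_wave(f, 20)
    omega <- 2 * pi * f / 128
    expect_equal(hjorth(x)$mobility, 2 * sin(omega / 2), tolerance = 1e-3)
  }
  # white noise: complexity > 1 (difference is rougher than the signal)
  set.seed(2)
  expect_gt(hjorth(rnorm(1e5))$complexity, 1)
})

test_that("flanking rejection spares identical epochs and flags outliers", {
  # identical epochs: SD = 0, strict inequality never fires
  seg <- sine_wave(3, 30, amp = 20)
  rec <- eeg_recording(matrix(rep(seg, 30), nrow = 1), fs = 128)
  h <- hypnogram(rep("N2", 30))
  m <- flanking_band_rejection(rec, h)
  expect_true(all(m$keep))

  # one epoch with 10x delta amplitude -> flank_delta, first epoch edge
  # case evaluated against its right-hand flankers only; injecting the
  # artifact must not flip any epoch that the clean run kept
  wn <- white_noise_recording(30, seed = 3)
  m_clean <- flanking_band_rejection(wn$rec, wn$h)
  bad <- inject_artifact_epochs(wn$rec, wn$h, 15, "high_delta",
                                amp_uV = 200)
  m2 <- flanking_band_rejection(bad, wn$h)
  expect_false(m2$keep[m2$epoch == 15])
  expect_equal(m2$reason[m2$epoch == 15], "flank_delta")
  expect_true(all(m2$keep[m2$epoch != 15] | !m_clean$keep[m_clean$epoch != 15]))

  bad1 <- inject_artifact_epochs(wn$rec, wn$h, 1, "high_delta",
                                 amp_uV = 200)
  m3 <- flanking_band_rejection(bad1, wn$h)
  expect_false(m3$keep[m3$epoch == 1])

  # beta outlier carries the beta reason
  badb <- inject_artifact_epochs(wn$rec, wn$h, 10, "high_beta",
                                 amp_uV = 100)
  m4 <- flanking_band_rejection(badb, wn$h)
  expect_equal(m4$reason[m4$epoch == 10], "flank_beta")
})

test_that("clipping rejection applies the 5% rule exactly", {
  wn <- white_noise_recording(12, seed = 4)
  x <- wn$rec$samples[1, ]
  hi <- max(x)
  # 6% of epoch 3 pinned -> rejected; 4% of epoch 7 -> kept
  ix3 <- 2 * 3840 + 1:231   # 6.0%
  ix7 <- 6 * 3840 + 1:150   # 3.9%
  x[ix3] <- hi
  x[ix7] <- hi
  rec <- eeg_recording(matrix(x, nrow = 1), fs = 128)
  m <- clipping_rejection(rec, wn$h)
  expect_false(m$keep[m$epoch == 3])
  expect_equal(m$reason[m$epoch == 3], "clipping")
  expect_true(m$keep[m$epoch == 7])

  # degenerate constant channel: every sample equals both extremes
  flat <- eeg_recording(matrix(0, 1, 12 * 3840), fs = 128)
  expect_warning(m0 <- clipping_rejection(flat, wn$h), "degenerate")
  expect_true(all(!m0$keep[m0$stage == "N2"]))
})

test_that("iterative rejection catches gross outliers and cascades", {
  # identical epochs: nothing rejected in any cycle
  seg <- sine_wave(5, 30, amp = 10)
  rec <- eeg_recording(matrix(rep(seg, 21), nrow = 1), fs = 128)
  h <- hypnogram(rep("N2", 21))
  expect_true(all(iterative_rejection(rec, h)$keep))

  # one epoch at 10x RMS among 20 normal ones -> rejected, reason iter_rms
  wn <- white_noise_recording(21, seed = 5)
  bad <- inject_artifact_epochs(wn$rec, wn$h, 11, "high_rms",
                                rms_factor = 10)
  m <- iterative_rejection(bad, wn$h)
  expect_false(m$keep[m$epoch == 11])
  expect_equal(m$reason[m$epoch == 11], "iter_rms")
  expect_true(all(m$keep[m$epoch != 11]))

  # a marginal epoch passes cycle 1 but falls in cycle 2 once the gross
  # outlier's removal shrinks the whole-signal reference
  x <- wn$rec$samples[1, ]
  x[10 * 3840 + 1:3840] <- x[10 * 3840 + 1:3840] * 6     # gross, epoch 11
  x[15 * 3840 + 1:3840] <- x[15 * 3840 + 1:3840] * 2.4   # marginal, epoch 16
  rec2 <- eeg_recording(matrix(x, nrow = 1), fs = 128)
  whole1 <- sqrt(mean(x^2))
  rms16 <- sqrt(mean(x[15 * 3840 + 1:3840]^2))
  expect_lt(rms16, 2 * whole1)          # survives cycle 1 by construction
  m2 <- iterative_rejection(rec2, wn$h)
  expect_false(m2$keep[m2$epoch == 11])
  expect_false(m2$keep[m2$epoch == 16])

  # early stop below 5 surviving epochs
  few <- white_noise_recording(3, seed = 6)
  expect_message(m3 <- iterative_rejection(few$rec, few$h), "fewer than 5")
  expect_true(all(m3$keep))
})

test_that("apply_mask and surviving_segments do exact bookkeeping", {
  wn <- white_noise_recording(10, seed = 7)
  all_ix <- apply_mask(wn$rec, wn$h)
  expect_length(all_ix[["ch1"]], 10 * 3840)

  mask <- nremtools:::init_mask(wn$rec, wn$h)
  mask$keep[mask$epoch == 5] <- FALSE
  ix <- apply_mask(wn$rec, wn$h, mask)
  expect_length(ix[["ch1"]], 9 * 3840)
  expect_false(any(ix[["ch1"]] %in% (4 * 3840 + 1:3840)))

  segs <- surviving_segments(wn$rec, wn$h, mask, "ch1")
  expect_length(segs, 2L)
  expect_equal(segs[[1]]$start, 1L)
  expect_equal(segs[[2]]$start, 5 * 3840 + 1L)
  expect_length(segs[[1]]$x, 4 * 3840)

  mask$keep[] <- FALSE
  expect_length(apply_mask(wn$rec, wn$h, mask)[["ch1"]], 0L)
  # REM request on an all-N2 hypnogram is empty
  expect_length(apply_mask(wn$rec, wn$h, stages = "REM")[["ch1"]], 0L)
})

test_that("each artifact mode is caught by its intended criterion in isolation", {
  wn <- white_noise_recording(21, seed = 8)
  m1 <- flanking_band_rejection(
    inject_artifact_epochs(wn$rec, wn$h, 8, "high_delta"), wn$h)
  expect_equal(m1$reason[m1$epoch == 8], "flank_delta")
  m2 <- flanking_band_rejection(
    inject_artifact_epochs(wn$rec, wn$h, 8, "high_beta", amp_uV = 80), wn$h)
  expect_equal(m2$reason[m2$epoch == 8], "flank_beta")
  m3 <- clipping_rejection(
    inject_artifact_epochs(wn$rec, wn$h, 8, "clipping"), wn$h)
  expect_equal(m3$reason[m3$epoch == 8], "clipping")
  m4 <- iterative_rejection(
    inject_artifact_epochs(wn$rec, wn$h, 8, "high_rms"), wn$h)
  expect_equal(m4$reason[m4$epoch == 8], "iter_rms")
})
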