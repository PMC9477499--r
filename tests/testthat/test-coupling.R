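test_that("phase convention: 0 at descending zero, 90 at trough, 270 at peak", {
  x <- sine_wave(1, 20)                 # descending zeros at k + 0.5 s
  ph <- sw_phase_series(x, 128)
  at <- function(ts) ph[round(ts * 128) + 1]
  wrap <- function(a, b) abs(((a - b + 180) %% 360) - 180)
  expect_true(all(wrap(at(seq(2.5, 17.5)), 0) < 2))
  expect_true(all(wrap(at(seq(2.75, 17.75)), 90) < 2))
  expect_true(all(wrap(at(seq(2.25, 17.25)), 270) < 2))
  # monotone advance (mod 360) away from the edges
  core <- ph[(2 * 128):(18 * 128)]
  expect_true(all(diff(core) %% 360 < 180))
  expect_error(sw_phase_series(sine_wave(1, 2), 128), "4 s")
})

test_that("spindle-SW matching applies the window and the tie-break", {
  sw <- tibble::tibble(start_s = c(9.5, 19.5), trough_s = c(10, 20),
                       end_s = c(10.5, 20.5))
  sp <- tibble::tibble(peak_s = c(10, 21.4, 15, 26))
  pairs <- match_spindles_to_sw(sp, sw)
  expect_equal(nrow(pairs), 2L)
  expect_equal(pairs$trough_s[pairs$peak_s == 10], 10)    # exact overlap
  expect_equal(pairs$trough_s[pairs$peak_s == 21.4], 20)  # within 1.5 s
  # 1.6 s away and equidistant cases
  sp2 <- tibble::tibble(peak_s = 21.6)
  expect_equal(nrow(match_spindles_to_sw(sp2, sw[2, ])), 0L)
  sp3 <- tibble::tibble(peak_s = 15)                      # 5 s from both
  expect_equal(nrow(match_spindles_to_sw(sp3, sw)), 0L)
  sw_close <- tibble::tibble(start_s = c(13.5, 15.5), trough_s = c(14, 16),
                             end_s = c(14.5, 16.5))
  tie <- match_spindles_to_sw(tibble::tibble(peak_s = 15), sw_close)
  expect_equal(tie$trough_s, 14)                          # earlier trough
  expect_equal(nrow(match_spindles_to_sw(sp[0, ], sw)), 0L)
})

test_that("coupling statistics match their closed forms", {
  expect_equal(coupling_stats(c(0, 0, 0))$mrl, 1)
  expect_equal(coupling_stats(c(0, 0, 0))$mean_angle_deg, 0)
  four <- coupling_stats(c(0, 90, 180, 270))
  expect_equal(four$mrl, 0, tolerance = 1e-12)
  expect_true(is.na(four$mean_angle_deg))
  two <- coupling_stats(c(0, 90))
  expect_equal(two$mrl, sqrt(2) / 2, tolerance = 1e-12)
  expect_equal(two$mean_angle_deg, 45)
})

test_that("mrl is rotation invariant and the mean angle rotates with it", {
  set.seed(1)
  th <- runif(50, 0, 360)
  base <- coupling_stats(th)
  rot <- coupling_stats((th + 73) %% 360)
  expect_equal(rot$mrl, base$mrl, tolerance = 1e-9)
  expect_equal(rot$mean_angle_deg %% 360,
               (base$mean_angle_deg + 73) %% 360, tolerance = 1e-9)
})

test_that("overlap z-score flags degenerate nulls and detects coupling", {
  sp <- tibble::tibble(peak_s = c(40, 70, 100))
  no_sw <- tibble::tibble(trough_s = numeric(0))
  res <- overlap_null_z(sp, no_sw, n_shuffles = 100, seed = 1)
  expect_equal(res$overlap_raw, 0)
  expect_true(is.na(res$overlap_z))
  none <- overlap_null_z(sp[0, ], no_sw, n_shuffles = 10, seed = 1)
  expect_true(is.na(none$overlap_raw))

  sim <- simulate_recording(sim_params(duration_s = 900, seed = 5,
                                       p_coupled = 1, kappa = 5,
                                       sp_density_per_min = 4))
  z <- overlap_null_z(sim$truth$sp_events, sim$truth$sw_events,
                      n_shuffles = 1000, seed = 2)
  expect_gt(z$overlap_z, 3)
})

test_that("MRL z-score is reproducible and flags unstable inputs", {
  sim <- sw_fixture(6)
  rec <- sim$recording; h <- sim$hypnogram
  sw <- detect_slow_waves(surviving_segments(rec, h, NULL, "ch1"), 128)
  phase <- nremtools:::sw_phase_record(rec, h, NULL, "ch1")
  set.seed(7)
  js <- sample(nrow(sw), 30, replace = TRUE)
  pairs <- make_pairs(sw, js, runif(30, sw$start_s[js], sw$end_s[js]))
  a <- mrl_null_z(pairs, phase, 128, n_shuffles = 300, seed = 11)
  b <- mrl_null_z(pairs, phase, 128, n_shuffles = 300, seed = 11)
  expect_equal(a$mrl_z, b$mrl_z, tolerance = 1e-12)

  few <- mrl_null_z(pairs[1:3, ], phase, 128, n_shuffles = 50, seed = 1)
  expect_true(is.na(few$mrl_z))
  expect_false(is.na(few$mrl_raw))

  # all peaks at the trough: mrl 1, strongly positive z
  at_trough <- make_pairs(sw, seq_len(min(50, nrow(sw))),
                          sw$trough_s[seq_len(min(50, nrow(sw)))])
  hi <- mrl_null_z(at_trough, phase, 128, n_shuffles = 500, seed = 3)
  expect_equal(hi$mrl_raw, 1, tolerance = 0.02)
  expect_gt(hi$mrl_z, 3)
})

test_that("SW-locked average reproduces the injected kernel", {
  # identical kernels on a zero background: the average equals the kernel
  fs <- 128
  x <- numeric(fs * 300)
  k <- make_sw_kernel(120, 1, fs)
  troughs <- c(50, 100, 150, 200, 250) + 0.5
  for (at in c(50, 100, 150, 200, 250)) {
    x[round(at * fs) + seq_along(k)] <- k
  }
  sws <- tibble::tibble(trough_s = troughs)
  avg <- sw_locked_average(x, sws, fs)
  expect_length(avg$mean_uV, 4 * fs + 1)
  expect_equal(avg$mean_uV[avg$lag_s == 0], -120, tolerance = 1e-9)
  expect_equal(attr(avg, "n_used"), 5L)
  # a window past the record edge drops that SW
  avg2 <- sw_locked_average(x, tibble::tibble(trough_s = c(troughs, 299.5)),
                            fs)
  expect_equal(attr(avg2, "n_used"), 5L)
  expect_error(sw_locked_average(x, tibble::tibble(trough_s = 0.5), fs),
               "no SW window")
})

test_that("SW-locked scalogram peaks at lag zero for trough-locked spindles", {
  set.seed(8)
  fs <- 128
  x <- colored_noise(fs * 420, fs, 1.5, 3)
  troughs <- seq(30, 390, by = 15)
  k <- make_sw_kernel(140, 1, fs)
  ks <- make_spindle_kernel(13, 1, 20, fs)
  for (at in troughs) {
    ix <- round((at - 0.5) * fs) + seq_along(k)
    x[ix] <- x[ix] + k
    ixs <- round((at - 0.5) * fs) + seq_along(ks)
    x[ixs] <- x[ixs] + ks           # spindle centred on the trough
  }
  sws <- tibble::tibble(trough_s = troughs)
  sc <- sw_locked_scalogram(x, sws, fs)
  peak_lag <- sc$lag_s[which.max(apply(sc$z, 2, max))]
  expect_lt(abs(peak_lag), 0.25)
  # deterministic: no randomness involved
  sc2 <- sw_locked_scalogram(x, sws, fs)
  expect_identical(sc$z, sc2$z)
  expect_error(sw_locked_scalogram(x, sws[1:3, ], fs), "at least 5")

  # background-only scalogram stays near zero on average
  set.seed(9)
  xb <- colored_noise(fs * 420, fs, 1.5, 3)
  scb <- sw_locked_scalogram(xb, sws, fs)
  expect_lt(abs(mean(scb$z)), 0.5)
})

test_that("coupling summary recovers the generative coupling per channel", {
  sim <- simulate_recording(sim_params(duration_s = 900, seed = 10,
                                       p_coupled = 1, kappa = 3,
                                       mu_deg = 30, sp_density_per_min = 4,
                                       sw_density_per_min = 10))
  ev <- detect_events(sim$recording, sim$hypnogram, individualize = FALSE)
  cs <- coupling_summary(sim$recording, sim$hypnogram, NULL, ev,
                         n_shuffles = 500, seed = 3)
  expect_equal(nrow(cs), 1L)
  expect_gt(cs$n_overlapping / cs$n_spindles, 0.8)
  expect_lt(abs(((cs$mean_angle_deg - 30 + 180) %% 360) - 180), 15)
  expect_gt(cs$mrl_z, 3)
})
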