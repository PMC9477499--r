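# Shared fixture builders. Everything is generated in code at test time.

fs_std <- 128

# A sinusoid of given frequency/amplitude/duration.
sine_wave <- function(freq_hz, dur_s, amp = 1, fs = fs_std, phase = 0) {
  amp * sin(2 * pi * freq_hz * (0:(round(dur_s * fs) - 1)) / fs + phase)
}

# Recording whose epochs are i.i.d. white noise, all scored N2.
white_noise_recording <- function(n_epochs, sd = 10, fs = fs_std, seed = 1) {
  set.seed(seed)
  n <- n_epochs * 30 * fs
  rec <- eeg_recording(matrix(rnorm(n, sd = sd), nrow = 1), fs = fs)
  list(rec = rec, h = hypnogram(rep("N2", n_epochs)))
}

# All-N2 hypnogram simulation at the standard detection fixture
# settings: 13 Hz, 1-s, 15-uV-envelope spindles at 2/min over a 5-uV-RMS
# 1/f background.
spindle_fixture <- function(seed, duration_s = 600, sp_freq_hz = 13,
                            p_coupled = 0) {
  n_ep <- duration_s / 30
  simulate_recording(sim_params(
    duration_s = duration_s, seed = seed, sp_freq_hz = sp_freq_hz,
    sp_amp_uV = 15, sp_dur_lo_s = 1, sp_dur_hi_s = 1.0001,
    sp_density_per_min = 2, background_rms_uV = 5,
    p_coupled = p_coupled, sw_density_per_min = if (p_coupled > 0) 8 else 0,
    stage_sequence = hypnogram(rep("N2", n_ep))))
}

# Fixed-amplitude (150 uV), 1-s slow-wave fixture, no spindles.
sw_fixture <- function(seed, duration_s = 600) {
  simulate_recording(sim_params(
    duration_s = duration_s, seed = seed, sw_amp_mean_uV = 150,
    sw_amp_sd_uV = 1e-6, sw_dur_lo_s = 1, sw_dur_hi_s = 1.0001,
    sp_density_per_min = 0,
    stage_sequence = hypnogram(rep("N2", duration_s / 30))))
}

# Recall/precision of detected against true event times.
match_rate <- function(detected_s, truth_s, tol_s) {
  if (!length(truth_s)) return(c(recall = NA, precision = NA))
  recall <- mean(vapply(truth_s, function(t)
    any(abs(detected_s - t) <= tol_s), logical(1)))
  precision <- if (length(detected_s)) {
    mean(vapply(detected_s, function(t)
      any(abs(truth_s - t) <= tol_s), logical(1)))
  } else NA
  c(recall = recall, precision = precision)
}

# Pair table in the shape match_spindles_to_sw() returns, built from a
# SW table and arbitrary peak times.
make_pairs <- function(sw_tbl, sw_idx, peak_s) {
  tibble::tibble(spindle = seq_along(sw_idx), sw = sw_idx,
                 peak_s = peak_s, trough_s = sw_tbl$trough_s[sw_idx],
                 sw_start_s = sw_tbl$start_s[sw_idx],
                 sw_end_s = sw_tbl$end_s[sw_idx])
}
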