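#' Detector configuration
#'
#' Parameters of the spindle and slow-wave detectors. Spindle thresholds
#' are multiples of the median smoothed wavelet magnitude over the whole
#' analyzed signal (median-relative, hence amplitude-scale invariant);
#' slow-wave thresholds are multiples of the median negative half-wave
#' trough amplitude.
#'
#' @param sp_center_hz Spindle wavelet centre frequency, Hz (typically
#'   individualized per subject and channel from the peak sigma
#'   frequency).
#' @param sp_main_mult,sp_secondary_mult Main and secondary median
#'   multipliers for the wavelet magnitude thresholds.
#' @param sp_min_s,sp_max_s,sp_merge_gap_s Spindle duration bounds and
#'   merge gap, seconds.
#' @param smooth_s Moving-average width applied to the wavelet
#'   magnitude, seconds.
#' @param sigma_band_hz Sigma FIR passband, Hz.
#' @param sigma_fir_order Sigma FIR order (linear phase).
#' @param sw_band_hz Slow-wave band-pass edges, Hz.
#' @param sw_fir_order Slow-wave FIR order.
#' @param sw_amp_mult Slow-wave median multiplier.
#' @param sw_min_s,sw_max_s Slow-wave duration bounds, seconds.
#' @return A list of class `detector_config`.
#' @export
detector_config <- function(sp_center_hz = 13, sp_main_mult = 3,
                            sp_secondary_mult = 1.5, sp_min_s = 0.5,
                            sp_max_s = 3, sp_merge_gap_s = 0.5,
                            smooth_s = 0.1, sigma_band_hz = c(10, 16),
                            sigma_fir_order = 960, sw_band_hz = c(0.25, 4),
                            sw_fir_order = 1536, sw_amp_mult = 2,
                            sw_min_s = 0.5, sw_max_s = 2) {
  cfg <- as.list(environment())
  stopifnot(cfg$sp_main_mult > 0, cfg$sp_secondary_mult > 0,
            cfg$sw_amp_mult > 0, cfg$sp_min_s < cfg$sp_max_s,
            cfg$sw_min_s < cfg$sw_max_s)
  class(cfg) <- "detector_config"
  cfg
}

# Complex frequency B-spline wavelet kernel:
# psi(t) = sqrt(fb) * sinc(fb t / m)^m * exp(2 pi i fc t),
# a fixed-shape kernel whose spectral envelope is an order-m B-spline of
# full width fb Hz centred on fc (so +/-1 Hz selectivity at fb = 2).
cfbs_kernel <- function(center_hz, fs, fb = 2, m = 2, support_s = 4) {
  t <- seq(-support_s, support_s, by = 1 / fs)
  u <- fb * t / m
  sinc <- ifelse(u == 0, 1, sin(pi * u) / (pi * u))
  sqrt(fb) * sinc^m * exp(2i * pi * center_hz * t)
}

#' Smoothed wavelet-transform magnitude at one centre frequency
#'
#' Magnitude of the convolution of the signal with a complex frequency
#' B-spline wavelet (order 2, bandwidth 2) at `center_hz`, smoothed with
#' a 0.1-s centred moving average. Same length as the input.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate, Hz.
#' @param center_hz Centre frequency, Hz; must lie in `valid_range`.
#' @param fb,m Wavelet bandwidth and order parameters.
#' @param smooth_s Moving-average width, seconds.
#' @param valid_range Permitted centre-frequency range, Hz.
#' @return Numeric magnitude series.
#' @export
cfbs_magnitude <- function(x, fs, center_hz, fb = 2, m = 2, smooth_s = 0.1,
                           valid_range = c(10, 16)) {
  if (center_hz < valid_range[1] || center_hz > valid_range[2]) {
    stop(sprintf("centre frequency %.2f Hz outside [%g, %g]", center_hz,
                 valid_range[1], valid_range[2]), call. = FALSE)
  }
  kern <- cfbs_kernel(center_hz, fs, fb, m)
  n <- length(x)
  mlen <- length(kern)
  nf <- stats::nextn(n + mlen - 1, 2)
  X <- stats::fft(c(x, numeric(nf - n)))
  K <- stats::fft(c(kern, complex(real = numeric(nf - mlen))))
  conv <- stats::fft(X * K, inverse = TRUE) / nf
  centre <- (mlen - 1) / 2
  mag <- Mod(conv[(1 + centre):(n + centre)])
  moving_average(mag, round(smooth_s * fs))
}

# Merge candidate intervals closer than gap_samp, unless the merged
# span would exceed max_samp (then both are kept unmerged).
merge_close_events <- function(iv, gap_samp, max_samp) {
  if (nrow(iv) < 2) return(iv)
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  out <- iv[1, , drop = FALSE]
  for (i in 2:nrow(iv)) {
    last <- nrow(out)
    gap <- iv[i, 1] - out[last, 2]
    span <- iv[i, 2] - out[last, 1] + 1
    if (gap < gap_samp && span <= max_samp) {
      out[last, 2] <- iv[i, 2]
    } else {
      out <- rbind(out, iv[i, ])
    }
  }
  out
}

#' Detect sleep spindles in surviving N2+N3 data
#'
#' Candidate spindles are contiguous runs where the smoothed wavelet
#' magnitude exceeds the main threshold (3 x median), extended outward
#' to the flanking secondary-threshold (1.5 x median) crossings; medians
#' are computed over all supplied segments pooled. Candidates touching a
#' segment edge are discarded (duration unverifiable), duration must lie
#' in \[0.5, 3\] s, events separated by under 0.5 s are merged unless
#' the merged span exceeds 3 s, and surviving candidates must pass the
#' band-ratio quality metric of [spindle_quality()]. Features follow
#' [spindle_features()].
#'
#' @param segments List of contiguous segments as returned by
#'   [surviving_segments()] (each `list(x=, start=)`), or a plain
#'   numeric vector.
#' @param fs Sampling rate, Hz.
#' @param cfg A [detector_config()].
#' @return Tibble of events: `start_s`, `peak_s`, `end_s`,
#'   `amplitude_uV`, `frequency_hz` (times from record start, seconds).
#' @export
detect_spindles <- function(segments, fs, cfg = detector_config()) {
  if (is.numeric(segments)) segments <- list(list(x = segments, start = 1L))
  empty <- tibble::tibble(start_s = numeric(0), peak_s = numeric(0),
                          end_s = numeric(0), amplitude_uV = numeric(0),
                          frequency_hz = numeric(0))
  if (!length(segments)) return(empty)
  mags <- lapply(segments, function(s)
    cfbs_magnitude(s$x, fs, cfg$sp_center_hz, smooth_s = cfg$smooth_s))
  med <- stats::median(unlist(mags))
  if (!is.finite(med) || med <= 0) {
    warning("zero median wavelet magnitude; no spindles detectable",
            call. = FALSE)
    return(empty)
  }
  main <- cfg$sp_main_mult * med
  sec <- cfg$sp_secondary_mult * med
  baseline <- welch_psd(lapply(segments, `[[`, "x"), fs,
                        fmin = 0.25, fmax = 30)
  bf <- signal::fir1(cfg$sigma_fir_order,
                     cfg$sigma_band_hz / (fs / 2), type = "pass")

  out <- list()
  for (si in seq_along(segments)) {
    x <- segments[[si]]$x
    mag <- mags[[si]]
    runs <- true_runs(mag > main)
    if (!nrow(runs)) next
    above_sec <- mag > sec
    iv <- t(apply(runs, 1, function(r) {
      s <- r[1]; e <- r[2]
      while (s > 1 && above_sec[s - 1]) s <- s - 1
      while (e < length(mag) && above_sec[e + 1]) e <- e + 1
      c(s, e)
    }))
    # distinct main-threshold runs must stay distinct candidates: when a
    # shared secondary region makes neighbouring extensions overlap, cut
    # at the magnitude minimum between the two main runs and let the
    # merge rule decide their fate
    if (nrow(iv) > 1) {
      for (i in 2:nrow(iv)) {
        if (iv[i, 1] <= iv[i - 1, 2]) {
          gap_ix <- (runs[i - 1, 2] + 1L):(runs[i, 1] - 1L)
          cut <- gap_ix[which.min(mag[gap_ix])]
          iv[i - 1, 2] <- cut - 1L
          iv[i, 1] <- cut + 1L
        }
      }
    }
    iv <- unique(iv)
    # drop candidates touching the segment edge
    iv <- iv[iv[, 1] > 1 & iv[, 2] < length(mag), , drop = FALSE]
    if (!nrow(iv)) next
    dur <- (iv[, 2] - iv[, 1]) / fs
    iv <- iv[dur >= cfg$sp_min_s & dur <= cfg$sp_max_s, , drop = FALSE]
    if (!nrow(iv)) next
    iv <- merge_close_events(iv, cfg$sp_merge_gap_s * fs, cfg$sp_max_s * fs)

    xf <- fir_filter_zerophase(x, bf)
    for (i in seq_len(nrow(iv))) {
      s <- iv[i, 1]; e <- iv[i, 2]
      if (!spindle_quality(x[s:e], fs, baseline,
                           sigma_band_hz = cfg$sigma_band_hz)) next
      pk <- s + which.max(mag[s:e]) - 1L
      feats <- spindle_features(xf[s:e], fs)
      start0 <- segments[[si]]$start - 1L
      out[[length(out) + 1L]] <- tibble::tibble(
        start_s = (start0 + s - 1) / fs,
        peak_s = (start0 + pk - 1) / fs,
        end_s = (start0 + e - 1) / fs,
        amplitude_uV = feats$amplitude_uV,
        frequency_hz = feats$frequency_hz)
    }
  }
  if (!length(out)) return(empty)
  dplyr::bind_rows(out)
}

#' Spindle band-ratio quality metric
#'
#' The sigma-band (10-16 Hz) power increase of the event window relative
#' to the baseline PSD must exceed the mean of the delta (1-4), theta
#' (4-8) and beta (16-25 Hz) increases relative to their baselines.
#' Bands with zero baseline power are dropped from the comparison.
#'
#' @param x_event Raw samples of the event window (>= 0.5 s).
#' @param fs Sampling rate, Hz.
#' @param baseline_psd `psd` tibble of the whole analyzed signal,
#'   covering 0.25-25 Hz.
#' @param sigma_band_hz,delta_band_hz,theta_band_hz,beta_band_hz Band
#'   edges, Hz.
#' @return `TRUE` if the event passes.
#' @export
spindle_quality <- function(x_event, fs, baseline_psd,
                            sigma_band_hz = c(10, 16),
                            delta_band_hz = c(1, 4),
                            theta_band_hz = c(4, 8),
                            beta_band_hz = c(16, 25)) {
  n <- length(x_event)
  X <- stats::fft(x_event)
  half <- n %/% 2 + 1L
  pxx <- Mod(X[1:half])^2 / (fs * n)
  pxx[2:(half - 1L)] <- 2 * pxx[2:(half - 1L)]
  freq <- (0:(half - 1L)) * fs / n
  inc <- function(band) {
    ev <- mean(pxx[freq >= band[1] & freq <= band[2]])
    bl <- mean(baseline_psd$power[baseline_psd$freq >= band[1] &
                                    baseline_psd$freq <= band[2]])
    if (!is.finite(bl) || bl <= 0) return(NA_real_)
    ev / bl
  }
  inc_sigma <- inc(sigma_band_hz)
  others <- c(inc(delta_band_hz), inc(theta_band_hz), inc(beta_band_hz))
  others <- others[!is.na(others)]
  if (is.na(inc_sigma) || !length(others)) return(FALSE)
  inc_sigma > mean(others)
}

#' Spindle amplitude and frequency features
#'
#' Amplitude is the maximum consecutive peak-to-trough excursion of the
#' sigma-filtered signal within the event; frequency is the reciprocal
#' of the mean interval between positive voltage peaks (local maxima
#' above zero). With fewer than two positive peaks the frequency is
#' `NA` and the event is retained.
#'
#' @param xf_event Sigma-filtered samples of the event window.
#' @param fs Sampling rate, Hz.
#' @return One-row tibble `amplitude_uV`, `frequency_hz`.
#' @export
spindle_features <- function(xf_event, fs) {
  n <- length(xf_event)
  d <- diff(xf_event)
  ext <- which(d[-length(d)] * d[-1] < 0) + 1L     # local extrema
  amp <- if (length(ext) >= 2) {
    max(abs(diff(xf_event[ext])))
  } else {
    max(xf_event) - min(xf_event)
  }
  is_max <- ext[xf_event[ext] > pmax(xf_event[ext - 1L], xf_event[ext + 1L])]
  pos_pk <- is_max[xf_event[is_max] > 0]
  freq <- if (length(pos_pk) >= 2) {
    # parabolic interpolation refines each peak below sample resolution
    refined <- vapply(pos_pk, function(i) {
      y0 <- xf_event[i - 1L]; y1 <- xf_event[i]; y2 <- xf_event[i + 1L]
      den <- y0 - 2 * y1 + y2
      if (abs(den) < .Machine$double.eps) return(as.numeric(i))
      i + 0.5 * (y0 - y2) / den
    }, numeric(1))
    1 / mean(diff(refined) / fs)
  } else NA_real_
  tibble::tibble(amplitude_uV = amp, frequency_hz = freq)
}

# Hamming-windowed sinc FIR band-pass for the slow-wave band, applied
# zero-phase. Exposed internally for the coupling and simulation code.
sw_bandpass <- function(x, fs, band_hz = c(0.25, 4), order = 1536) {
  bf <- signal::fir1(order, band_hz / (fs / 2), type = "pass")
  fir_filter_zerophase(x, bf)
}

#' Detect slow-wave negative half-waves in surviving N2+N3 data
#'
#' The signal is band-pass filtered (0.25-4 Hz, Hamming-windowed sinc
#' FIR, zero-phase) per contiguous segment. Every negative half-wave
#' (positive-to-negative zero crossing to the next negative-to-positive
#' crossing) is enumerated; a candidate is kept iff its trough depth
#' exceeds `sw_amp_mult` times the median trough depth of the
#' duration-eligible (0.5-2 s) half-waves pooled across segments, and
#' its own duration lies in \[0.5, 2\] s.
#'
#' @inheritParams detect_spindles
#' @return Tibble of events: `start_s`, `trough_s`, `end_s`,
#'   `amplitude_uV` (signed, negative: the raw signal's peak negative
#'   deflection within the half-wave), `duration_s`.
#' @export
detect_slow_waves <- function(segments, fs, cfg = detector_config()) {
  if (is.numeric(segments)) segments <- list(list(x = segments, start = 1L))
  empty <- tibble::tibble(start_s = numeric(0), trough_s = numeric(0),
                          end_s = numeric(0), amplitude_uV = numeric(0),
                          duration_s = numeric(0))
  if (!length(segments)) return(empty)
  halves <- list()
  for (si in seq_along(segments)) {
    xf <- sw_bandpass(segments[[si]]$x, fs, cfg$sw_band_hz, cfg$sw_fir_order)
    neg <- xf < 0
    pn <- which(!neg[-length(neg)] & neg[-1])          # P->N at i -> i+1
    np <- which(neg[-length(neg)] & !neg[-1])          # N->P at j -> j+1
    if (!length(pn) || !length(np)) next
    for (i in pn) {
      j <- np[np > i]
      if (!length(j)) next
      j <- j[1]
      seg_ix <- (i + 1L):j
      tr <- seg_ix[which.min(xf[seg_ix])]
      halves[[length(halves) + 1L]] <- data.frame(
        seg = si, start = i, trough = tr, end = j + 1L,
        amp = xf[tr], dur = (j + 1L - i) / fs)
    }
  }
  if (!length(halves)) return(empty)
  hw <- do.call(rbind, halves)
  # the reference median is taken over the duration-eligible half-waves:
  # sub-0.5-s noise ripples vastly outnumber SW-scale half-waves and have
  # far smaller troughs, so pooling them would collapse the median and let
  # background half-waves through the 2x threshold
  dur_ok <- hw$dur >= cfg$sw_min_s & hw$dur <= cfg$sw_max_s
  if (!any(dur_ok)) return(empty)
  med <- stats::median(abs(hw$amp[dur_ok]))
  keep <- abs(hw$amp) > cfg$sw_amp_mult * med & dur_ok
  hw <- hw[keep, , drop = FALSE]
  if (!nrow(hw)) return(empty)
  start0 <- vapply(segments, function(s) s$start - 1L, numeric(1))
  # reported amplitude = peak negative deflection of the raw signal
  # inside the half-wave (the band-pass removes an isolated half-wave's
  # sub-0.25 Hz content and would understate its depth)
  raw_amp <- vapply(seq_len(nrow(hw)), function(i) {
    min(segments[[hw$seg[i]]]$x[hw$start[i]:hw$end[i]])
  }, numeric(1))
  tibble::tibble(
    start_s = (start0[hw$seg] + hw$start - 1) / fs,
    trough_s = (start0[hw$seg] + hw$trough - 1) / fs,
    end_s = (start0[hw$seg] + hw$end - 1) / fs,
    amplitude_uV = raw_amp,
    duration_s = hw$dur)
}

#' Event density per analyzed minute
#'
#' @param events Event tibble (or an event count).
#' @param analyzed_minutes Surviving N2+N3 minutes (> 0).
#' @return Events per minute.
#' @export
event_density <- function(events, analyzed_minutes) {
  if (analyzed_minutes <= 0) {
    stop("analyzed time must be positive", call. = FALSE)
  }
  n <- if (is.numeric(events)) events else nrow(events)
  n / analyzed_minutes
}

#' Detect spindles and slow waves on every channel of a recording
#'
#' Convenience wrapper: per channel, gathers surviving N2+N3 segments,
#' optionally individualizes the spindle centre frequency from the peak
#' sigma frequency of the z-scored oscillatory spectrum, and runs both
#' detectors.
#'
#' @param rec Conditioned [eeg_recording()].
#' @param h [hypnogram()].
#' @param mask Epoch mask (or `NULL`).
#' @param cfg Base [detector_config()].
#' @param individualize Recompute `sp_center_hz` per channel from the
#'   data (default `TRUE`).
#' @return List with tibbles `spindles` and `slow_waves` (each with a
#'   `channel` column) and `centers` (per-channel centre frequency).
#' @export
detect_events <- function(rec, h, mask = NULL, cfg = detector_config(),
                          individualize = TRUE) {
  sp_all <- list(); sw_all <- list(); centers <- list()
  for (ch in rec$channel_labels) {
    segs <- surviving_segments(rec, h, mask, ch)
    cfg_ch <- cfg
    if (individualize && length(segs) &&
        sum(lengths(lapply(segs, `[[`, "x"))) >= 60 * rec$fs) {
      x <- unlist(lapply(segs, `[[`, "x"))
      z <- (x - mean(x)) / stats::sd(x)
      pk <- peak_sigma_frequency(irasa(z, rec$fs)$oscillatory,
                                 cfg$sigma_band_hz)
      cfg_ch$sp_center_hz <- pk$peak_hz
    }
    sp <- detect_spindles(segs, rec$fs, cfg_ch)
    sw <- detect_slow_waves(segs, rec$fs, cfg_ch)
    sp_all[[ch]] <- dplyr::mutate(sp, channel = ch, .before = 1)
    sw_all[[ch]] <- dplyr::mutate(sw, channel = ch, .before = 1)
    centers[[ch]] <- cfg_ch$sp_center_hz
  }
  list(spindles = dplyr::bind_rows(sp_all),
       slow_waves = dplyr::bind_rows(sw_all),
       centers = tibble::tibble(channel = names(centers),
                                sp_center_hz = unname(unlist(centers))))
}
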