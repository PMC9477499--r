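#' Instantaneous slow-wave phase series
#'
#' Phase of the analytic (Hilbert) signal of the slow-wave-filtered
#' trace, remapped so that 0 degrees is the positive-to-negative zero
#' crossing, 90 the trough, 180 the negative-to-positive crossing and
#' 270 the peak (reported phase = analytic angle - 90, modulo 360).
#'
#' @param filtered_samples Signal already band-passed to the SW band
#'   (0.25-4 Hz); one contiguous segment of at least 4 s.
#' @param fs Sampling rate, Hz.
#' @return Phase in degrees, `[0, 360)`, same length as input.
#' @export
sw_phase_series <- function(filtered_samples, fs) {
  if (length(filtered_samples) < 4 * fs) {
    stop("phase series needs a contiguous segment of at least 4 s",
         call. = FALSE)
  }
  a <- analytic_signal(filtered_samples)
  (Arg(a) * 180 / pi - 90) %% 360
}

# Record-length phase vector for one channel: NA outside surviving
# segments, package phase convention inside each segment.
sw_phase_record <- function(rec, h, mask = NULL, channel,
                            band_hz = c(0.25, 4), order = 1536) {
  phase <- rep(NA_real_, ncol(rec$samples))
  for (seg in surviving_segments(rec, h, mask, channel)) {
    if (length(seg$x) < 4 * rec$fs) next
    xf <- sw_bandpass(seg$x, rec$fs, band_hz, order)
    phase[seg$start + seq_along(seg$x) - 1L] <- sw_phase_series(xf, rec$fs)
  }
  phase
}

#' Match spindles to overlapping slow waves
#'
#' A spindle overlaps a SW when its peak lies within +/- `window_s` of
#' the SW trough. A spindle within range of several SWs is assigned to
#' the one with the nearest trough; exact ties go to the earlier trough.
#'
#' @param spindles Spindle tibble (needs `peak_s`).
#' @param sws Slow-wave tibble (needs `trough_s`, `start_s`, `end_s`).
#' @param window_s Overlap half-window, seconds (default 1.5).
#' @return Tibble of pairs: `spindle` and `sw` row indices, `peak_s`,
#'   `trough_s`, `sw_start_s`, `sw_end_s`.
#' @export
match_spindles_to_sw <- function(spindles, sws, window_s = 1.5) {
  empty <- tibble::tibble(spindle = integer(0), sw = integer(0),
                          peak_s = numeric(0), trough_s = numeric(0),
                          sw_start_s = numeric(0), sw_end_s = numeric(0))
  if (!nrow(spindles) || !nrow(sws)) return(empty)
  ord <- order(sws$trough_s)
  rows <- lapply(seq_len(nrow(spindles)), function(i) {
    d <- abs(sws$trough_s - spindles$peak_s[i])
    if (min(d) > window_s + 1e-12) return(NULL)
    # nearest trough; ties broken toward the earlier trough
    j <- order(d, sws$trough_s)[1]
    tibble::tibble(spindle = i, sw = j, peak_s = spindles$peak_s[i],
                   trough_s = sws$trough_s[j], sw_start_s = sws$start_s[j],
                   sw_end_s = sws$end_s[j])
  })
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) empty else out
}

#' Mean resultant length and mean angle of coupling phases
#'
#' `mrl = |mean(exp(i theta))|`; `mean_angle = arg(mean(exp(i theta)))`
#' mapped to `[0, 360)`. The mean angle is `NA` when the resultant is
#' numerically zero (no preferred direction).
#'
#' @param phases_deg Phases in degrees.
#' @return One-row tibble `mrl`, `mean_angle_deg`, `n`.
#' @export
#' @examples
#' coupling_stats(c(0, 90)) # mrl ~ 0.707, angle 45
coupling_stats <- function(phases_deg) {
  phases_deg <- phases_deg[!is.na(phases_deg)]
  if (!length(phases_deg)) {
    return(tibble::tibble(mrl = NA_real_, mean_angle_deg = NA_real_, n = 0L))
  }
  z <- mean(exp(1i * phases_deg * pi / 180))
  mrl <- Mod(z)
  ang <- if (mrl < 1e-12) NA_real_ else (Arg(z) * 180 / pi) %% 360
  tibble::tibble(mrl = mrl, mean_angle_deg = ang, n = length(phases_deg))
}

# Fraction of peaks within window_s of any trough (troughs sorted).
overlap_fraction <- function(peaks, troughs_sorted, window_s) {
  if (!length(peaks)) return(NA_real_)
  if (!length(troughs_sorted)) return(0)
  pos <- findInterval(peaks, troughs_sorted)
  lo <- pmax(pos, 1L)
  hi <- pmin(pos + 1L, length(troughs_sorted))
  d <- pmin(abs(peaks - troughs_sorted[lo]), abs(peaks - troughs_sorted[hi]))
  mean(d <= window_s + 1e-12)
}

#' Shuffle-null z-score of the spindle-SW overlap proportion
#'
#' Each shuffle repositions every spindle peak uniformly within its own
#' 30-s epoch and recomputes the overlap fraction; the observed fraction
#' is z-scored against the null mean and SD.
#'
#' @param spindles Spindle tibble (needs `peak_s`).
#' @param sws SW tibble (needs `trough_s`).
#' @param epoch_len_s Epoch length, seconds.
#' @param window_s Overlap half-window, seconds.
#' @param n_shuffles Number of shuffles (default 1000).
#' @param seed Integer seed (deterministic for fixed seed).
#' @return One-row tibble `overlap_raw`, `overlap_z` (`NA` when the
#'   null SD is zero), `n_spindles`.
#' @export
overlap_null_z <- function(spindles, sws, epoch_len_s = 30, window_s = 1.5,
                           n_shuffles = 1000, seed = 1L) {
  if (!nrow(spindles)) {
    return(tibble::tibble(overlap_raw = NA_real_, overlap_z = NA_real_,
                          n_spindles = 0L))
  }
  troughs <- sort(sws$trough_s)
  obs <- overlap_fraction(spindles$peak_s, troughs, window_s)
  ep <- floor(spindles$peak_s / epoch_len_s)
  set.seed(seed)
  null <- vapply(seq_len(n_shuffles), function(k) {
    shuf <- (ep + stats::runif(length(ep))) * epoch_len_s
    overlap_fraction(shuf, troughs, window_s)
  }, numeric(1))
  s <- stats::sd(null)
  z <- if (!is.finite(s) || s == 0) NA_real_ else (obs - mean(null)) / s
  tibble::tibble(overlap_raw = obs, overlap_z = z,
                 n_spindles = nrow(spindles))
}

#' Shuffle-null z-score of the mean resultant length
#'
#' Each shuffle repositions every paired spindle peak uniformly within
#' its host SW's extent (or, optionally, within the +/-1.5 s matching
#' window) and recomputes the MRL from the phase series. Shuffled peaks
#' landing where phase is undefined are redrawn (up to 100 times, then
#' dropped from that shuffle).
#'
#' @param pairs Pair tibble from [match_spindles_to_sw()].
#' @param phase Record-length phase vector in degrees (`NA` where
#'   undefined), e.g. from internal segment-wise phase computation.
#' @param fs Sampling rate, Hz.
#' @param n_shuffles Number of shuffles.
#' @param seed Integer seed.
#' @param domain `"sw_extent"` (default) or `"window"`.
#' @param window_s Half-window when `domain = "window"`.
#' @param min_pairs Below this many pairs the z is flagged unstable
#'   (`NA`).
#' @return One-row tibble `mrl_raw`, `mrl_z`, `mean_angle_deg`, `n_pairs`.
#' @export
mrl_null_z <- function(pairs, phase, fs, n_shuffles = 1000, seed = 1L,
                       domain = c("sw_extent", "window"), window_s = 1.5,
                       min_pairs = 5) {
  domain <- match.arg(domain)
  n <- nrow(pairs)
  if (!n) {
    return(tibble::tibble(mrl_raw = NA_real_, mrl_z = NA_real_,
                          mean_angle_deg = NA_real_, n_pairs = 0L))
  }
  peak_ix <- round(pairs$peak_s * fs) + 1L
  obs <- coupling_stats(phase[peak_ix])
  if (domain == "sw_extent") {
    lo <- round(pairs$sw_start_s * fs) + 1L
    hi <- round(pairs$sw_end_s * fs) + 1L
  } else {
    lo <- round((pairs$trough_s - window_s) * fs) + 1L
    hi <- round((pairs$trough_s + window_s) * fs) + 1L
  }
  lo <- pmax(lo, 1L); hi <- pmin(hi, length(phase))
  set.seed(seed)
  null <- vapply(seq_len(n_shuffles), function(k) {
    ix <- lo + floor(stats::runif(n) * (hi - lo + 1L))
    th <- phase[ix]
    for (r in seq_len(100)) {
      miss <- which(is.na(th))
      if (!length(miss)) break
      ix2 <- lo[miss] + floor(stats::runif(length(miss)) *
                                (hi[miss] - lo[miss] + 1L))
      th[miss] <- phase[ix2]
    }
    th <- th[!is.na(th)]
    if (!length(th)) return(NA_real_)
    Mod(mean(exp(1i * th * pi / 180)))
  }, numeric(1))
  null <- null[!is.na(null)]
  s <- stats::sd(null)
  z <- if (n < min_pairs || !is.finite(s) || s == 0) NA_real_
       else (obs$mrl - mean(null)) / s
  tibble::tibble(mrl_raw = obs$mrl, mrl_z = z,
                 mean_angle_deg = obs$mean_angle_deg, n_pairs = n)
}

#' Slow-wave-trough-locked average waveform
#'
#' Averages raw-signal windows centred on SW troughs; SWs whose window
#' extends past the record edge are excluded.
#'
#' @param x Raw record-time signal of one channel.
#' @param sws SW tibble (needs `trough_s`).
#' @param fs Sampling rate, Hz.
#' @param window_s Two-element lag window, seconds (default `c(-2, 2)`).
#' @return Tibble with `lag_s` and `mean_uV`; attribute `n_used` gives
#'   the number of contributing SWs.
#' @export
sw_locked_average <- function(x, sws, fs, window_s = c(-2, 2)) {
  lags <- seq(round(window_s[1] * fs), round(window_s[2] * fs))
  tr <- round(sws$trough_s * fs) + 1L
  ok <- tr + lags[1] >= 1 & tr + lags[length(lags)] <= length(x)
  if (!any(ok)) stop("no SW window fits inside the record", call. = FALSE)
  tr <- tr[ok]
  acc <- numeric(length(lags))
  for (t0 in tr) acc <- acc + x[t0 + lags]
  out <- tibble::tibble(lag_s = lags / fs, mean_uV = acc / length(tr))
  attr(out, "n_used") <- length(tr)
  out
}

#' Slow-wave-trough-locked scalogram
#'
#' Wavelet magnitude (complex frequency B-spline, bandwidth 2, order 2)
#' over 8-16 Hz around each SW trough, z-scored per frequency row
#' against the mean and SD of the 2 to 1.5 s pre-trough baseline
#' columns, then averaged across SWs. Rows with zero baseline SD are
#' flagged missing (`NA`).
#'
#' @param x Raw record-time signal of one channel.
#' @param sws SW tibble (>= 5 rows).
#' @param fs Sampling rate, Hz.
#' @param freqs_hz Analysis frequencies, Hz.
#' @param window_s Lag window around the trough, seconds.
#' @param baseline_s Baseline lag window, seconds.
#' @return Object of class `sw_scalogram`: list with `lag_s`, `freq`
#'   and `z` (freq x lag matrix).
#' @export
sw_locked_scalogram <- function(x, sws, fs, freqs_hz = seq(8, 16, by = 0.5),
                                window_s = c(-2, 2),
                                baseline_s = c(-2, -1.5)) {
  if (nrow(sws) < 5) stop("scalogram needs at least 5 SWs", call. = FALSE)
  lags <- seq(round(window_s[1] * fs), round(window_s[2] * fs))
  tr <- round(sws$trough_s * fs) + 1L
  tr <- tr[tr + lags[1] >= 1 & tr + lags[length(lags)] <= length(x)]
  if (length(tr) < 5) stop("fewer than 5 SW windows fit the record",
                           call. = FALSE)
  bl_cols <- which(lags / fs >= baseline_s[1] - 1e-12 &
                     lags / fs <= baseline_s[2] + 1e-12)
  zmat <- matrix(0, length(freqs_hz), length(lags))
  nmat <- matrix(0, length(freqs_hz), length(lags))
  for (fi in seq_along(freqs_hz)) {
    mag <- cfbs_magnitude(x, fs, freqs_hz[fi], valid_range = c(8, 16))
    for (t0 in tr) {
      w <- mag[t0 + lags]
      mu <- mean(w[bl_cols]); s <- stats::sd(w[bl_cols])
      if (!is.finite(s) || s == 0) next
      zmat[fi, ] <- zmat[fi, ] + (w - mu) / s
      nmat[fi, ] <- nmat[fi, ] + 1
    }
  }
  z <- zmat / nmat
  z[nmat == 0] <- NA_real_
  structure(list(lag_s = lags / fs, freq = freqs_hz, z = z,
                 n_used = length(tr)),
            class = "sw_scalogram")
}

#' @export
print.sw_scalogram <- function(x, ...) {
  cat(sprintf("<sw_scalogram> %d freqs x %d lags, %d SWs\n",
              length(x$freq), length(x$lag_s), x$n_used))
  invisible(x)
}

#' Per-channel spindle-slow-wave coupling summary
#'
#' Computes, for every channel: spindle count, number overlapping a SW,
#' raw overlap proportion with its epoch-shuffle z-score, MRL of the SW
#' phase at paired spindle peaks with its within-SW-shuffle z-score, and
#' the mean coupling angle.
#'
#' @param rec Conditioned [eeg_recording()].
#' @param h [hypnogram()].
#' @param mask Epoch mask (or `NULL`).
#' @param events Result of [detect_events()] (or a compatible list with
#'   `spindles` and `slow_waves` tibbles carrying a `channel` column).
#' @param n_shuffles Shuffles per null (default 1000).
#' @param seed Integer seed.
#' @param shuffle_domain Passed to [mrl_null_z()].
#' @return Tibble with one row per channel: `channel`, `n_spindles`,
#'   `n_overlapping`, `overlap_raw`, `overlap_z`, `mrl_raw`, `mrl_z`,
#'   `mean_angle_deg`.
#' @export
coupling_summary <- function(rec, h, mask = NULL, events,
                             n_shuffles = 1000, seed = 1L,
                             shuffle_domain = "sw_extent") {
  purrr::map_dfr(rec$channel_labels, function(ch) {
    sp <- dplyr::filter(events$spindles, .data$channel == ch)
    sw <- dplyr::filter(events$slow_waves, .data$channel == ch)
    pairs <- match_spindles_to_sw(sp, sw)
    ov <- overlap_null_z(sp, sw, epoch_len_s = h$epoch_len_s,
                         n_shuffles = n_shuffles, seed = seed)
    phase <- sw_phase_record(rec, h, mask, ch)
    mr <- mrl_null_z(pairs, phase, rec$fs, n_shuffles = n_shuffles,
                     seed = seed + 1L, domain = shuffle_domain)
    tibble::tibble(channel = ch, n_spindles = nrow(sp),
                   n_overlapping = nrow(pairs),
                   overlap_raw = ov$overlap_raw, overlap_z = ov$overlap_z,
                   mrl_raw = mr$mrl_raw, mrl_z = mr$mrl_z,
                   mean_angle_deg = mr$mean_angle_deg)
  })
}
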