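#' Welch power spectral density
#'
#' Averaged modified periodogram with a 4-s Hann window advanced in 2-s
#' steps. Input longer than one scoring epoch is split into 30-s epochs,
#' each epoch's windows are averaged, and the epoch spectra are then
#' averaged with equal weight; a list of contiguous segments may be
#' passed, in which case no window spans a segment boundary. Output is a
#' one-sided power density (uV^2/Hz) on a 0.25 Hz grid restricted to
#' `[fmin, fmax]`, with a dB view (`10*log10`, floored at -300 dB for
#' zero-power bins).
#'
#' @param x Numeric vector, or list of numeric vectors (contiguous
#'   segments).
#' @param fs Sampling rate, Hz.
#' @param window_s,step_s Welch window length and step, seconds.
#' @param fmin,fmax Frequency range retained, Hz.
#' @param epoch_len_s Scoring epoch length used to chunk long input.
#' @return A tibble of class `psd` with columns `freq`, `power`,
#'   `power_db` and attributes `kind` and `fs`.
#' @export
#' @examples
#' x <- sin(2 * pi * 13 * seq(0, 30, by = 1 / 128))
#' p <- welch_psd(x, 128)
#' p$freq[which.max(p$power)] # 13
welch_psd <- function(x, fs, window_s = 4, step_s = 2, fmin = 0.25,
                      fmax = 20, epoch_len_s = 30) {
  segs <- if (is.list(x)) x else list(x)
  nw <- round(window_s * fs)
  if (all(vapply(segs, length, 1L) < nw)) {
    stop(sprintf("welch_psd needs at least one segment of >= %g s", window_s),
         call. = FALSE)
  }
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(nw - 1)) / nw)   # periodic Hann
  u <- sum(w^2)
  step <- round(step_s * fs)
  ep_n <- round(epoch_len_s * fs)

  one_chunk <- function(seg) {
    starts <- seq(1L, length(seg) - nw + 1L, by = step)
    acc <- numeric(nw %/% 2 + 1)
    for (s in starts) {
      X <- stats::fft(seg[s:(s + nw - 1L)] * w)
      pxx <- (Mod(X[1:(nw %/% 2 + 1)])^2) / (fs * u)
      pxx[2:(nw %/% 2)] <- 2 * pxx[2:(nw %/% 2)]
      acc <- acc + pxx
    }
    acc / length(starts)
  }

  chunks <- list()
  for (seg in segs) {
    if (length(seg) < nw) next
    if (length(seg) >= 2 * ep_n) {
      n_ep <- length(seg) %/% ep_n
      for (e in seq_len(n_ep)) {
        chunks[[length(chunks) + 1L]] <-
          one_chunk(seg[((e - 1L) * ep_n + 1L):(e * ep_n)])
      }
      rem <- seg[(n_ep * ep_n + 1L):length(seg)]
      if (length(rem) >= nw) chunks[[length(chunks) + 1L]] <- one_chunk(rem)
    } else {
      chunks[[length(chunks) + 1L]] <- one_chunk(seg)
    }
  }
  pw <- Reduce(`+`, chunks) / length(chunks)
  freq <- (0:(nw %/% 2)) * fs / nw
  keep <- freq >= fmin - 1e-9 & freq <= fmax + 1e-9
  new_psd(freq[keep], pw[keep], kind = "raw", fs = fs)
}

new_psd <- function(freq, power, kind, fs) {
  out <- tibble::tibble(freq = freq, power = power,
                        power_db = power_to_db(power))
  class(out) <- c("psd", class(out))
  attr(out, "kind") <- kind
  attr(out, "fs") <- fs
  out
}

#' Welch PSD of the z-scored signal
#'
#' Standardizes the signal in the time domain (subtract mean, divide by
#' SD over all supplied samples) before [welch_psd()], removing
#' broadband amplitude differences between recordings.
#'
#' @inheritParams welch_psd
#' @param ... Passed to [welch_psd()].
#' @return A `psd` tibble with kind `"zscored"`.
#' @export
welch_psd_zscored <- function(x, fs, ...) {
  segs <- if (is.list(x)) x else list(x)
  all_x <- unlist(segs)
  s <- stats::sd(all_x)
  if (!is.finite(s) || s == 0) {
    stop("cannot z-score a zero-variance channel", call. = FALSE)
  }
  m <- mean(all_x)
  out <- welch_psd(lapply(segs, function(v) (v - m) / s), fs, ...)
  attr(out, "kind") <- "zscored"
  out
}

## ---- multitaper -----------------------------------------------------

.dpss_cache <- new.env(parent = emptyenv())

# Discrete prolate spheroidal (Slepian) sequences via the symmetric
# tridiagonal eigenproblem; returns n x k matrix of unit-energy tapers.
dpss_tapers <- function(n, nw, k) {
  key <- paste(n, nw, k, sep = "_")
  if (!is.null(.dpss_cache[[key]])) return(.dpss_cache[[key]])
  W <- nw / n
  i <- 0:(n - 1)
  d <- ((n - 1 - 2 * i) / 2)^2 * cos(2 * pi * W)
  e <- (1:(n - 1)) * ((n - 1):1) / 2
  M <- matrix(0, n, n)
  diag(M) <- d
  M[cbind(1:(n - 1), 2:n)] <- e
  M[cbind(2:n, 1:(n - 1))] <- e
  ev <- eigen(M, symmetric = TRUE)
  tapers <- ev$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    v <- tapers[, j]
    v <- v / sqrt(sum(v^2))
    if (sum(v) < 0) v <- -v
    tapers[, j] <- v
  }
  .dpss_cache[[key]] <- tapers
  tapers
}

#' Multitaper spectrogram
#'
#' Slepian-taper spectrogram with a 30-s window advanced in 10-s steps
#' and 1 Hz bandwidth (time-half-bandwidth 15, hence 29 tapers).
#'
#' @param x Numeric signal.
#' @param fs Sampling rate, Hz.
#' @param window_s Window length, seconds.
#' @param step_s Step between window starts, seconds.
#' @param bandwidth_hz Full spectral bandwidth, Hz.
#' @param fmin,fmax Frequency range retained, Hz.
#' @return An object of class `mt_spectrogram`: list with `time` (window
#'   centers, s), `freq` (Hz) and `power` (freq x time matrix, uV^2/Hz).
#' @export
multitaper_spectrogram <- function(x, fs, window_s = 30, step_s = 10,
                                   bandwidth_hz = 1, fmin = 0.25, fmax = 20) {
  nw_samp <- round(window_s * fs)
  if (length(x) < nw_samp) {
    stop("multitaper_spectrogram needs at least ", window_s, " s of data",
         call. = FALSE)
  }
  nw <- window_s * bandwidth_hz / 2
  k <- max(1L, round(2 * nw - 1))
  tapers <- dpss_tapers(nw_samp, nw, k)
  step <- round(step_s * fs)
  starts <- seq(1L, length(x) - nw_samp + 1L, by = step)
  freq <- (0:(nw_samp %/% 2)) * fs / nw_samp
  keep <- freq >= fmin - 1e-9 & freq <= fmax + 1e-9
  pw <- matrix(0, sum(keep), length(starts))
  half <- nw_samp %/% 2 + 1L
  for (ti in seq_along(starts)) {
    seg <- x[starts[ti]:(starts[ti] + nw_samp - 1L)]
    acc <- numeric(half)
    for (j in seq_len(k)) {
      X <- stats::fft(seg * tapers[, j])
      pxx <- Mod(X[1:half])^2 / fs
      pxx[2:(half - 1L)] <- 2 * pxx[2:(half - 1L)]
      acc <- acc + pxx
    }
    pw[, ti] <- (acc / k)[keep]
  }
  structure(list(time = (starts - 1) / fs + window_s / 2,
                 freq = freq[keep], power = pw, fs = fs),
            class = "mt_spectrogram")
}

#' @export
print.mt_spectrogram <- function(x, ...) {
  cat(sprintf("<mt_spectrogram> %d freqs x %d windows, %.2f-%.2f Hz\n",
              length(x$freq), length(x$time), min(x$freq), max(x$freq)))
  invisible(x)
}

## ---- IRASA ----------------------------------------------------------

#' IRASA: irregular-resampling decomposition into fractal and
#' oscillatory spectra
#'
#' For each resampling factor `h`, the signal is resampled by `h` and by
#' `1/h` (polyphase, anti-aliased), the Welch PSD of each is computed on
#' the nominal frequency grid, and the pair is combined by geometric
#' mean. The median across the factor set estimates the aperiodic
#' (fractal) spectrum, which resampling leaves invariant while
#' oscillatory peaks are displaced and cancelled. The oscillatory
#' spectrum is the residual `raw - fractal` in linear power, so the
#' identity `fractal + oscillatory = raw` holds exactly.
#'
#' @param x Numeric signal (or list of contiguous segments, which are
#'   concatenated), at least 60 s.
#' @param fs Sampling rate, Hz.
#' @param hset Resampling factors, all > 1 and expressible on a 0.05
#'   grid; default `seq(1.1, 1.9, by = 0.05)`.
#' @param fmin,fmax Frequency range retained, Hz.
#' @return List with `psd` tibbles `fractal`, `oscillatory` and `raw`.
#' @export
irasa <- function(x, fs, hset = seq(1.1, 1.9, by = 0.05), fmin = 0.25,
                  fmax = 20) {
  if (!length(hset)) stop("empty IRASA factor set", call. = FALSE)
  if (any(hset <= 1)) stop("IRASA factors must exceed 1", call. = FALSE)
  if (is.list(x)) x <- unlist(x)
  if (length(x) < 60 * fs) {
    stop("irasa needs at least 60 s of data", call. = FALSE)
  }
  raw <- welch_psd(x, fs, fmin = fmin, fmax = fmax)
  geo <- matrix(0, nrow(raw), length(hset))
  for (i in seq_along(hset)) {
    p <- round(hset[i] * 20)
    q <- 20L
    g <- gcd(p, q)
    p <- p / g; q <- q / g
    up <- signal::resample(x, p, q)
    dn <- signal::resample(x, q, p)
    ph <- welch_psd(up, fs, fmin = fmin, fmax = fmax)
    pih <- welch_psd(dn, fs, fmin = fmin, fmax = fmax)
    geo[, i] <- sqrt(ph$power * pih$power)
  }
  frac <- apply(geo, 1, stats::median)
  fractal <- new_psd(raw$freq, frac, kind = "fractal", fs = fs)
  osc <- raw$power - frac
  oscillatory <- tibble::tibble(freq = raw$freq, power = osc,
                                power_db = power_to_db(osc))
  class(oscillatory) <- class(fractal)
  attr(oscillatory, "kind") <- "oscillatory"
  attr(oscillatory, "fs") <- fs
  list(fractal = fractal, oscillatory = oscillatory, raw = raw)
}

#' Fit the aperiodic (power-law) component of a spectrum
#'
#' Least-squares line on (log f, log P): `log P = intercept - slope *
#' log f`, i.e. `P = exp(intercept) * f^(-slope)`. Non-positive power
#' bins inside the range are dropped; at least 5 must remain.
#'
#' @param psd A `psd` tibble (typically the IRASA fractal component).
#' @param fit_range_hz Two-element frequency range, Hz; default 1-20 Hz
#'   to avoid the high-pass shoulder.
#' @return Object of class `aperiodic_fit` with fields `slope`,
#'   `intercept`, `fit_range_hz`, `rmse` (log-power units), `n_bins`.
#' @export
#' @examples
#' f <- seq(1, 20, by = 0.25)
#' p <- fit_aperiodic(tibble::tibble(freq = f, power = exp(2) * f^-1.5))
#' c(p$slope, p$intercept) # 1.5, 2
fit_aperiodic <- function(psd, fit_range_hz = c(1, 20)) {
  sel <- psd$freq >= fit_range_hz[1] - 1e-9 &
    psd$freq <= fit_range_hz[2] + 1e-9 & psd$power > 0
  if (sum(sel) < 5) {
    stop("fewer than 5 positive power bins in the fit range", call. = FALSE)
  }
  lf <- log(psd$freq[sel])
  lp <- log(psd$power[sel])
  fit <- stats::lm(lp ~ lf)
  structure(
    list(slope = -unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         fit_range_hz = fit_range_hz,
         rmse = sqrt(mean(stats::residuals(fit)^2)),
         n_bins = sum(sel)),
    class = "aperiodic_fit"
  )
}

#' @export
print.aperiodic_fit <- function(x, ...) {
  cat(sprintf("<aperiodic_fit> slope %.3f, intercept %.3f (%g-%g Hz, rmse %.3g)\n",
              x$slope, x$intercept, x$fit_range_hz[1], x$fit_range_hz[2],
              x$rmse))
  invisible(x)
}

#' Peak sigma frequency of an oscillatory spectrum
#'
#' Frequency of maximum oscillatory power within the sigma band. When no
#' bin in the band has positive oscillatory power (no detectable sigma
#' peak), a fallback of 13 Hz is returned and flagged.
#'
#' @param oscillatory A `psd` tibble (IRASA oscillatory component)
#'   covering the band.
#' @param band_hz Sigma band, Hz.
#' @param fallback_hz Frequency returned when no peak exists.
#' @return One-row tibble with `peak_hz` and logical `fallback`.
#' @export
peak_sigma_frequency <- function(oscillatory, band_hz = c(10, 16),
                                 fallback_hz = 13) {
  sel <- oscillatory$freq >= band_hz[1] - 1e-9 &
    oscillatory$freq <= band_hz[2] + 1e-9
  if (!any(sel)) stop("spectrum does not cover the sigma band", call. = FALSE)
  pw <- oscillatory$power[sel]
  if (max(pw) <= 0) {
    return(tibble::tibble(peak_hz = fallback_hz, fallback = TRUE))
  }
  tibble::tibble(peak_hz = oscillatory$freq[sel][which.max(pw)],
                 fallback = FALSE)
}

#' Mean band power in decibels
#'
#' Mean of per-bin dB values across bins with `lo <= f <= hi`. Bins with
#' non-positive linear power (possible for oscillatory residuals) are
#' excluded; if none remain the -300 dB floor is returned.
#'
#' @param psd A `psd` tibble.
#' @param band_hz Two-element band, Hz.
#' @return Mean power in dB.
#' @export
band_power <- function(psd, band_hz) {
  sel <- psd$freq >= band_hz[1] - 1e-9 & psd$freq <= band_hz[2] + 1e-9
  if (!any(sel)) stop("band contains no frequency bins", call. = FALSE)
  pw <- psd$power[sel]
  pos <- pw > 0
  if (!any(pos)) return(DB_FLOOR)
  mean(10 * log10(pw[pos]))
}

#' Per-channel, per-stage spectral summary
#'
#' Computes the spectral block of the feature table: slow-delta power,
#' sigma power and peak sigma frequency from the oscillatory component
#' of the z-scored signal (N2 and N3 separately), and aperiodic slope
#' and intercept from the fractal component of the raw signal (N2, N3
#' and REM separately) - 12 measures per channel. Surviving segments of
#' each stage are concatenated before spectral estimation; a stage with
#' under 60 s of surviving data yields `NA` measures.
#'
#' @param rec An [eeg_recording()] (conditioned to 128 Hz).
#' @param h The matching [hypnogram()].
#' @param mask An epoch mask from [reject_artifacts()]; `NULL` keeps all
#'   epochs.
#' @param slow_delta_band_hz Slow-delta band (default `c(0.25, 1.5)`;
#'   the literature also uses an upper edge of 1.25 Hz).
#' @param sigma_band_hz Sigma band.
#' @param fit_range_hz Aperiodic fit range.
#' @return Tibble with columns `channel`, `stage`, `measure`, `value`.
#' @export
spectral_summary <- function(rec, h, mask = NULL,
                             slow_delta_band_hz = c(0.25, 1.5),
                             sigma_band_hz = c(10, 16),
                             fit_range_hz = c(1, 20)) {
  purrr::map_dfr(rec$channel_labels, function(ch) {
    rows <- list()
    for (stage in c("N2", "N3", "REM")) {
      segs <- stage_segments(rec, h, mask, ch, stages = stage)
      enough <- length(segs) && sum(lengths(segs)) >= 60 * rec$fs
      slope <- intercept <- NA_real_
      if (enough) {
        ir <- irasa(segs, rec$fs)
        fit <- fit_aperiodic(ir$fractal, fit_range_hz)
        slope <- fit$slope
        intercept <- fit$intercept
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        channel = ch, stage = stage,
        measure = c("aperiodic_slope", "aperiodic_intercept"),
        value = c(slope, intercept))
      if (stage %in% c("N2", "N3")) {
        sd_pw <- sg_pw <- pk <- NA_real_
        if (enough) {
          x <- unlist(segs)
          z <- (x - mean(x)) / stats::sd(x)
          irz <- irasa(z, rec$fs)
          sd_pw <- band_power(irz$oscillatory, slow_delta_band_hz)
          sg_pw <- band_power(irz$oscillatory, sigma_band_hz)
          pk <- peak_sigma_frequency(irz$oscillatory, sigma_band_hz)$peak_hz
        }
        rows[[length(rows) + 1L]] <- tibble::tibble(
          channel = ch, stage = stage,
          measure = c("slow_delta_power_db", "sigma_power_db",
                      "sigma_peak_hz"),
          value = c(sd_pw, sg_pw, pk))
      }
    }
    dplyr::bind_rows(rows)
  })
}
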