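#' Condition a recording: anti-aliased downsample and detrend
#'
#' Resamples every channel to 128 Hz (polyphase, anti-alias filtered)
#' and removes drift with a 0.25 Hz high-pass (second-order Butterworth
#' applied forward-backward, so zero-phase and >= 20 dB attenuation well
#' below the cutoff).
#'
#' @param rec An [eeg_recording()].
#' @param target_fs Output sampling rate, Hz (default 128).
#' @param highpass_hz Detrending high-pass cutoff, Hz.
#' @return A conditioned [eeg_recording()] at `target_fs`.
#' @export
condition_signal <- function(rec, target_fs = 128, highpass_hz = 0.25) {
  if (rec$fs < target_fs) {
    stop("sampling rate below ", target_fs, " Hz; cannot condition",
         call. = FALSE)
  }
  ratio <- target_fs / rec$fs
  g <- gcd(round(target_fs), round(rec$fs))
  p <- round(target_fs) / g
  q <- round(rec$fs) / g
  bf <- signal::butter(2, highpass_hz / (target_fs / 2), type = "high")
  out <- lapply(seq_len(nrow(rec$samples)), function(ch) {
    x <- rec$samples[ch, ]
    if (ratio < 1) x <- signal::resample(x, p, q)
    as.numeric(signal::filtfilt(bf, x))
  })
  n_min <- min(lengths(out))
  eeg_recording(do.call(rbind, lapply(out, function(v) v[seq_len(n_min)])),
                fs = target_fs, channel_labels = rec$channel_labels,
                subject_id = rec$subject_id, family_id = rec$family_id,
                group_label = rec$group_label)
}

#' Hjorth parameters of a signal epoch
#'
#' Activity (variance, uV^2), mobility (`sqrt(var(diff(x)) / var(x))`)
#' and complexity (mobility of the first difference divided by mobility
#' of the signal). Undefined for constant signals.
#'
#' @param x Numeric vector (>= 2 samples).
#' @return One-row tibble with `activity`, `mobility`, `complexity`.
#' @export
hjorth <- function(x) {
  stopifnot(length(x) >= 2)
  v0 <- stats::var(x)
  if (!is.finite(v0) || v0 == 0) {
    stop("Hjorth parameters undefined for a constant signal", call. = FALSE)
  }
  d1 <- diff(x)
  d2 <- diff(d1)
  v1 <- stats::var(d1)
  v2 <- stats::var(d2)
  mob <- sqrt(v1 / v0)
  tibble::tibble(activity = v0, mobility = mob,
                 complexity = sqrt(v2 / v1) / mob)
}

# Internal: start from a fully-kept mask over all (channel, epoch).
init_mask <- function(rec, h) {
  tidyr::expand_grid(channel = rec$channel_labels,
                     epoch = seq_along(h$stages)) |>
    dplyr::mutate(stage = h$stages[.data$epoch], keep = TRUE,
                  reason = "none")
}

# Mean linear band power of one epoch via a 4-s Hann Welch estimate.
epoch_band_powers <- function(x, fs, bands) {
  p <- welch_psd(x, fs, fmin = 0.25, fmax = 30)
  vapply(bands, function(b) {
    mean(p$power[p$freq >= b[1] - 1e-9 & p$freq <= b[2] + 1e-9])
  }, numeric(1))
}

#' Flanking band-power epoch rejection
#'
#' Rejects pooled N2/N3 epochs whose delta (1-4 Hz) band power exceeds
#' the mean + 2.5 SD, or whose beta (16-25 Hz) band power exceeds the
#' mean + 2 SD, of the flanking 14 epochs (up to 7 pooled N2/N3 epochs
#' on each side; fewer at the record edges). Band powers are compared on
#' the decibel (log) scale, the conventional unit for EEG band power,
#' which keeps the criterion calibrated under the strong right skew of
#' linear power. Epochs with fewer than 3 available flankers pass with a
#' warning.
#'
#' @param rec Conditioned [eeg_recording()].
#' @param h [hypnogram()].
#' @param mask Epoch mask tibble (default: all kept).
#' @param delta_band_hz,beta_band_hz Band edges, Hz.
#' @param delta_sd,beta_sd SD multipliers.
#' @return Updated mask tibble (columns `channel`, `epoch`, `stage`,
#'   `keep`, `reason`).
#' @export
flanking_band_rejection <- function(rec, h, mask = NULL,
                                    delta_band_hz = c(1, 4),
                                    beta_band_hz = c(16, 25),
                                    delta_sd = 2.5, beta_sd = 2) {
  mask <- mask %||% init_mask(rec, h)
  few_flankers <- FALSE
  for (ch in rec$channel_labels) {
    sel <- mask$channel == ch & mask$stage %in% c("N2", "N3") & mask$keep
    eps <- mask$epoch[sel]
    if (!length(eps)) next
    bp <- t(vapply(eps, function(e) {
      ix <- epoch_sample_range(e, h$epoch_len_s, rec$fs)
      ix <- ix[ix <= ncol(rec$samples)]
      log10(epoch_band_powers(rec$samples[ch, ix], rec$fs,
                              list(delta_band_hz, beta_band_hz)))
    }, numeric(2)))
    for (j in seq_along(eps)) {
      fl <- setdiff(max(1, j - 7):min(length(eps), j + 7), j)
      if (length(fl) < 3) { few_flankers <- TRUE; next }
      reason <- NULL
      md <- mean(bp[fl, 1]); sdd <- stats::sd(bp[fl, 1])
      mb <- mean(bp[fl, 2]); sdb <- stats::sd(bp[fl, 2])
      if (is.finite(sdd) && bp[j, 1] > md + delta_sd * sdd) {
        reason <- "flank_delta"
      } else if (is.finite(sdb) && bp[j, 2] > mb + beta_sd * sdb) {
        reason <- "flank_beta"
      }
      if (!is.null(reason)) {
        row <- mask$channel == ch & mask$epoch == eps[j]
        mask$keep[row] <- FALSE
        mask$reason[row] <- reason
      }
    }
  }
  if (few_flankers) {
    warning("some epochs had fewer than 3 flankers and were passed unchecked",
            call. = FALSE)
  }
  mask
}

#' Clipped-sample epoch rejection
#'
#' Rejects pooled N2/N3 epochs in which more than `max_fraction` of
#' samples equal the channel's global minimum or maximum value. A
#' constant (degenerate) channel, where every sample equals both
#' extremes, has all its epochs rejected with a warning.
#'
#' @inheritParams flanking_band_rejection
#' @param max_fraction Maximum tolerated clipped fraction (default 0.05).
#' @return Updated mask tibble.
#' @export
clipping_rejection <- function(rec, h, mask = NULL, max_fraction = 0.05) {
  mask <- mask %||% init_mask(rec, h)
  for (ch in rec$channel_labels) {
    x <- rec$samples[ch, ]
    lo <- min(x); hi <- max(x)
    if (lo == hi) {
      warning("degenerate constant channel '", ch,
              "': all epochs rejected as clipped", call. = FALSE)
    }
    sel <- which(mask$channel == ch & mask$stage %in% c("N2", "N3") &
                   mask$keep)
    for (i in sel) {
      ix <- epoch_sample_range(mask$epoch[i], h$epoch_len_s, rec$fs)
      ix <- ix[ix <= length(x)]
      frac <- mean(x[ix] == lo | x[ix] == hi)
      if (frac > max_fraction) {
        mask$keep[i] <- FALSE
        mask$reason[i] <- "clipping"
      }
    }
  }
  mask
}

#' Iterative RMS/Hjorth epoch rejection
#'
#' Three fixed cycles. In each cycle the RMS and the three Hjorth
#' parameters are computed for every surviving pooled N2/N3 epoch and
#' for the whole surviving signal (all surviving epochs concatenated);
#' an epoch is rejected when any of its metrics exceeds `threshold_mult`
#' times the corresponding whole-signal value. Later cycles recompute
#' the whole-signal reference from the reduced set, so removing a gross
#' outlier can expose a marginal epoch in the next cycle. Stops early
#' (with a message) if fewer than 5 epochs survive. The criterion is
#' one-sided: artifacts inflate these metrics.
#'
#' @inheritParams flanking_band_rejection
#' @param threshold_mult Rejection threshold as a multiple of the
#'   whole-signal metric (default 2).
#' @param n_cycles Number of cycles (default 3).
#' @return Updated mask tibble.
#' @export
iterative_rejection <- function(rec, h, mask = NULL, threshold_mult = 2,
                                n_cycles = 3) {
  mask <- mask %||% init_mask(rec, h)
  metrics <- function(x) {
    if (stats::var(x) == 0) return(c(sqrt(mean(x^2)), NA, NA, NA))
    hj <- hjorth(x)
    c(sqrt(mean(x^2)), hj$activity, hj$mobility, hj$complexity)
  }
  for (ch in rec$channel_labels) {
    for (cycle in seq_len(n_cycles)) {
      sel <- which(mask$channel == ch & mask$stage %in% c("N2", "N3") &
                     mask$keep)
      if (length(sel) < 5) {
        message("channel ", ch, ": fewer than 5 surviving epochs; ",
                "iterative rejection stopped at cycle ", cycle)
        break
      }
      met <- t(vapply(sel, function(i) {
        ix <- epoch_sample_range(mask$epoch[i], h$epoch_len_s, rec$fs)
        metrics(rec$samples[ch, ix[ix <= ncol(rec$samples)]])
      }, numeric(4)))
      whole <- metrics(rec$samples[ch, unlist(lapply(
        mask$epoch[sel], function(e) {
          ix <- epoch_sample_range(e, h$epoch_len_s, rec$fs)
          ix[ix <= ncol(rec$samples)]
        }))])
      ratio <- sweep(met, 2, whole, "/")
      bad_rms <- !is.na(ratio[, 1]) & ratio[, 1] > threshold_mult
      bad_hjorth <- rowSums(ratio[, 2:4, drop = FALSE] > threshold_mult,
                            na.rm = TRUE) > 0
      bad <- which(bad_rms | bad_hjorth)
      if (!length(bad)) break
      mask$keep[sel[bad]] <- FALSE
      mask$reason[sel[bad]] <- ifelse(bad_rms[bad], "iter_rms", "iter_hjorth")
    }
  }
  mask
}

#' Run the full epoch-level artifact rejection chain
#'
#' Applies, in order, the flanking band-power criterion, the
#' clipped-sample criterion and the iterative RMS/Hjorth criterion to
#' the pooled N2+N3 epochs of every channel independently. Each rejected
#' epoch carries the first criterion that fired.
#'
#' @inheritParams flanking_band_rejection
#' @return Mask tibble with columns `channel`, `epoch`, `stage`, `keep`,
#'   `reason` (one row per channel x epoch).
#' @export
reject_artifacts <- function(rec, h) {
  mask <- init_mask(rec, h)
  mask <- flanking_band_rejection(rec, h, mask)
  mask <- clipping_rejection(rec, h, mask)
  iterative_rejection(rec, h, mask)
}

#' Sample indices of surviving epochs
#'
#' @param rec An [eeg_recording()].
#' @param h [hypnogram()].
#' @param mask Epoch mask (or `NULL` for all kept).
#' @param stages Stages to include (default pooled N2+N3).
#' @return Named list (per channel) of integer sample index vectors.
#' @export
apply_mask <- function(rec, h, mask = NULL, stages = c("N2", "N3")) {
  mask <- mask %||% init_mask(rec, h)
  out <- lapply(rec$channel_labels, function(ch) {
    eps <- mask$epoch[mask$channel == ch & mask$keep &
                        mask$stage %in% stages]
    if (!length(eps)) return(integer(0))
    ix <- unlist(lapply(sort(eps), epoch_sample_range,
                        epoch_len_s = h$epoch_len_s, fs = rec$fs))
    ix[ix <= ncol(rec$samples)]
  })
  names(out) <- rec$channel_labels
  out
}

#' Contiguous surviving segments of one channel
#'
#' Groups the surviving epochs of the requested stages into maximal
#' contiguous runs and returns each run's samples together with its
#' starting sample index, so detected event times can be mapped back to
#' record time.
#'
#' @inheritParams apply_mask
#' @param channel Channel label.
#' @return List of `list(x = samples, start = first sample index)`.
#' @export
surviving_segments <- function(rec, h, mask = NULL, channel,
                               stages = c("N2", "N3")) {
  mask <- mask %||% init_mask(rec, h)
  eps <- sort(mask$epoch[mask$channel == channel & mask$keep &
                           mask$stage %in% stages])
  if (!length(eps)) return(list())
  grp <- cumsum(c(1, diff(eps) != 1))
  lapply(split(eps, grp), function(run) {
    ix <- unlist(lapply(run, epoch_sample_range,
                        epoch_len_s = h$epoch_len_s, fs = rec$fs))
    ix <- ix[ix <= ncol(rec$samples)]
    list(x = as.numeric(rec$samples[channel, ix]), start = ix[1])
  })
}

# Segment samples only (used by spectral summaries).
stage_segments <- function(rec, h, mask, channel, stages) {
  lapply(surviving_segments(rec, h, mask, channel, stages), `[[`, "x")
}
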