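#' Run the full sleep-EEG analysis pipeline
#'
#' Chains every stage: optional conditioning (downsample to 128 Hz,
#' 0.25 Hz detrend), epoch-level artifact rejection, spectral summary
#' (Welch + IRASA + aperiodic fits), individualized spindle and
#' slow-wave detection, and spindle-SW coupling with shuffle nulls; then
#' assembles the long-format per-channel feature table (21 measures per
#' channel: 12 spectral, 3 spindle, 3 slow-wave, 3 coupling).
#'
#' @param rec An [eeg_recording()].
#' @param h The matching [hypnogram()].
#' @param condition Run [condition_signal()] first (default `TRUE`;
#'   skip when the recording is already at 128 Hz and detrended).
#' @param cfg Base [detector_config()].
#' @param n_shuffles Shuffles for the coupling nulls.
#' @param seed Integer seed for the shuffle nulls.
#' @return Object of class `nrem_pipeline`: list with `recording`,
#'   `hypnogram`, `mask`, `architecture`, `spectral`, `events`,
#'   `coupling` and `feature_table`.
#' @export
run_pipeline <- function(rec, h, condition = TRUE, cfg = detector_config(),
                         n_shuffles = 1000, seed = 1L) {
  if (condition) rec <- condition_signal(rec)
  mask <- reject_artifacts(rec, h)
  arch <- sleep_architecture(h)
  spect <- spectral_summary(rec, h, mask)
  ev <- detect_events(rec, h, mask, cfg)
  coup <- coupling_summary(rec, h, mask, ev, n_shuffles = n_shuffles,
                           seed = seed)

  rows <- list(dplyr::mutate(spect, subject_id = rec$subject_id))
  for (ch in rec$channel_labels) {
    kept_min <- sum(mask$keep[mask$channel == ch &
                                mask$stage %in% c("N2", "N3")]) *
      h$epoch_len_s / 60
    sp <- dplyr::filter(ev$spindles, .data$channel == ch)
    sw <- dplyr::filter(ev$slow_waves, .data$channel == ch)
    cs <- dplyr::filter(coup, .data$channel == ch)
    dens <- function(tbl) if (kept_min > 0) event_density(tbl, kept_min)
                          else NA_real_
    rows[[length(rows) + 1L]] <- tibble::tibble(
      subject_id = rec$subject_id, channel = ch, stage = "N2+N3",
      measure = c("spindle_density", "spindle_amplitude",
                  "spindle_frequency", "sw_density", "sw_amplitude",
                  "sw_duration", "sp_sw_overlap_z", "sp_sw_mrl_z",
                  "sp_sw_mean_angle"),
      value = c(dens(sp),
                if (nrow(sp)) mean(sp$amplitude_uV) else NA_real_,
                if (nrow(sp)) mean(sp$frequency_hz, na.rm = TRUE)
                else NA_real_,
                dens(sw),
                if (nrow(sw)) mean(sw$amplitude_uV) else NA_real_,
                if (nrow(sw)) mean(sw$duration_s) else NA_real_,
                cs$overlap_z, cs$mrl_z, cs$mean_angle_deg))
  }
  features <- dplyr::bind_rows(rows) |>
    dplyr::select("subject_id", "channel", "stage", "measure", "value") |>
    dplyr::arrange(.data$subject_id, .data$channel, .data$stage,
                   .data$measure)

  structure(list(recording = rec, hypnogram = h, mask = mask,
                 architecture = arch, spectral = spect, events = ev,
                 coupling = coup, feature_table = features),
            class = "nrem_pipeline")
}

#' @export
print.nrem_pipeline <- function(x, ...) {
  cat("<nrem_pipeline>\n")
  cat(sprintf("  %d channel(s); %d/%d N2+N3 epochs kept\n",
              length(x$recording$channel_labels),
              sum(x$mask$keep & x$mask$stage %in% c("N2", "N3")),
              sum(x$mask$stage %in% c("N2", "N3"))))
  cat(sprintf("  %d spindles, %d slow waves detected\n",
              nrow(x$events$spindles), nrow(x$events$slow_waves)))
  cat(sprintf("  feature table: %d rows\n", nrow(x$feature_table)))
  invisible(x)
}
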