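#' Construct an EEG recording object
#'
#' A recording bundles a channels-by-samples voltage matrix (in microvolts)
#' with its sampling rate, channel labels and subject metadata. All
#' downstream stages (artifact rejection, spectral analysis, event
#' detection, coupling) operate on this container.
#'
#' @param samples Numeric matrix of voltages in uV, one row per channel.
#'   A plain numeric vector is treated as a single channel.
#' @param fs Sampling rate in Hz (> 0).
#' @param channel_labels Character vector of unique channel names; defaults
#'   to `"ch1"`, `"ch2"`, ...
#' @param subject_id,family_id,group_label Subject metadata strings;
#'   `group_label` is typically `"case"` or `"control"`.
#'
#' @return An object of class `eeg_recording`: a list with elements
#'   `samples`, `fs`, `channel_labels`, `subject_id`, `family_id`,
#'   `group_label`.
#' @export
#' @examples
#' rec <- eeg_recording(matrix(rnorm(256), nrow = 2), fs = 128)
#' rec
eeg_recording <- function(samples, fs, channel_labels = NULL,
                          subject_id = "s1", family_id = subject_id,
                          group_label = "control") {
  if (is.vector(samples)) samples <- matrix(samples, nrow = 1)
  stopifnot(is.matrix(samples), is.numeric(samples))
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("`fs` must be a single positive sampling rate in Hz", call. = FALSE)
  }
  if (is.null(channel_labels)) {
    channel_labels <- paste0("ch", seq_len(nrow(samples)))
  }
  if (length(channel_labels) != nrow(samples)) {
    stop("`channel_labels` must have one entry per row of `samples`",
         call. = FALSE)
  }
  if (anyDuplicated(channel_labels)) {
    stop("channel labels must be unique", call. = FALSE)
  }
  rownames(samples) <- channel_labels
  structure(
    list(samples = samples, fs = fs,
         channel_labels = as.character(channel_labels),
         subject_id = subject_id, family_id = family_id,
         group_label = group_label),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  dur <- ncol(x$samples) / x$fs
  cat(sprintf("<eeg_recording> subject %s (%s), %d channel(s) @ %g Hz, %.1f s\n",
              x$subject_id, x$group_label, nrow(x$samples), x$fs, dur))
  cat("  channels:", paste(utils::head(x$channel_labels, 8), collapse = ", "),
      if (length(x$channel_labels) > 8) "..." else "", "\n")
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec An `eeg_recording`.
#' @return Duration in seconds.
#' @export
recording_duration <- function(rec) ncol(rec$samples) / rec$fs

#' Extract one channel as a numeric vector
#' @param rec An `eeg_recording`.
#' @param channel Channel label or index.
#' @return Numeric vector of samples in uV.
#' @export
channel_samples <- function(rec, channel) {
  if (is.character(channel) && !channel %in% rec$channel_labels) {
    stop("unknown channel: ", channel, call. = FALSE)
  }
  as.numeric(rec$samples[channel, ])
}

# Valid sleep stage vocabulary, in display order.
STAGE_LEVELS <- c("W", "N1", "N2", "N3", "REM", "ART")
SLEEP_STAGES <- c("N1", "N2", "N3", "REM")

#' Construct a hypnogram
#'
#' A hypnogram is the ordered sequence of sleep stages scored in fixed
#' epochs (30 s by convention). Stages are `W`, `N1`, `N2`, `N3`, `REM`
#' and `ART` (artifact).
#'
#' @param stages Character vector of stage labels.
#' @param epoch_len_s Epoch length in seconds (default 30).
#' @return An object of class `hypnogram`.
#' @export
hypnogram <- function(stages, epoch_len_s = 30) {
  stages <- toupper(as.character(stages))
  stages[stages == "R"] <- "REM"
  bad <- which(!stages %in% STAGE_LEVELS)
  if (length(bad)) {
    stop(sprintf("unknown stage token '%s' at position %d", stages[bad[1]],
                 bad[1]), call. = FALSE)
  }
  if (!length(stages)) stop("hypnogram must be non-empty", call. = FALSE)
  stopifnot(epoch_len_s > 0)
  structure(list(stages = stages, epoch_len_s = epoch_len_s),
            class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  cat(sprintf("<hypnogram> %d x %g s epochs (%.1f min)\n",
              length(x$stages), x$epoch_len_s,
              length(x$stages) * x$epoch_len_s / 60))
  print(table(factor(x$stages, levels = STAGE_LEVELS)))
  invisible(x)
}

#' @export
length.hypnogram <- function(x) length(x$stages)

#' Read a hypnogram from a text or CSV file
#'
#' Accepts either one stage token per line, or a CSV with a `stage`
#' column. Tokens are case-folded; unknown tokens raise an error that
#' names the offending line.
#'
#' @param path Path to the file.
#' @param epoch_len_s Epoch length in seconds (default 30).
#' @return A [hypnogram()].
#' @export
read_hypnogram <- function(path, epoch_len_s = 30) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty hypnogram file: ", path, call. = FALSE)
  offset <- 0L
  if (grepl(",", lines[1]) || tolower(trimws(lines[1])) == "stage") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!"stage" %in% names(df)) {
      stop("CSV hypnogram must have a 'stage' column", call. = FALSE)
    }
    tokens <- df$stage
    offset <- 1L
  } else {
    tokens <- trimws(lines)
  }
  up <- toupper(tokens)
  up[up == "R"] <- "REM"
  bad <- which(!up %in% STAGE_LEVELS)
  if (length(bad)) {
    stop(sprintf("unknown stage token '%s' at line %d of %s",
                 tokens[bad[1]], bad[1] + offset, path), call. = FALSE)
  }
  hypnogram(up, epoch_len_s)
}

#' Write a hypnogram to a CSV file
#' @param h A [hypnogram()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hypnogram <- function(h, path) {
  utils::write.csv(data.frame(epoch = seq_along(h$stages), stage = h$stages),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Sleep architecture summary from a hypnogram
#'
#' Computes the conventional polysomnography architecture variables:
#' total sleep time (TST), sleep efficiency, latencies to N1 and REM,
#' stage percentages of total sleep, and the number of awakenings.
#'
#' Conventions: N1 latency is measured from the start of the recording;
#' REM latency from the first sleep epoch (sleep-onset referenced).
#' Sleep efficiency uses the full hypnogram duration as denominator
#' (time-in-bed proxy). `ART` epochs count toward total time but never
#' toward sleep. An awakening is a contiguous bout of `W` epochs strictly
#' between the first and last sleep epoch.
#'
#' @param h A [hypnogram()].
#' @return A one-row tibble with columns `tst_min`, `se_pct`,
#'   `n1_latency_min`, `rem_latency_min`, `pct_n1`, `pct_n2`, `pct_n3`,
#'   `pct_rem`, `awakenings_n`. Undefined quantities (no sleep, no
#'   N1/REM) are `NA`.
#' @export
#' @examples
#' sleep_architecture(hypnogram(c("W", "W", "N1", "N2", "REM", "W", "N2")))
sleep_architecture <- function(h) {
  stopifnot(inherits(h, "hypnogram"))
  st <- h$stages
  ep_min <- h$epoch_len_s / 60
  is_sleep <- st %in% SLEEP_STAGES
  n_sleep <- sum(is_sleep)
  tst_min <- n_sleep * ep_min
  total_min <- length(st) * ep_min
  se_pct <- if (n_sleep > 0) 100 * tst_min / total_min else 0

  first_n1 <- match("N1", st)
  n1_latency <- if (is.na(first_n1)) NA_real_ else (first_n1 - 1) * ep_min
  first_sleep <- if (n_sleep > 0) which(is_sleep)[1] else NA_integer_
  first_rem <- match("REM", st)
  rem_latency <- if (is.na(first_rem) || is.na(first_sleep)) NA_real_
                 else (first_rem - first_sleep) * ep_min

  pct <- function(stage) {
    if (n_sleep == 0) return(NA_real_)
    100 * sum(st == stage) / n_sleep
  }

  awakenings <- 0L
  if (n_sleep > 0) {
    last_sleep <- max(which(is_sleep))
    if (last_sleep - first_sleep >= 2) {
      inner <- st[(first_sleep + 1):(last_sleep - 1)]
      r <- rle(inner == "W")
      awakenings <- sum(r$values)
    }
  }

  tibble::tibble(
    tst_min = tst_min, se_pct = se_pct,
    n1_latency_min = n1_latency, rem_latency_min = rem_latency,
    pct_n1 = pct("N1"), pct_n2 = pct("N2"),
    pct_n3 = pct("N3"), pct_rem = pct("REM"),
    awakenings_n = awakenings
  )
}

#' Sample indices covered by a given epoch
#' @param epoch Epoch index (1-based).
#' @param epoch_len_s Epoch length in seconds.
#' @param fs Sampling rate in Hz.
#' @return Integer vector of sample indices.
#' @keywords internal
epoch_sample_range <- function(epoch, epoch_len_s, fs) {
  n <- round(epoch_len_s * fs)
  ((epoch - 1L) * n + 1L):(epoch * n)
}

#' Write the long-format feature table to CSV
#'
#' The feature table holds the per-subject, per-channel derived EEG
#' measures (spectral, spindle, slow-wave and coupling blocks) in long
#' format. Rows are validated for key uniqueness and written in a
#' deterministic order (subject, channel, stage, measure).
#'
#' @param features Data frame with columns `subject_id`, `channel`,
#'   `stage`, `measure`, `value`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  req <- c("subject_id", "channel", "stage", "measure", "value")
  missing_cols <- setdiff(req, names(features))
  if (length(missing_cols)) {
    stop("feature table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  key <- do.call(paste, c(features[c("subject_id", "channel", "stage",
                                     "measure")], sep = "|"))
  if (anyDuplicated(key)) {
    stop("duplicate feature table key(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
  }
  out <- features[order(features$subject_id, features$channel,
                        features$stage, features$measure), req]
  # full double precision so reruns can be compared byte-for-byte
  out$value <- vapply(out$value, function(v) {
    if (is.na(v)) "NA" else sprintf("%.17g", v)
  }, character(1))
  utils::write.table(out, path, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
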