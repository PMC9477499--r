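# Minimal European Data Format (EDF, 16-bit) reader/writer.
# Supports the plain-EDF subset used for sleep EEG exports: a single
# sampling rate across the analyzed channels, one-second data records,
# little-endian int16 samples mapped linearly between the digital and
# physical (uV) ranges declared in the header.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording to an EDF file
#'
#' Samples are quantized to 16-bit integers over a symmetric physical
#' range covering the recording's extremes. Data records are one second
#' long; if the recording does not contain a whole number of seconds the
#' final partial second is zero-padded.
#'
#' @param rec An [eeg_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  ns <- nrow(rec$samples)
  spr <- as.integer(round(rec$fs))        # samples per 1-s record
  if (abs(spr - rec$fs) > 1e-9) {
    stop("write_edf requires an integer sampling rate", call. = FALSE)
  }
  n_rec <- as.integer(ceiling(ncol(rec$samples) / spr))

  phys_max <- max(1e-6, max(abs(rec$samples), na.rm = TRUE))
  dig_max <- 32767L
  dig_min <- -32767L        # symmetric, so phys = dig * phys_max / dig_max
  scale <- phys_max / dig_max

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad(rec$subject_id, 80),
    edf_pad(paste("Startdate 01-JAN-2000", rec$group_label), 80),
    "01.01.00", "00.00.00",
    edf_pad(256 + 256 * ns, 8),
    edf_pad("", 44),
    edf_pad(n_rec, 8),
    edf_pad(1, 8),
    edf_pad(ns, 4)
  )
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, width) {
    writeChar(paste(vapply(vals, edf_pad, "", width = width), collapse = ""),
              con, eos = NULL)
  }
  field(rec$channel_labels, 16)
  field(rep("", ns), 80)                       # transducer
  field(rep("uV", ns), 8)                      # physical dimension
  field(rep(sprintf("%.7g", -phys_max), ns), 8)
  field(rep(sprintf("%.7g", phys_max), ns), 8)
  field(rep(dig_min, ns), 8)
  field(rep(dig_max, ns), 8)
  field(rep("", ns), 80)                       # prefiltering
  field(rep(spr, ns), 8)
  field(rep("", ns), 32)                       # reserved

  padded <- matrix(0, nrow = ns, ncol = n_rec * spr)
  padded[, seq_len(ncol(rec$samples))] <- rec$samples
  dig <- round(padded / scale)
  dig[dig > dig_max] <- dig_max
  dig[dig < dig_min] <- dig_min
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * spr + 1L):(r * spr)
    block <- as.integer(t(dig[, cols, drop = FALSE]))
    writeBin(block, con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file into a recording
#'
#' Reads a plain 16-bit EDF file. All channels must share one sampling
#' rate (a mismatch raises an error naming the offending channel).
#' Voltages are returned in uV via the header's physical/digital mapping.
#'
#' @param path Path to the EDF file.
#' @param subject_id Optional subject id override; defaults to the EDF
#'   patient field.
#' @return An [eeg_recording()].
#' @export
read_edf <- function(path, subject_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 256) {
    stop("malformed EDF header (file too short): ", path, call. = FALSE)
  }
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  version <- rd(8)
  if (version != "0") stop("malformed EDF header (version field)", call. = FALSE)
  patient <- rd(80)
  rd(80); rd(8); rd(8)
  header_bytes <- suppressWarnings(as.integer(rd(8)))
  rd(44)
  n_rec <- suppressWarnings(as.integer(rd(8)))
  rec_dur <- suppressWarnings(as.numeric(rd(8)))
  ns <- suppressWarnings(as.integer(rd(4)))
  if (anyNA(c(header_bytes, n_rec, rec_dur, ns)) || ns < 1) {
    stop("malformed EDF header (numeric fields)", call. = FALSE)
  }
  rdv <- function(width) vapply(seq_len(ns), function(i) rd(width), "")
  labels <- rdv(16)
  rdv(80); rdv(8)
  phys_min <- as.numeric(rdv(8))
  phys_max <- as.numeric(rdv(8))
  dig_min <- as.numeric(rdv(8))
  dig_max <- as.numeric(rdv(8))
  rdv(80)
  spr <- as.integer(rdv(8))
  rdv(32)
  if (length(unique(spr)) != 1L) {
    bad <- labels[which(spr != spr[1])[1]]
    stop("unsupported EDF: channel '", bad,
         "' has a different sampling rate", call. = FALSE)
  }
  fs <- spr[1] / rec_dur

  n_total <- n_rec * ns * spr[1]
  raw <- readBin(con, integer(), n = n_total, size = 2L, signed = TRUE,
                 endian = "little")
  if (length(raw) < n_total) {
    stop("malformed EDF: truncated data section", call. = FALSE)
  }
  samples <- matrix(0, nrow = ns, ncol = n_rec * spr[1])
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  idx <- 0L
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      block <- raw[(idx + 1L):(idx + spr[1])]
      cols <- ((r - 1L) * spr[1] + 1L):(r * spr[1])
      samples[ch, cols] <- (block - dig_min[ch]) * gain[ch] + phys_min[ch]
      idx <- idx + spr[1]
    }
  }
  eeg_recording(samples, fs = fs, channel_labels = labels,
                subject_id = subject_id %||% patient)
}
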