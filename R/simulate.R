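#' Simulation parameters for synthetic sleep EEG
#'
#' Bundles every knob of the synthetic polysomnography generator: the
#' aperiodic (1/f) background, slow-wave (SW) and spindle event trains,
#' and the von Mises spindle-to-SW phase coupling. Defaults describe a
#' plausible low-noise overnight montage fragment: a 1/f background of
#' exponent 1.5 at 5 uV RMS, 8 SW negative half-waves per minute with
#' log-normal amplitudes around 100 uV, 2 spindles per minute at 13 Hz
#' with 15 uV envelope peak, and half of the spindles coupled to a SW at
#' a preferred phase of 30 degrees (concentration 3).
#'
#' @param fs Sampling rate in Hz.
#' @param duration_s Recording duration in seconds (>= 60).
#' @param n_channels Number of independent channels.
#' @param aperiodic_slope_true Spectral exponent beta of the background
#'   (power ~ f^-beta).
#' @param background_rms_uV Background RMS amplitude in uV.
#' @param sw_density_per_min SW events per analyzed (N2+N3) minute.
#' @param sw_amp_mean_uV,sw_amp_sd_uV Mean/SD of the log-normal SW trough
#'   amplitude distribution, uV.
#' @param sw_dur_lo_s,sw_dur_hi_s SW duration range (uniform), seconds;
#'   must lie in \[0.5, 2\].
#' @param sp_density_per_min Spindles per analyzed minute.
#' @param sp_freq_hz Spindle carrier frequency, Hz in \[10, 16\].
#' @param sp_amp_uV Spindle envelope peak amplitude, uV.
#' @param sp_dur_lo_s,sp_dur_hi_s Spindle duration range (uniform),
#'   seconds; must lie in \[0.5, 3\].
#' @param p_coupled Fraction of spindles phase-locked to a SW.
#' @param sp_avoid_sw Placement of uncoupled spindles: `TRUE` (default)
#'   keeps their peaks more than 1.5 s from every SW trough; `FALSE`
#'   places them uniformly in N2/N3 time regardless of SWs (the
#'   appropriate null for calibrating overlap shuffle z-scores).
#' @param mu_deg Preferred SW phase of coupled spindle peaks, degrees
#'   (0 = descending zero crossing, 90 = trough).
#' @param kappa von Mises concentration (>= 0; 0 = uniform).
#' @param stage_sequence Optional [hypnogram()] to emulate; default is a
#'   simple sleep-cycle pattern from [default_hypnogram()].
#' @param seed Integer seed; the generator is deterministic given it.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(fs = 128, duration_s = 600, n_channels = 1,
                       aperiodic_slope_true = 1.5, background_rms_uV = 5,
                       sw_density_per_min = 8, sw_amp_mean_uV = 100,
                       sw_amp_sd_uV = 30, sw_dur_lo_s = 0.8,
                       sw_dur_hi_s = 1.5, sp_density_per_min = 2,
                       sp_freq_hz = 13, sp_amp_uV = 15, sp_dur_lo_s = 0.8,
                       sp_dur_hi_s = 1.5, p_coupled = 0.5, sp_avoid_sw = TRUE,
                       mu_deg = 30, kappa = 3, stage_sequence = NULL,
                       seed = 1L) {
  p <- as.list(environment())
  stopifnot(p$fs > 0, p$duration_s >= 60, p$n_channels >= 1,
            p$sw_density_per_min >= 0, p$sp_density_per_min >= 0,
            p$p_coupled >= 0, p$p_coupled <= 1, p$kappa >= 0,
            p$sw_dur_lo_s >= 0.5, p$sw_dur_hi_s <= 2,
            p$sw_dur_lo_s <= p$sw_dur_hi_s,
            p$sp_dur_lo_s >= 0.5, p$sp_dur_hi_s <= 3,
            p$sp_dur_lo_s <= p$sp_dur_hi_s,
            p$sp_freq_hz >= 10, p$sp_freq_hz <= 16)
  class(p) <- "sim_params"
  p
}

#' Default hypnogram for simulations
#'
#' Emulates a condensed sleep cycle: two epochs of wake and one of N1,
#' then repeating blocks of N2, N3, N2 and REM until the requested
#' duration is filled.
#'
#' @param duration_s Total duration in seconds.
#' @param epoch_len_s Epoch length (default 30 s).
#' @return A [hypnogram()].
#' @export
default_hypnogram <- function(duration_s, epoch_len_s = 30) {
  n <- floor(duration_s / epoch_len_s)
  cycle <- c(rep("N2", 8), rep("N3", 6), rep("N2", 3), rep("REM", 3))
  stages <- c("W", "W", "N1", rep(cycle, ceiling(n / length(cycle))))
  hypnogram(stages[seq_len(n)], epoch_len_s)
}

#' 1/f (power-law) background noise
#'
#' Spectrally shapes white Gaussian noise so its power spectrum follows
#' f^-beta, by scaling FFT amplitudes to f^(-beta/2). Below
#' `floor_hz` the shaping is held flat to avoid unbounded drifts.
#'
#' @param n Number of samples.
#' @param fs Sampling rate, Hz.
#' @param beta Spectral exponent (power ~ f^-beta).
#' @param rms_uV Target RMS amplitude, uV.
#' @param floor_hz Frequency below which shaping saturates.
#' @return Numeric vector of length `n`.
#' @export
colored_noise <- function(n, fs, beta, rms_uV, floor_hz = 0.25) {
  w <- stats::rnorm(n)
  X <- stats::fft(w)
  f <- c(0, seq_len(n - 1)) * fs / n
  f <- pmin(f, fs - f)                       # two-sided frequency axis
  shape <- pmax(f, floor_hz)^(-beta / 2)
  shape[1] <- 0                              # remove DC
  x <- Re(stats::fft(X * shape, inverse = TRUE)) / n
  x * rms_uV / stats::sd(x)
}

#' Slow-wave kernel: a single negative half-sine
#'
#' @param amp_uV Trough depth in uV (> 0; the kernel minimum is `-amp_uV`).
#' @param dur_s Duration in seconds, within \[0.5, 2\].
#' @param fs Sampling rate, Hz.
#' @return Numeric waveform starting and ending at 0 uV.
#' @export
#' @examples
#' k <- make_sw_kernel(150, 1, 128)
#' min(k) # -150
make_sw_kernel <- function(amp_uV, dur_s, fs) {
  if (dur_s < 0.5 || dur_s > 2) {
    stop("SW duration must lie in [0.5, 2] s", call. = FALSE)
  }
  stopifnot(amp_uV > 0)
  n <- round(dur_s * fs)
  t <- seq(0, dur_s, length.out = n + 1)
  -amp_uV * sin(pi * t / dur_s)
}

#' Spindle kernel: sinusoid under a Hann envelope
#'
#' @param freq_hz Carrier frequency in Hz, within \[10, 16\].
#' @param dur_s Duration in seconds, within \[0.5, 3\].
#' @param amp_uV Envelope peak amplitude in uV (max peak-to-trough is
#'   about `2 * amp_uV`).
#' @param fs Sampling rate, Hz.
#' @return Numeric waveform of `round(dur_s * fs)` samples.
#' @export
make_spindle_kernel <- function(freq_hz, dur_s, amp_uV, fs) {
  if (freq_hz < 10 || freq_hz > 16) {
    stop("spindle frequency must lie in [10, 16] Hz", call. = FALSE)
  }
  if (dur_s < 0.5 || dur_s > 3) {
    stop("spindle duration must lie in [0.5, 3] s", call. = FALSE)
  }
  n <- round(dur_s * fs)
  t <- (seq_len(n) - 1) / fs
  env <- 0.5 - 0.5 * cos(2 * pi * t / (dur_s - 1 / fs))
  amp_uV * env * sin(2 * pi * freq_hz * t)
}

#' Draw phases from a von Mises distribution
#'
#' Best-Fisher rejection sampler. `kappa = 0` gives the circular uniform
#' distribution.
#'
#' @param n Number of draws.
#' @param mu_deg Mean direction, degrees.
#' @param kappa Concentration parameter (>= 0).
#' @return Angles in degrees, in \[0, 360).
#' @export
draw_coupling_phase <- function(n, mu_deg, kappa) {
  if (kappa < 0) stop("kappa must be >= 0", call. = FALSE)
  if (kappa == 0) return(stats::runif(n, 0, 360))
  mu <- mu_deg * pi / 180
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    if (c_ * (2 - c_) - u[2] > 0 || log(c_ / u[2]) + 1 - c_ >= 0) {
      theta <- mu + sign(u[3] - 0.5) * acos(f)
      out[i] <- theta
      i <- i + 1L
    }
  }
  (out * 180 / pi) %% 360
}

# Sample k event-center times (in samples) uniformly over the eligible
# positions, enforcing a minimum center-to-center gap. Eligible positions
# are given per contiguous block as (lo, hi) sample bounds.
place_events <- function(k, blocks, min_gap_samp, max_tries = 200L) {
  accepted <- numeric(0)
  lens <- blocks$hi - blocks$lo
  lens[lens < 0] <- 0
  if (k == 0 || sum(lens) <= 0) return(accepted)
  tries <- 0L
  while (length(accepted) < k && tries < max_tries * k) {
    b <- sample.int(nrow(blocks), 1, prob = pmax(lens, 1e-9))
    cand <- stats::runif(1, blocks$lo[b], blocks$hi[b])
    if (!length(accepted) || min(abs(accepted - cand)) >= min_gap_samp) {
      accepted <- c(accepted, cand)
    }
    tries <- tries + 1L
  }
  sort(accepted)
}

#' Simulate a multichannel sleep EEG recording with ground truth
#'
#' Generates, per channel independently: a 1/f background, slow-wave
#' negative half-waves and sigma-band spindle bursts superposed on it in
#' N2/N3 epochs only, with a configurable fraction of spindles
#' phase-locked to a host SW at von Mises-distributed phases. Event
#' trains are Poisson with a 1-s minimum spacing between same-type
#' events. Coupled spindle peaks are placed at the sample inside the
#' host SW's +/-1.5 s window whose instantaneous SW phase (package phase
#' convention, see [sw_phase_series()]) is closest to the drawn angle.
#'
#' @param p A [sim_params()] object.
#' @return A list with elements `recording` ([eeg_recording()]),
#'   `hypnogram` ([hypnogram()]) and `truth` (list of tibbles
#'   `sw_events` and `sp_events`).
#' @export
simulate_recording <- function(p) {
  stopifnot(inherits(p, "sim_params"))
  feasible <- 60 / (p$sw_dur_hi_s + 1)
  if (p$sw_density_per_min > feasible) {
    stop(sprintf("SW density %.1f/min infeasible under 1-s gap; max ~%.1f/min",
                 p$sw_density_per_min, feasible), call. = FALSE)
  }
  if (p$sp_density_per_min > 60 / (p$sp_dur_hi_s + 1)) {
    stop(sprintf("spindle density %.1f/min infeasible under 1-s gap; max ~%.1f/min",
                 p$sp_density_per_min, 60 / (p$sp_dur_hi_s + 1)), call. = FALSE)
  }
  if (!is.null(p$seed)) set.seed(p$seed)
  h <- p$stage_sequence %||% default_hypnogram(p$duration_s)
  fs <- p$fs
  n <- round(p$duration_s * fs)
  ep_n <- round(h$epoch_len_s * fs)

  nrem <- which(h$stages %in% c("N2", "N3"))
  # contiguous N2/N3 blocks in sample coordinates
  blocks <- if (length(nrem)) {
    grp <- cumsum(c(1, diff(nrem) != 1))
    do.call(rbind, lapply(split(nrem, grp), function(e) {
      data.frame(lo = (min(e) - 1) * ep_n + 1, hi = min(max(e) * ep_n, n))
    }))
  } else data.frame(lo = numeric(0), hi = numeric(0))
  nrem_min <- length(nrem) * h$epoch_len_s / 60

  samples <- matrix(0, nrow = p$n_channels, ncol = n)
  sw_all <- list()
  sp_all <- list()
  for (ch in seq_len(p$n_channels)) {
    lab <- paste0("ch", ch)
    bg <- colored_noise(n, fs, p$aperiodic_slope_true, p$background_rms_uV)
    x <- bg

    ## --- slow waves ---------------------------------------------------
    n_sw <- stats::rpois(1, p$sw_density_per_min * nrem_min)
    sw_dur <- stats::runif(n_sw, p$sw_dur_lo_s, p$sw_dur_hi_s)
    # log-normal amplitudes moment-matched to (mean, sd)
    s2 <- log(1 + (p$sw_amp_sd_uV / p$sw_amp_mean_uV)^2)
    sw_amp <- stats::rlnorm(n_sw, log(p$sw_amp_mean_uV) - s2 / 2, sqrt(s2))
    margin <- ceiling(max(p$sw_dur_hi_s / 2, 0.1) * fs)
    bl <- data.frame(lo = blocks$lo + margin, hi = blocks$hi - margin)
    ctr <- place_events(n_sw, bl, min_gap_samp = (p$sw_dur_hi_s + 1) * fs)
    n_sw <- length(ctr)
    sw_tab <- tibble::tibble(channel = lab,
                             start_s = numeric(n_sw), trough_s = numeric(n_sw),
                             end_s = numeric(n_sw), amp_uV = numeric(n_sw))
    sw_sig <- numeric(n)
    for (i in seq_len(n_sw)) {
      kern <- make_sw_kernel(sw_amp[i], sw_dur[i], fs)
      st <- round(ctr[i] - length(kern) / 2)
      ix <- st:(st + length(kern) - 1)
      ok <- ix >= 1 & ix <= n
      sw_sig[ix[ok]] <- sw_sig[ix[ok]] + kern[ok]
      sw_tab$start_s[i] <- (st - 1) / fs
      sw_tab$trough_s[i] <- (st - 1 + (which.min(kern) - 1)) / fs
      sw_tab$end_s[i] <- (st - 1 + length(kern) - 1) / fs
      sw_tab$amp_uV[i] <- sw_amp[i]
    }
    x <- x + sw_sig

    ## --- spindles -----------------------------------------------------
    n_sp <- stats::rpois(1, p$sp_density_per_min * nrem_min)
    coupled <- stats::runif(n_sp) < p$p_coupled
    if (n_sw == 0) coupled[] <- FALSE
    sp_dur <- stats::runif(n_sp, p$sp_dur_lo_s, p$sp_dur_hi_s)
    sp_tab <- tibble::tibble(channel = lab, start_s = rep(NA_real_, n_sp),
                             peak_s = NA_real_, end_s = NA_real_,
                             freq_hz = p$sp_freq_hz, coupled = coupled,
                             true_phase_deg = NA_real_)

    # phase trajectory of the noiseless SW train, in the package's
    # coupling convention (0 deg = descending zero crossing, 90 = trough)
    phase <- if (any(coupled)) {
      sw_f <- sw_bandpass(sw_sig, fs)
      sw_phase_series(sw_f, fs)
    } else NULL

    peaks <- numeric(0)
    win <- round(1.5 * fs)
    for (i in seq_len(n_sp)) {
      half <- round(sp_dur[i] * fs / 2)
      pk <- NA_real_
      if (coupled[i]) {
        theta <- draw_coupling_phase(1, p$mu_deg, p$kappa)
        hosts <- sample.int(n_sw)
        for (jh in hosts) {
          tr <- round(sw_tab$trough_s[jh] * fs) + 1
          ix <- max(1, tr - win):min(n, tr + win)
          d <- abs(((phase[ix] - theta + 180) %% 360) - 180)
          cand <- ix[order(d, ix)[1]]
          inside <- any(cand - half >= blocks$lo & cand + half <= blocks$hi)
          gap_ok <- !length(peaks) || min(abs(peaks - cand)) >= (p$sp_dur_hi_s + 1) * fs
          if (inside && gap_ok) { pk <- cand; break }
        }
        if (!is.na(pk)) sp_tab$true_phase_deg[i] <- theta
      } else {
        bl <- data.frame(lo = blocks$lo + half, hi = blocks$hi - half)
        for (try in 1:200) {
          cand <- place_events(1, bl, min_gap_samp = 1)
          if (!length(cand)) break
          cand <- round(cand)
          far_sw <- !p$sp_avoid_sw || !n_sw ||
            min(abs(sw_tab$trough_s * fs + 1 - cand)) > 1.5 * fs
          gap_ok <- !length(peaks) || min(abs(peaks - cand)) >= (p$sp_dur_hi_s + 1) * fs
          if (far_sw && gap_ok) { pk <- cand; break }
        }
      }
      if (is.na(pk)) next
      peaks <- c(peaks, pk)
      kern <- make_spindle_kernel(p$sp_freq_hz, sp_dur[i], p$sp_amp_uV, fs)
      st <- pk - half
      ix <- st:(st + length(kern) - 1)
      ok <- ix >= 1 & ix <= n
      x[ix[ok]] <- x[ix[ok]] + kern[ok]
      sp_tab$start_s[i] <- (st - 1) / fs
      sp_tab$peak_s[i] <- (pk - 1) / fs
      sp_tab$end_s[i] <- (st - 1 + length(kern) - 1) / fs
    }
    sp_tab <- sp_tab[!is.na(sp_tab$peak_s), ]

    samples[ch, ] <- x
    sw_all[[ch]] <- sw_tab
    sp_all[[ch]] <- sp_tab
  }

  rec <- eeg_recording(samples, fs,
                       channel_labels = paste0("ch", seq_len(p$n_channels)),
                       subject_id = paste0("sim", p$seed %||% 0))
  list(recording = rec, hypnogram = h,
       truth = list(sw_events = dplyr::bind_rows(sw_all),
                    sp_events = dplyr::bind_rows(sp_all)))
}

#' Inject artifact epochs into a recording
#'
#' Alters selected epochs to violate one of the rejection criteria:
#' `"high_delta"` adds a large 2 Hz sinusoid, `"high_beta"` a 20 Hz
#' sinusoid, `"clipping"` pins a fraction of samples to the channel's
#' global extreme, `"high_rms"` scales the epoch by a factor.
#'
#' @param rec An [eeg_recording()].
#' @param h The matching [hypnogram()].
#' @param which_epochs Integer epoch indices to corrupt.
#' @param mode One of `"high_delta"`, `"high_beta"`, `"clipping"`,
#'   `"high_rms"` (hyphens accepted).
#' @param channel Channel label or index (default: all channels).
#' @param amp_uV Added sinusoid amplitude for the band modes.
#' @param clip_fraction Fraction of samples pinned in `"clipping"` mode.
#' @param rms_factor Scale factor in `"high_rms"` mode.
#' @return The modified recording.
#' @export
inject_artifact_epochs <- function(rec, h, which_epochs, mode,
                                   channel = NULL, amp_uV = 150,
                                   clip_fraction = 0.06, rms_factor = 10) {
  mode <- gsub("-", "_", tolower(mode))
  if (!mode %in% c("high_delta", "high_beta", "clipping", "high_rms")) {
    stop("unknown artifact mode: ", mode, call. = FALSE)
  }
  if (!length(which_epochs)) return(rec)
  if (any(which_epochs < 1 | which_epochs > length(h$stages))) {
    stop("epoch index out of range", call. = FALSE)
  }
  chans <- if (is.null(channel)) seq_along(rec$channel_labels) else channel
  for (ch in chans) {
    for (e in which_epochs) {
      ix <- epoch_sample_range(e, h$epoch_len_s, rec$fs)
      ix <- ix[ix <= ncol(rec$samples)]
      seg <- rec$samples[ch, ix]
      t <- (seq_along(ix) - 1) / rec$fs
      seg <- switch(mode,
        high_delta = seg + amp_uV * sin(2 * pi * 2 * t),
        high_beta = seg + amp_uV * sin(2 * pi * 20 * t),
        clipping = {
          extreme <- max(abs(rec$samples[ch, ]))
          k <- ceiling(clip_fraction * length(seg))
          pin <- sample(seq_along(seg), k)
          seg[pin] <- extreme
          seg
        },
        high_rms = seg * rms_factor)
      rec$samples[ch, ix] <- seg
    }
  }
  rec
}
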