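#' @importFrom rlang %||% .data
#' @keywords internal
"_PACKAGE"

# dB view of linear power with a finite floor for zero/negative bins.
DB_FLOOR <- -300

power_to_db <- function(p) {
  out <- rep(DB_FLOOR, length(p))
  pos <- is.finite(p) & p > 0
  out[pos] <- 10 * log10(p[pos])
  out
}

# Greatest common divisor (for rational resampling factors).
gcd <- function(a, b) if (b == 0) a else gcd(b, a %% b)

# Analytic signal via the frequency-domain Hilbert transform.
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  hmult <- numeric(n)
  if (n %% 2 == 0) {
    hmult[c(1, n / 2 + 1)] <- 1
    hmult[2:(n / 2)] <- 2
  } else {
    hmult[1] <- 1
    hmult[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * hmult, inverse = TRUE) / n
}

# Zero-phase application of a linear-phase FIR filter: convolve and
# compensate the group delay (order/2 samples). Edges are zero-padded,
# so the first/last order/2 samples are transient.
fir_filter_zerophase <- function(x, coefs) {
  n <- length(x)
  m <- length(coefs)
  nf <- stats::nextn(n + m - 1, 2)
  X <- stats::fft(c(x, numeric(nf - n)))
  H <- stats::fft(c(coefs, numeric(nf - m)))
  y <- Re(stats::fft(X * H, inverse = TRUE)) / nf
  delay <- (m - 1) / 2
  y[(1 + delay):(n + delay)]
}

# Centered moving average with edge renormalization.
moving_average <- function(x, width) {
  width <- max(1L, as.integer(width))
  if (width %% 2 == 0) width <- width + 1L
  kern <- rep(1, width)
  num <- stats::filter(x, kern, sides = 2)
  den <- stats::filter(rep(1, length(x)), kern, sides = 2)
  # renormalize partial windows at the edges
  half <- (width - 1L) / 2L
  num[is.na(num)] <- 0
  den[is.na(den)] <- 0
  for (i in seq_len(half)) {
    num[i] <- sum(x[1:(i + half)]); den[i] <- i + half
    j <- length(x) - i + 1L
    num[j] <- sum(x[(j - half):length(x)]); den[j] <- length(x) - j + 1L + half
  }
  as.numeric(num / den)
}

# Runs of TRUE in a logical vector, as a two-column matrix (start, end).
true_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}
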