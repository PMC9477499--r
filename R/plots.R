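#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a power spectrum
#'
#' @param object A `psd` tibble.
#' @param ... Unused.
#' @return A ggplot of power (dB) against frequency.
#' @export
autoplot.psd <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$freq, y = .data$power_db)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Frequency (Hz)",
                  y = expression(Power ~ (10 * log[10] ~ mu * V^2 / Hz)),
                  title = paste0(attr(object, "kind") %||% "", " spectrum")) +
    ggplot2::theme_minimal()
}

#' Plot a multitaper spectrogram
#'
#' @param object An `mt_spectrogram`.
#' @param ... Unused.
#' @return A ggplot heat map of dB power over time and frequency.
#' @export
autoplot.mt_spectrogram <- function(object, ...) {
  df <- tidyr::expand_grid(ti = seq_along(object$time),
                           fi = seq_along(object$freq))
  df$time_min <- object$time[df$ti] / 60
  df$freq <- object$freq[df$fi]
  df$db <- power_to_db(object$power[cbind(df$fi, df$ti)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_min, y = .data$freq,
                                   fill = .data$db)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "dB") +
    ggplot2::labs(x = "Time (min)", y = "Frequency (Hz)") +
    ggplot2::theme_minimal()
}

#' Plot a SW-trough-locked scalogram
#'
#' @param object An `sw_scalogram` from [sw_locked_scalogram()].
#' @param ... Unused.
#' @return A ggplot heat map of baseline-normalized z around the trough.
#' @export
autoplot.sw_scalogram <- function(object, ...) {
  df <- tidyr::expand_grid(li = seq_along(object$lag_s),
                           fi = seq_along(object$freq))
  df$lag_s <- object$lag_s[df$li]
  df$freq <- object$freq[df$fi]
  df$z <- object$z[cbind(df$fi, df$li)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lag_s, y = .data$freq,
                                   fill = .data$z)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(name = "z") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "Lag from SW trough (s)", y = "Frequency (Hz)") +
    ggplot2::theme_minimal()
}

#' Plot a hypnogram
#'
#' @param h A [hypnogram()].
#' @return A ggplot step trace of stage against time.
#' @export
plot_hypnogram <- function(h) {
  depth <- c(W = 4, REM = 3, N1 = 2, N2 = 1, N3 = 0, ART = 5)
  df <- tibble::tibble(
    t_min = (seq_along(h$stages) - 1) * h$epoch_len_s / 60,
    depth = depth[h$stages])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t_min, y = .data$depth)) +
    ggplot2::geom_step() +
    ggplot2::scale_y_continuous(breaks = unname(depth),
                                labels = names(depth)) +
    ggplot2::labs(x = "Time (min)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the distribution of coupling phases
#'
#' Circular histogram (rose plot) of SW phases at spindle peaks, with
#' the mean angle marked.
#'
#' @param phases_deg Phases in degrees.
#' @param bin_width_deg Histogram bin width, degrees.
#' @return A ggplot in polar coordinates.
#' @export
plot_coupling_phases <- function(phases_deg, bin_width_deg = 20) {
  df <- tibble::tibble(phase = phases_deg %% 360)
  cs <- coupling_stats(phases_deg)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$phase)) +
    ggplot2::geom_histogram(binwidth = bin_width_deg, boundary = 0,
                            fill = "grey60", colour = "white") +
    ggplot2::geom_vline(xintercept = cs$mean_angle_deg, colour = "red") +
    ggplot2::coord_polar(start = -pi / 2, direction = -1) +
    ggplot2::scale_x_continuous(limits = c(0, 360),
                                breaks = seq(0, 270, by = 90)) +
    ggplot2::labs(x = "SW phase at spindle peak (deg)", y = "count") +
    ggplot2::theme_minimal()
}
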