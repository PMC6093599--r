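# ggplot2 visualization methods for the result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a time-frequency result
#'
#' Raster of power averaged over epochs for one channel.
#'
#' @param object a `ts_tfr`.
#' @param channel channel index.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.ts_tfr <- function(object, channel = 1, ...) {
  pw <- apply(object$power[, channel, , , drop = FALSE], c(3, 4), mean,
              na.rm = TRUE)
  df <- tidyr::expand_grid(freq = object$freqs_hz, time = object$times_s)
  df$power <- as.vector(pw)
  ggplot2::ggplot(df[is.finite(df$power), ],
                  ggplot2::aes(x = .data$time, y = .data$freq,
                               fill = .data$power)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "power\n(amp²)") +
    ggplot2::labs(x = "time (s, anchor-relative)", y = "frequency (Hz)",
                  title = sprintf("Time-frequency power, channel %d", channel)) +
    ggplot2::theme_minimal()
}

#' Plot a PAC spectrum
#'
#' @param object a `ts_pac`.
#' @param ... unused.
#' @return A ggplot raster of the coupling matrix.
#' @export
autoplot.ts_pac <- function(object, ...) {
  df <- tidyr::expand_grid(amp = object$amp_freqs_hz,
                           phase = object$phase_freqs_hz)
  df$coupling <- as.vector(t(object$coupling))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$phase, y = .data$amp,
                                   fill = .data$coupling)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "coherence²") +
    ggplot2::labs(x = "phase frequency (Hz)",
                  y = "amplitude frequency (Hz)",
                  title = "Phase-amplitude coupling") +
    ggplot2::theme_minimal()
}

#' Plot a phase-bin profile
#'
#' Deviation of fast-gamma power from the cross-position mean per phase bin
#' and position, with a strip showing the winning position per bin.
#'
#' @param object a `ts_phase_profile`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.ts_phase_profile <- function(object, ...) {
  df <- tidyr::expand_grid(position = factor(1:3, labels = paste0("P", 1:3)),
                           bin = seq_len(object$n_bins))
  df$phase <- object$bin_centers[df$bin]
  df$deviation <- as.vector(t(object$deviation_by_position))
  strip <- tibble::tibble(
    phase = object$bin_centers,
    label = factor(paste0("P", object$labels)),
    y = min(df$deviation) * 1.15)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$phase, y = .data$deviation,
                                   colour = .data$position)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::geom_point(data = strip,
                        ggplot2::aes(x = .data$phase, y = .data$y,
                                     colour = .data$label),
                        inherit.aes = FALSE, shape = 15, size = 3) +
    ggplot2::scale_x_continuous(
      breaks = c(0, pi / 2, pi, 3 * pi / 2, 2 * pi),
      labels = c("0", "π/2", "π", "3π/2", "2π")) +
    ggplot2::labs(x = "theta/alpha phase (rad)",
                  y = "fast-gamma power deviation",
                  colour = "list position",
                  title = "Phase-binned gamma power by list position") +
    ggplot2::theme_minimal()
}

#' Plot a serial-order test result
#'
#' Histogram of surrogate template fits with the observed fit marked.
#'
#' @param object a `ts_order_test`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.ts_order_test <- function(object, ...) {
  df <- tibble::tibble(fit = object$surrogate_fits)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fit)) +
    ggplot2::geom_bar(fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$observed_fit,
                        colour = "firebrick", linewidth = 1) +
    ggplot2::labs(
      x = "template fit (matching bins)", y = "surrogate count",
      title = sprintf("Serial-order permutation test (p = %.4g)",
                      object$p_value)) +
    ggplot2::theme_minimal()
}

#' Plot the peak-locked average waveform
#'
#' @param object a `ts_peaklock`.
#' @param ... unused.
#' @return A ggplot of the mean unfiltered waveform around theta/alpha peaks.
#' @export
autoplot.ts_peaklock <- function(object, ...) {
  df <- tibble::tibble(time = object$times_s, amplitude = object$waveform)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$amplitude)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "time from theta/alpha peak (s)", y = "amplitude (µV)",
      title = sprintf("Peak-locked average (harmonic ratio %.1f, %s)",
                      object$harmonic_ratio,
                      if (object$sinusoidal) "sinusoidal" else
                        "nonsinusoidal")) +
    ggplot2::theme_minimal()
}
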