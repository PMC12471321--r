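#' Plot a Hilbert spectrum
#'
#' Energy over the instantaneous frequency-time plane, log10 color scale.
#'
#' @param object A `hilbert_spectrum`.
#' @param fmax_plot Upper frequency limit of the display (default 300 Hz).
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot hilbert_spectrum
#' @export
autoplot.hilbert_spectrum <- function(object, fmax_plot = 300, ...) {
  keep <- object$freq_centers <= fmax_plot
  df <- expand.grid(freq_hz = object$freq_centers[keep],
                    time_s = object$t0 + (seq_len(ncol(object$energy)) - 1) / object$fs)
  df$energy <- as.vector(object$energy[keep, ])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$freq_hz,
                                   fill = log10(.data$energy + 1e-12))) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "log10 energy") +
    ggplot2::labs(x = "time (s, 0 = contact)", y = "frequency (Hz)") +
    ggplot2::theme_minimal()
}

#' Plot an IMF set
#'
#' IMFs (fast to slow) and the residual in stacked facets.
#'
#' @param object An `imf_set`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot imf_set
#' @export
autoplot.imf_set <- function(object, ...) {
  df <- as_tibble(object) |>
    tidyr::pivot_longer(-"time_s", names_to = "component", values_to = "value")
  lev <- c(paste0("imf_", seq_len(ncol(object$imfs))), "residual")
  df$component <- factor(df$component, levels = lev)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$component), scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a trial's EMG channels and GRF
#'
#' @param trial A `trial_record`.
#' @param seg Optional `stance_segment`; onset/offset drawn as dashed lines.
#' @return A ggplot object.
#' @export
plot_trial <- function(trial, seg = NULL) {
  df <- as_tibble(trial) |>
    tidyr::pivot_longer(-"time_s", names_to = "channel", values_to = "value")
  df$channel <- factor(df$channel, levels = c(names(trial$emg), "GRF_N"))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$channel), scales = "free_y") +
    ggplot2::labs(x = "time (s, 0 = contact)", y = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(seg)) {
    tt <- trace_time(trial$grf)[c(seg$onset_index, seg$offset_index)]
    p <- p + ggplot2::geom_vline(xintercept = tt, linetype = "dashed",
                                 colour = "grey40")
  }
  p
}
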