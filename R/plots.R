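## ggplot2 methods for the package's result types.

#' Plot a baseband I/Q record
#'
#' In-phase and quadrature components against slow time, one panel per
#' fast-time channel when there are several.
#'
#' @param object A `baseband_signal` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot baseband_signal
#' @export
autoplot.baseband_signal <- function(object, ...) {
  df <- tidyr::pivot_longer(as_tibble(object), c("i", "q"),
                            names_to = "component", values_to = "value")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$value,
                                        colour = .data$component)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "slow time [s]", y = "baseband amplitude",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (max(object$channel) > 1) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$channel),
                                 labeller = ggplot2::label_both)
  }
  p
}

#' Plot the MTI filter magnitude response
#'
#' @param object A `first_order_iir` object.
#' @param n Number of frequency points.
#' @param ... Unused.
#' @return A ggplot object (gain in dB over rad/sample, log frequency axis).
#' @method autoplot first_order_iir
#' @export
autoplot.first_order_iir <- function(object, n = 512, ...) {
  ggplot2::ggplot(frequency_response(object, n),
                  ggplot2::aes(x = .data$omega_rad, y = .data$gain_db)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "digital frequency [rad/sample]", y = "gain [dB]") +
    ggplot2::theme_minimal()
}

#' Plot a power spectrum
#'
#' @param object A `power_spectrum` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot power_spectrum
#' @export
autoplot.power_spectrum <- function(object, ...) {
  xvar <- if (all(is.na(object$freq_hz))) "bin" else "freq_hz"
  ggplot2::ggplot(object, ggplot2::aes(x = .data[[xvar]], y = .data$power)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = if (xvar == "bin") "bin" else "frequency [Hz]",
                  y = "power") +
    ggplot2::theme_minimal()
}

#' Plot a CFAR detection table
#'
#' Power and adaptive threshold per bin, detections highlighted.
#'
#' @param object A `cfar_detection` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cfar_detection
#' @export
autoplot.cfar_detection <- function(object, ...) {
  xvar <- if (all(is.na(object$freq_hz))) "bin" else "freq_hz"
  ggplot2::ggplot(object, ggplot2::aes(x = .data[[xvar]])) +
    ggplot2::geom_line(ggplot2::aes(y = .data$power), colour = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = .data$threshold), colour = "red",
                       linetype = "dashed") +
    ggplot2::geom_point(
      data = dplyr::filter(object, .data$detected),
      ggplot2::aes(y = .data$power), colour = "red", size = 1.5
    ) +
    ggplot2::labs(x = if (xvar == "bin") "bin" else "frequency [Hz]",
                  y = "power (threshold dashed)") +
    ggplot2::theme_minimal()
}

#' Plot a vital-sign report
#'
#' The CFAR-gated detection spectrum with the estimated heart and
#' respiration peak frequencies marked.
#'
#' @param object A `vital_sign_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot vital_sign_report
#' @export
autoplot.vital_sign_report <- function(object, ...) {
  p <- autoplot(object$detection)
  if (!is.null(object$estimates)) {
    p <- p + ggplot2::geom_vline(
      data = as_tibble(object$estimates),
      ggplot2::aes(xintercept = .data$peak_freq_hz, colour = .data$band),
      linetype = "dotted"
    ) + ggplot2::labs(colour = "band peak")
  }
  p
}
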