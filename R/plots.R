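# ggplot2 methods for the result types.

#' Plot a corrected pair
#'
#' Overlays the raw sensor, the reference and the corrected trace against
#' time, the standard way dual-resonator corrections are presented.
#'
#' @param object A `qcm_correction`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.qcm_correction <- function(object, ...) {
  long <- tidyr::pivot_longer(object$data, c("sensor", "reference",
                                             "corrected"),
                              names_to = "trace", values_to = "value")
  long$trace <- factor(long$trace, c("sensor", "reference", "corrected"))
  ylab <- if (object$channel == "frequency") {
    "Resonance frequency shift (Hz)"
  } else {
    expression(paste("Dissipation shift (", 10^-6, ")"))
  }
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$time_s, y = .data$value,
                               colour = .data$trace)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::scale_colour_manual(
      values = c(sensor = "#c23b22", reference = "#2b6cb0",
                 corrected = "black"), name = NULL) +
    ggplot2::labs(x = "Time (s)", y = ylab) +
    ggplot2::theme_minimal()
}

#' Plot an Allan deviation curve
#'
#' Log-log Allan deviation versus integration time. Supply several curves
#' bound with a `method` column via `dplyr::bind_rows()` to compare
#' correction methods.
#'
#' @param object An `allan_curve` tibble (optionally with a `method` column).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.allan_curve <- function(object, ...) {
  aes <- if ("method" %in% names(object)) {
    ggplot2::aes(x = .data$tau_s, y = .data$adev, colour = .data$method)
  } else {
    ggplot2::aes(x = .data$tau_s, y = .data$adev)
  }
  ggplot2::ggplot(object, aes) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(paste("Integration time ", tau, " (s)")),
                  y = expression(sigma[y](tau))) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
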