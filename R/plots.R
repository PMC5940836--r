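#' Plot a Bland-Altman analysis
#'
#' Difference-versus-average scatter with the fixed bias (solid) and the
#' bias +/- k SD band (dashed), matching the conventional method-comparison
#' display.
#'
#' @param object A `ppg_bland_altman` from [bland_altman()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ppg_bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$average, y = .data$difference)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = object$bias) +
    ggplot2::geom_hline(yintercept = c(object$lower, object$upper),
                        linetype = "dashed") +
    ggplot2::labs(
      x = "Average of methods", y = "Difference (second - first)",
      title = sprintf("Bland-Altman: bias %.2f, %s%.3g SD limits",
                      object$bias, "±", object$limit_multiplier)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a geometric mean regression
#'
#' Scatter of the paired measurements with the geometric mean regression
#' line and the identity line for reference.
#'
#' @param object A `ppg_gmr` from [gm_regression()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ppg_gmr <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_abline(slope = object$slope,
                         intercept = object$intercept) +
    ggplot2::labs(
      title = sprintf("y = %.3g x %+.3g, r = %.3f",
                      object$slope, object$intercept, object$r)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a PPG record with detected beats
#'
#' Waveform trace with detected pulse feet marked; outlier beats (if the
#' beat table is flagged) are highlighted.
#'
#' @param record A [ppg_record()].
#' @param beats Optional beat tibble from [beat_features()] /
#'   [flag_outliers()].
#' @param max_s Plot at most this many seconds of signal.
#' @return A ggplot object.
#' @export
plot_ppg <- function(record, beats = NULL, max_s = 30) {
  dat <- dplyr::filter(tibble::as_tibble(record),
                       .data$time <= .data$time[1] + max_s)
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "Time (s)", y = "PPG amplitude (a.u.)") +
    ggplot2::theme_minimal()
  if (!is.null(beats) && nrow(beats) > 0) {
    b <- dplyr::filter(beats, .data$onset_s <= max(dat$time))
    b$value <- approx(dat$time, dat$value, xout = b$onset_s, rule = 2)$y
    p <- p + ggplot2::geom_point(
      data = b,
      ggplot2::aes(x = .data$onset_s, y = .data$value,
                   colour = .data$outlier)
    ) +
      ggplot2::scale_colour_manual(
        values = c(`FALSE` = "#2c7fb8", `TRUE` = "#d95f02"),
        name = "outlier"
      )
  }
  p
}
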