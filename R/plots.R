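#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a time series trace
#' @param object A `glu_ts`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.glu_ts <- function(object, ...) {
  df <- tibble::tibble(time_s = ts_time(object), value = object$values)
  ylab <- switch(object$units, ampere = "current (A)",
                 dff = expression(Delta * F / F[0]),
                 rate = "release rate (1/s)", "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = ylab, title = object$label) +
    ggplot2::theme_minimal()
}

#' Plot per-stimulus train metrics
#' @param object A `train_metrics` tibble.
#' @param ... Unused.
#' @export
autoplot.train_metrics <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$stimulus, y = .data$amplitude)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::labs(x = "stimulus", y = "amplitude (magnitude)") +
    ggplot2::theme_minimal()
}

#' Cumulative-response pool plot with the back-extrapolated fit
#'
#' The cumulative response against stimulus number, the straight-line fit
#' through the steady-state points, and its continuation to the ordinate
#' (dashed), whose intercept estimates the pool size.
#'
#' @param responses Per-stimulus responses (not yet cumulative).
#' @param fit_last_k Number of final points in the fit.
#' @return A ggplot.
#' @export
plot_smn <- function(responses, fit_last_k = 10) {
  est <- y1_over_intercept(responses, fit_last_k)
  df <- tibble::tibble(stimulus = seq_along(responses),
                       cumulative = cumsum(responses))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stimulus, y = .data$cumulative)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = est$y_intercept, slope = est$slope,
                         linetype = "dashed") +
    ggplot2::expand_limits(x = 0, y = 0) +
    ggplot2::labs(x = "stimulus number", y = "cumulative response") +
    ggplot2::theme_minimal()
}

#' Optical vs electrical readout scatter with fits
#'
#' Scatter of paired normalized readouts with the origin-constrained
#' regression (dashed) and the identity line (dotted).
#'
#' @param comparison Result of [compare_readouts()].
#' @return A ggplot.
#' @export
plot_readout_comparison <- function(comparison) {
  reg <- comparison$regression
  ggplot2::ggplot(comparison$pairs,
                  ggplot2::aes(x = .data$electrical, y = .data$optical)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = reg$slope, intercept = 0, linetype = "dashed") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "normalized eEPSC amplitude",
                  y = "normalized optical response",
                  subtitle = sprintf("slope = %.3f, d = %.3g",
                                     reg$slope, reg$d_identity)) +
    ggplot2::theme_minimal()
}
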