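#' Plot a DFA log-log fluctuation fit
#'
#' F(n) against window size on log-log axes; filled points are the sizes in
#' the scaling-fit range, with the fitted slope (alpha) overlaid.
#'
#' @param object A `dfa_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot dfa_result
#' @export
autoplot.dfa_result <- function(object, ...) {
  df <- object$table
  fit <- df[df$in_fit, ]
  ggplot2::ggplot(df, ggplot2::aes(.data$n_hours, .data$fluctuation)) +
    ggplot2::geom_point(ggplot2::aes(alpha = .data$in_fit), size = 2) +
    ggplot2::geom_smooth(data = fit, method = "lm", formula = y ~ x,
                         se = FALSE, linewidth = 0.5) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.3),
                                guide = "none") +
    ggplot2::labs(x = "window size n (h)", y = "F(n)",
                  title = sprintf("DFA: alpha = %.3f (%g-%g h)",
                                  object$alpha, object$fit_range_h[1],
                                  object$fit_range_h[2])) +
    ggplot2::theme_minimal()
}

#' Plot a folded periodogram
#'
#' Statistic against tested period with the chi-square null threshold line.
#'
#' @param object A `periodogram_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot periodogram_result
#' @export
autoplot.periodogram_result <- function(object, ...) {
  ggplot2::ggplot(object$table, ggplot2::aes(.data$period_h)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$statistic)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$threshold), linetype = 2) +
    ggplot2::geom_vline(xintercept = object$peak_period_h,
                        colour = "grey50", linetype = 3) +
    ggplot2::labs(x = "period (h)", y = "variance explained",
                  title = sprintf("Peak %.2f h, strength %.3f",
                                  object$peak_period_h, object$strength)) +
    ggplot2::theme_minimal()
}

#' Plot a vigilance-state timecourse
#'
#' Per-state percentage against zeitgeber time, faceted by state, one line
#' per recording day; dark/dim phase shaded.
#'
#' @param object A `state_timecourse`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot state_timecourse
#' @export
autoplot.state_timecourse <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$bin_mid_zt, .data$percent,
                               colour = factor(.data$day))) +
    ggplot2::annotate("rect", xmin = 12, xmax = 24, ymin = -Inf, ymax = Inf,
                      alpha = 0.1) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~state, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "zeitgeber time (h)", y = "% of recording time",
                  colour = "day") +
    ggplot2::theme_minimal()
}

#' Plot an SWA timecourse
#'
#' Mean NREM slow-wave power per clock bin, one line per day.
#'
#' @param object A `swa_timecourse`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot swa_timecourse
#' @export
autoplot.swa_timecourse <- function(object, ...) {
  band <- attr(object, "band")
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$bin_mid_zt, .data$swa,
                               colour = factor(.data$day))) +
    ggplot2::annotate("rect", xmin = 12, xmax = 24, ymin = -Inf, ymax = Inf,
                      alpha = 0.1) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "zeitgeber time (h)",
                  y = sprintf("NREM power %g-%g Hz (uV^2)",
                              band$lo_hz, band$hi_hz),
                  colour = "day") +
    ggplot2::theme_minimal()
}

#' Plot per-state mean EEG spectra
#'
#' Mean power density per 0.25-Hz bin for each vigilance state, log power
#' axis.
#'
#' @param object A `state_spectra` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot state_spectra
#' @export
autoplot.state_spectra <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$freq_hz, .data$power,
                                       colour = .data$state)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "frequency (Hz)", y = "power density (uV^2 / 0.25 Hz)") +
    ggplot2::theme_minimal()
}
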