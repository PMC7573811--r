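#' Tidy a DFA result
#'
#' One row per window size: `n_bins`, `n_hours`, `fluctuation`,
#' `n_windows`, `in_fit`.
#' @param x A `dfa_result`.
#' @param ... Unused.
#' @method tidy dfa_result
#' @export
tidy.dfa_result <- function(x, ...) x$table

#' @rdname tidy.dfa_result
#' @method glance dfa_result
#' @export
glance.dfa_result <- function(x, ...) {
  tibble(alpha = x$alpha, fit_r2 = x$fit_r2,
         fit_lo_h = x$fit_range_h[1], fit_hi_h = x$fit_range_h[2],
         n_sizes_fit = sum(x$table$in_fit))
}

#' Tidy a periodogram result
#'
#' One row per tested period: `period_h`, `statistic`, `threshold`.
#' @param x A `periodogram_result`.
#' @param ... Unused.
#' @method tidy periodogram_result
#' @export
tidy.periodogram_result <- function(x, ...) x$table

#' @rdname tidy.periodogram_result
#' @method glance periodogram_result
#' @export
glance.periodogram_result <- function(x, ...) {
  tibble(peak_period_h = x$peak_period_h, strength = x$strength,
         peak_significant = x$peak_significant, alpha = x$alpha,
         n_bins = x$n_bins)
}

#' Tidy a waking-peak delay regression
#'
#' Coefficient rows in broom layout: `term`, `estimate`, `std.error`,
#' `statistic`, `p.value`.
#' @param x A `delay_regression`.
#' @param ... Unused.
#' @method tidy delay_regression
#' @export
tidy.delay_regression <- function(x, ...) {
  co <- summary(x$fit)$coefficients
  tibble(term = rownames(co), estimate = co[, "Estimate"],
         std.error = co[, "Std. Error"], statistic = co[, "t value"],
         p.value = co[, "Pr(>|t|)"])
}

#' @rdname tidy.delay_regression
#' @method glance delay_regression
#' @export
glance.delay_regression <- function(x, ...) {
  tibble(slope = x$slope, slope_se = x$slope_se, intercept = x$intercept,
         intercept_se = x$intercept_se, r_squared = x$r_squared, n = x$n)
}
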