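#' Re-bin an activity trace
#'
#' Sums counts into coarser bins. The target bin must be an integer multiple
#' of the source bin and the trace must divide evenly; total counts are
#' conserved exactly.
#'
#' @param trace An `activity_trace`.
#' @param target_bin_seconds New bin length in seconds.
#' @return An `activity_trace` at the new resolution.
#' @export
bin_activity <- function(trace, target_bin_seconds) {
  stopifnot(inherits(trace, "activity_trace"))
  src <- attr(trace, "bin_seconds")
  if (nrow(trace) == 0L) abort("Empty trace.")
  if (target_bin_seconds %% src != 0) {
    abort("`target_bin_seconds` must be an integer multiple of the source bin.")
  }
  k <- target_bin_seconds %/% src
  if (k == 1L) return(trace)
  n_keep <- (nrow(trace) %/% k) * k
  if (n_keep != nrow(trace)) {
    abort("Trace length is not a whole number of target bins.")
  }
  counts <- colSums(matrix(trace$count[seq_len(n_keep)], nrow = k))
  new_activity_trace(counts, as.integer(target_bin_seconds),
                     attr(trace, "schedule"), attr(trace, "start_zt_h"))
}

#' Folded periodogram of rest-activity (period and rhythm strength)
#'
#' For each candidate period P the trace is folded at P and the fraction of
#' total variance explained by the folded mean waveform (eta-squared) is
#' computed; this is the Sokolove-Bushell-style chi-square periodogram
#' statistic expressed on a 0-1 scale. The peak period is the grid argmax and
#' the rhythm strength is the statistic at the peak. The null significance
#' line comes from the chi-square distribution of N x eta-squared with
#' (number of phase classes - 1) degrees of freedom, Bonferroni-corrected
#' across the period grid by default.
#'
#' Because the folding statistic is not the (uncited) original F-periodogram
#' formula, absolute strength values are comparable within this package only;
#' orderings across conditions and significance calls are the meaningful
#' outputs.
#'
#' @param trace An `activity_trace`.
#' @param period_grid_h Candidate periods in hours (default `seq(20, 28,
#'   by = 0.05)`). Each period must be a whole number of bins.
#' @param alpha Significance level for the null threshold (default 0.05).
#' @param correct Bonferroni-correct the threshold across the grid
#'   (default TRUE).
#' @return A `periodogram_result` with elements `table` (tibble: `period_h`,
#'   `statistic`, `threshold`), `peak_period_h`, `strength`,
#'   `peak_significant`.
#' @examples
#' tr <- simulate_activity(activity_params(days = 15, seed = 1))
#' pg <- periodogram(tr)
#' pg$peak_period_h
#' @export
periodogram <- function(trace, period_grid_h = seq(20, 28, by = 0.05),
                        alpha = 0.05, correct = TRUE) {
  stopifnot(inherits(trace, "activity_trace"))
  bin_s <- attr(trace, "bin_seconds")
  x <- trace$count
  n <- length(x)
  m_bins <- round(period_grid_h * 3600 / bin_s)
  if (any(abs(m_bins * bin_s / 3600 - period_grid_h) > 1e-9)) {
    abort("Every period in the grid must be a whole number of bins.")
  }
  if (n < 2 * max(m_bins)) {
    abort("Trace must cover at least 2 cycles of the longest tested period.")
  }
  sst <- sum((x - mean(x))^2)
  if (sst == 0) abort("Constant trace: periodogram undefined.")
  n_tests <- length(period_grid_h)
  a_eff <- if (correct) alpha / n_tests else alpha
  stat <- thr <- numeric(n_tests)
  idx0 <- seq_len(n) - 1L
  gm <- mean(x)
  for (j in seq_len(n_tests)) {
    m <- m_bins[j]
    cls <- idx0 %% m
    sums <- rowsum(x, cls)
    sizes <- tabulate(cls + 1L, nbins = m)
    stat[j] <- sum((sums - sizes * gm)^2 / sizes) / sst
    thr[j] <- qchisq(1 - a_eff, df = m - 1) / n
  }
  peak <- which.max(stat)
  structure(
    list(
      table = tibble(period_h = period_grid_h, statistic = stat,
                     threshold = thr),
      peak_period_h = period_grid_h[peak],
      strength = stat[peak],
      peak_significant = stat[peak] > thr[peak],
      alpha = alpha, corrected = correct, n_bins = n
    ),
    class = "periodogram_result"
  )
}

#' @export
print.periodogram_result <- function(x, ...) {
  cat(sprintf(
    "<periodogram_result> peak %.2f h, strength %.4f (%ssignificant at %g)\n",
    x$peak_period_h, x$strength, if (x$peak_significant) "" else "not ",
    x$alpha))
  invisible(x)
}

# core DFA-1 fluctuation function: profile already integrated, one window size
dfa_fluctuation <- function(profile, n_win) {
  n_seg <- length(profile) %/% n_win
  seg <- matrix(profile[seq_len(n_seg * n_win)], nrow = n_win)
  t_idx <- seq_len(n_win)
  # per-segment OLS linear detrend, vectorized across segments
  tc <- t_idx - mean(t_idx)
  stt <- sum(tc^2)
  seg_mean <- colMeans(seg)
  slope <- colSums(tc * seg) / stt
  resid <- seg - outer(tc, slope) - rep(seg_mean, each = n_win)
  sqrt(mean(resid^2))
}

#' Detrended fluctuation analysis of rest-activity
#'
#' The counts are mean-centred and cumulatively integrated into a profile;
#' the profile is split into non-overlapping windows of size n (forward pass,
#' leftover tail discarded); each window is linearly detrended by ordinary
#' least squares (DFA-1); F(n) is the root-mean-square residual pooled over
#' windows. Window sizes are log-spaced (about 16 inside the fit range, plus
#' diagnostic sizes outside), and alpha is the OLS slope of log10 F against
#' log10 n restricted to the fit range — by default 3-8 h, the circadian
#' scaling range within which window sizes above 8 h are not statistically
#' reliable at 15-day trace lengths.
#'
#' @param trace An `activity_trace`.
#' @param fit_range_h Fit range in hours, default `c(3, 8)`.
#' @param n_sizes Approximate number of window sizes within the fit range.
#' @return A `dfa_result` with `table` (tibble: `n_bins`, `n_hours`,
#'   `fluctuation`, `n_windows`, `in_fit`), `alpha`, `fit_r2`, `fit_range_h`.
#' @examples
#' tr <- simulate_activity(activity_params(days = 15, seed = 1))
#' dfa(tr)$alpha
#' @export
dfa <- function(trace, fit_range_h = c(3, 8), n_sizes = 16) {
  stopifnot(inherits(trace, "activity_trace"), length(fit_range_h) == 2,
            fit_range_h[1] > 0, fit_range_h[1] < fit_range_h[2])
  bin_s <- attr(trace, "bin_seconds")
  x <- trace$count
  if (length(unique(x)) == 1L) {
    abort("Constant input: F(n) is identically zero, DFA undefined.")
  }
  lo_bins <- fit_range_h[1] * 3600 / bin_s
  hi_bins <- fit_range_h[2] * 3600 / bin_s
  if (length(x) < 4 * lo_bins) {
    abort("Fit range not covered: even the smallest fitted window lacks 4 repetitions.")
  }
  if (length(x) < 4 * hi_bins) {
    warn(paste("Trace shorter than 4 repetitions of the largest fit window;",
               "window sizes with fewer than 4 repetitions are excluded",
               "from the alpha fit."))
  }
  # log-spaced sizes: fit range plus diagnostic decades on both sides
  sizes_fit <- unique(round(exp(seq(log(lo_bins), log(hi_bins),
                                    length.out = n_sizes))))
  lo_diag <- max(8, round(lo_bins / 4))
  hi_diag <- length(x) %/% 4
  sizes_diag <- unique(round(exp(seq(log(lo_diag), log(hi_diag),
                                     length.out = 12))))
  sizes <- sort(unique(c(sizes_fit, sizes_diag)))
  sizes <- sizes[sizes >= 4 & sizes <= length(x) %/% 2]
  profile <- cumsum(x - mean(x))
  fl <- vapply(sizes, function(nw) dfa_fluctuation(profile, nw), numeric(1))
  n_hours <- sizes * bin_s / 3600
  in_fit <- n_hours >= fit_range_h[1] - 1e-9 &
    n_hours <= fit_range_h[2] + 1e-9 &
    (length(x) %/% sizes) >= 4
  if (sum(in_fit) < 3) abort("Fit range not covered by the data.")
  fit <- lm(log10(fl[in_fit]) ~ log10(sizes[in_fit]))
  structure(
    list(
      table = tibble(n_bins = sizes, n_hours = n_hours, fluctuation = fl,
                     n_windows = length(x) %/% sizes, in_fit = in_fit),
      alpha = unname(coef(fit)[2]),
      fit_r2 = summary(fit)$r.squared,
      fit_range_h = fit_range_h
    ),
    class = "dfa_result"
  )
}

#' @export
print.dfa_result <- function(x, ...) {
  cat(sprintf("<dfa_result> alpha = %.3f over %g-%g h (R^2 = %.4f)\n",
              x$alpha, x$fit_range_h[1], x$fit_range_h[2], x$fit_r2))
  invisible(x)
}
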