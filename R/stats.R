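#' Fixed-effects ANOVA table
#'
#' Fits a fixed-effects linear model on the named factor columns and returns
#' a tidy ANOVA table. Unbalanced designs (the usual case with unequal group
#' sizes) use Type-II sums of squares.
#'
#' @param data A data frame with a numeric response column and factor
#'   columns.
#' @param response Name of the response column.
#' @param factors Character vector of factor column names (1-3 factors,
#'   e.g. treatment, time of day, light/dark, day).
#' @param interactions Include all interaction terms (default FALSE: main
#'   effects only).
#' @return A tibble: `term`, `sumsq`, `df`, `statistic`, `p.value`
#'   (residuals row included with `NA` statistic).
#' @examples
#' df <- data.frame(y = rnorm(12), g = rep(c("a", "b"), 6))
#' anova_table(df, "y", "g")
#' @export
anova_table <- function(data, response, factors, interactions = FALSE) {
  stopifnot(is.data.frame(data), length(factors) >= 1)
  if (!response %in% names(data)) abort("Response column not found.")
  if (!all(factors %in% names(data))) abort("Factor column(s) not found.")
  data <- as.data.frame(data)
  for (f in factors) {
    data[[f]] <- factor(data[[f]])
    if (nlevels(data[[f]]) < 2) {
      abort(sprintf("Factor `%s` needs >= 2 levels.", f))
    }
  }
  y <- data[[response]]
  if (length(unique(y[is.finite(y)])) < 2) {
    abort("Degenerate input: all observations identical, F undefined.")
  }
  op <- if (interactions) " * " else " + "
  form <- as.formula(paste(response, "~", paste(factors, collapse = op)))
  fit <- lm(form, data = data)
  if (stats::df.residual(fit) < 1) abort("No residual degrees of freedom.")
  tab <- car::Anova(fit, type = 2)
  tibble(
    term = rownames(tab),
    sumsq = tab[["Sum Sq"]],
    df = tab[["Df"]],
    statistic = tab[["F value"]],
    p.value = tab[["Pr(>F)"]]
  )
}

#' One-way ANOVA from group summary statistics
#'
#' Computes the one-way fixed-effects F test from printed group means,
#' standard deviations and sizes — the form in which grouped results are
#' usually published. Between-group sum of squares from the weighted means,
#' within-group from the (n-1) s^2 terms.
#'
#' @param means,sds,ns Equal-length numeric vectors of group means, SDs,
#'   sizes.
#' @return A tibble: `term`, `sumsq`, `df`, `statistic`, `p.value`.
#' @examples
#' # rhythm-strength style summary entry for three groups
#' anova_from_summary(c(0.21, 0.14, 0.11), c(0.02, 0.049, 0.03), c(5, 5, 9))
#' @export
anova_from_summary <- function(means, sds, ns) {
  stopifnot(length(means) == length(sds), length(means) == length(ns),
            all(ns >= 2))
  k <- length(means)
  if (k < 2) abort("Need >= 2 groups.")
  n_tot <- sum(ns)
  grand <- sum(ns * means) / n_tot
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum((ns - 1) * sds^2)
  df1 <- k - 1
  df2 <- n_tot - k
  if (ssw == 0) abort("Degenerate input: zero within-group variance.")
  f <- (ssb / df1) / (ssw / df2)
  tibble(
    term = c("group", "Residuals"),
    sumsq = c(ssb, ssw),
    df = c(df1, df2),
    statistic = c(f, NA_real_),
    p.value = c(pf(f, df1, df2, lower.tail = FALSE), NA_real_)
  )
}

#' Bonferroni-corrected planned t-tests
#'
#' Runs a declared plan of pairwise comparisons (Welch's t for unpaired by
#' default, pooled variance by flag; paired t where flagged) and adjusts
#' raw p values by the plan size m: adjusted p = min(1, m * p). The plan —
#' which pairs and hence which m — mirrors per-figure comparison families
#' rather than a single global correction.
#'
#' @param data Data frame with a value column and a group column.
#' @param response,group Column names.
#' @param plan List of 2-element character vectors (group pairs); default
#'   all pairs.
#' @param paired Logical, one per comparison or length 1 (default FALSE).
#'   Paired comparisons require equal-length matched vectors in plan order.
#' @param pool_variance Use the pooled-variance Student t instead of Welch
#'   for unpaired tests (default FALSE).
#' @return A tibble: `group1`, `group2`, `paired`, `estimate`, `statistic`,
#'   `df`, `p.value`, `p.adjusted`, `m`.
#' @export
bonferroni_ttests <- function(data, response, group, plan = NULL,
                              paired = FALSE, pool_variance = FALSE) {
  stopifnot(is.data.frame(data))
  g <- as.character(data[[group]])
  y <- data[[response]]
  lev <- unique(g)
  if (is.null(plan)) {
    plan <- utils::combn(lev, 2, simplify = FALSE)
  }
  m <- length(plan)
  paired <- rep_len(paired, m)
  rows <- purrr::map2_dfr(plan, paired, function(pr, pd) {
    x <- y[g == pr[1]]
    z <- y[g == pr[2]]
    if (length(x) < 2 || length(z) < 2) abort("Each group needs n >= 2.")
    if (pd && length(x) != length(z)) {
      abort("Paired comparisons require equal-length matched vectors.")
    }
    if (isTRUE(all.equal(x, z)) && pd) {
      # zero within-pair variance: t = 0 by convention
      return(tibble(group1 = pr[1], group2 = pr[2], paired = pd,
                    estimate = 0, statistic = 0,
                    df = length(x) - 1, p.value = 1))
    }
    tt <- t.test(x, z, paired = pd, var.equal = !pd && pool_variance)
    tibble(group1 = pr[1], group2 = pr[2], paired = pd,
           estimate = unname(if (pd) tt$estimate else diff(rev(tt$estimate))),
           statistic = unname(tt$statistic), df = unname(tt$parameter),
           p.value = tt$p.value)
  })
  dplyr::mutate(rows, p.adjusted = pmin(1, m * .data$p.value), m = m)
}

#' Waking-peak delay regression
#'
#' Ordinary least squares of waking-peak time (hours) on an exposure index,
#' with coefficient standard errors and R^2. The conventional exposure-index
#' coding assigns consecutive integers 1..k to increasing exposure
#' durations (e.g. points 1-4 for 0, 1, 7 and 30 days) rather than using
#' the day counts themselves.
#'
#' @param x Exposure index (n >= 3 for standard errors; n = 2 reproduces
#'   the two points exactly).
#' @param y Waking-peak times in hours.
#' @return A `delay_regression` object wrapping the `lm` fit with `slope`,
#'   `slope_se`, `intercept`, `intercept_se`, `r_squared`.
#' @examples
#' fit_delay_regression(1:4, 2.469 * (1:4) + 12.55)
#' @export
fit_delay_regression <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 2) abort("Need at least 2 points.")
  if (length(unique(x)) < 2) abort("Constant x: slope undefined.")
  fit <- lm(y ~ x)
  sm <- suppressWarnings(summary(fit))     # exact lines are legitimate input
  co <- sm$coefficients
  structure(
    list(fit = fit,
         slope = unname(co["x", "Estimate"]),
         slope_se = unname(co["x", "Std. Error"]),
         intercept = unname(co["(Intercept)", "Estimate"]),
         intercept_se = unname(co["(Intercept)", "Std. Error"]),
         r_squared = if (is.nan(sm$r.squared)) 0 else sm$r.squared,
         n = length(x)),
    class = "delay_regression"
  )
}

#' @export
print.delay_regression <- function(x, ...) {
  cat(sprintf(
    "<delay_regression> y = %.4g x + %.4g (slope SE %.3g), R^2 = %.3f, n = %d\n",
    x$slope, x$intercept, x$slope_se, x$r_squared, x$n))
  invisible(x)
}
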