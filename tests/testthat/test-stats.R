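test_that("one-way ANOVA F equals the squared two-sample pooled t", {
  set.seed(1)
  df <- data.frame(y = c(rnorm(8), rnorm(8, 1)),
                   g = rep(c("a", "b"), each = 8))
  tab <- anova_table(df, "y", "g")
  tt <- t.test(y ~ g, data = df, var.equal = TRUE)
  expect_equal(tab$statistic[1], unname(tt$statistic)^2, tolerance = 1e-10)
})

test_that("ANOVA matches the from-scratch sums-of-squares oracle", {
  set.seed(99)
  for (rep in 1:100) {
    k <- sample(2:4, 1)
    n <- sample(3:6, k, replace = TRUE)
    g <- rep(letters[1:k], n)
    two_way <- runif(1) < 0.5
    df <- data.frame(y = rnorm(sum(n)), g = g)
    factors <- "g"
    if (two_way) {
      # interleave the second factor so the design is always full rank
      df$h <- rep(c("u", "v"), length.out = sum(n))
      factors <- c("g", "h")
    }
    tab <- anova_table(df, "y", factors)
    ref <- bf_anova_main(df$y, lapply(factors, function(f) df[[f]]))
    for (i in seq_along(factors)) {
      expect_equal(tab$sumsq[i], unname(ref$terms[i, "sumsq"]),
                   tolerance = 1e-8)
      expect_equal(tab$statistic[i], unname(ref$terms[i, "statistic"]),
                   tolerance = 1e-8)
      expect_equal(tab$p.value[i], unname(ref$terms[i, "p.value"]),
                   tolerance = 1e-8)
    }
  }
})

test_that("summary-statistics ANOVA reproduces the hand-computed F", {
  # three groups with the published rhythm-strength layout: unequal n
  means <- c(0.21, 0.14, 0.11); sds <- c(0.02, 0.049, 0.03); ns <- c(5, 5, 9)
  tab <- anova_from_summary(means, sds, ns)
  # oracle: SSB/SSW from first principles
  grand <- sum(ns * means) / sum(ns)
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum((ns - 1) * sds^2)
  f_ref <- (ssb / 2) / (ssw / (sum(ns) - 3))
  expect_equal(tab$statistic[1], f_ref, tolerance = 1e-12)
  expect_lt(tab$p.value[1], 0.001)
  # must agree with raw-data ANOVA on data having exactly these summaries
  raw <- unlist(lapply(1:3, function(i) {
    x <- rnorm(ns[i]); x <- (x - mean(x)) / sd(x) * sds[i] + means[i]
  }))
  df <- data.frame(y = raw, g = rep(c("a", "b", "c"), ns))
  expect_equal(anova_table(df, "y", "g")$statistic[1], tab$statistic[1],
               tolerance = 1e-8)
})

test_that("ANOVA rejects degenerate designs", {
  df <- data.frame(y = rep(1, 10), g = rep(c("a", "b"), 5))
  expect_error(anova_table(df, "y", "g"), "identical")
  expect_error(anova_table(data.frame(y = rnorm(4), g = "a"), "y", "g"),
               "levels")
})

test_that("Bonferroni t-tests match the closed-form Welch oracle", {
  set.seed(4)
  df <- data.frame(y = c(rnorm(9), rnorm(5, 1), rnorm(6, 2)),
                   g = rep(c("a", "b", "c"), c(9, 5, 6)))
  res <- bonferroni_ttests(df, "y", "g")
  expect_identical(nrow(res), 3L)
  for (i in seq_len(3)) {
    ref <- bf_welch(df$y[df$g == res$group1[i]], df$y[df$g == res$group2[i]])
    expect_equal(res$statistic[i], unname(ref["statistic"]), tolerance = 1e-10)
    expect_equal(res$p.value[i], unname(ref["p.value"]), tolerance = 1e-10)
    expect_equal(res$p.adjusted[i], min(1, 3 * res$p.value[i]))
  }
})

test_that("Bonferroni adjustment caps at 1 and is monotone in m", {
  df <- data.frame(y = rnorm(20), g = rep(c("a", "b"), 10))
  r1 <- bonferroni_ttests(df, "y", "g", plan = list(c("a", "b")))
  expect_equal(r1$p.adjusted, min(1, r1$p.value))
  # identical groups: t = 0, p = 1
  df2 <- data.frame(y = rep(c(1, 2, 3), 2), g = rep(c("a", "b"), each = 3))
  r2 <- bonferroni_ttests(df2, "y", "g", paired = TRUE)
  expect_equal(r2$statistic, 0)
  expect_equal(r2$p.value, 1)
  expect_equal(r2$p.adjusted, 1)
  # cap: m = 10 with raw p 0.2 must give 1
  expect_equal(min(1, 10 * 0.2), 1)
  expect_error(bonferroni_ttests(
    data.frame(y = c(1, 2, 3), g = c("a", "a", "b")), "y", "g"), "n >= 2")
  expect_error(bonferroni_ttests(
    data.frame(y = rnorm(7), g = rep(c("a", "b"), c(3, 4))), "y", "g",
    paired = TRUE), "equal-length")
})

test_that("delay regression reproduces exact lines and the OLS oracle", {
  ex <- fit_delay_regression(1:4, 2.469 * (1:4) + 12.55)
  expect_equal(ex$slope, 2.469, tolerance = 1e-12)
  expect_equal(ex$intercept, 12.55, tolerance = 1e-12)
  expect_equal(ex$r_squared, 1, tolerance = 1e-12)
  flat <- fit_delay_regression(1:4, rep(5, 4))
  expect_equal(flat$slope, 0, tolerance = 1e-12)
  expect_equal(flat$r_squared, 0, tolerance = 1e-12)
  two <- fit_delay_regression(c(0, 1), c(3, 7))
  expect_equal(unname(predict(two$fit)), c(3, 7), tolerance = 1e-12)
  expect_error(fit_delay_regression(c(1, 1, 1), 1:3), "Constant")
  set.seed(6)
  x <- runif(10); y <- 2 * x + rnorm(10)
  fit <- fit_delay_regression(x, y)
  ref <- bf_ols(x, y)
  g <- glance(fit)
  expect_equal(g$slope, unname(ref["slope"]), tolerance = 1e-10)
  expect_equal(g$slope_se, unname(ref["slope_se"]), tolerance = 1e-10)
  expect_equal(g$intercept_se, unname(ref["intercept_se"]), tolerance = 1e-10)
  expect_equal(g$r_squared, unname(ref["r_squared"]), tolerance = 1e-10)
})

test_that("tidiers return broom-shaped tibbles", {
  fit <- fit_delay_regression(1:5, c(2, 4, 5, 8, 10))
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error", "statistic", "p.value"))
  tr <- simulate_activity(activity_params(days = 3, seed = 2))
  expect_named(glance(dfa(tr)),
               c("alpha", "fit_r2", "fit_lo_h", "fit_hi_h", "n_sizes_fit"))
  expect_s3_class(tidy(periodogram(tr, period_grid_h = seq(20, 28, 1))),
                  "tbl_df")
})
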