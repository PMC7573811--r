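test_that("rebinning conserves counts and handles edge cases", {
  tr <- simulate_activity(activity_params(days = 2, seed = 5))
  tr6 <- bin_activity(tr, 360)
  expect_equal(sum(tr6$count), sum(tr$count))
  expect_identical(nrow(tr6), nrow(tr) %/% 6L)
  expect_identical(bin_activity(tr, 60), tr)
  ones <- activity_trace(rep(1, 2880), 60)
  expect_true(all(bin_activity(ones, 120)$count == 2))
  expect_error(bin_activity(tr, 90), "multiple")
})

test_that("DFA matches the brute-force windowed oracle to 1e-10 relative", {
  set.seed(31)
  counts <- pmax(0, 50 + 20 * rnorm(10000))
  tr <- activity_trace(counts, 60)
  res <- dfa(tr)
  tab <- tidy(res)
  for (i in seq_len(nrow(tab))) {
    expect_equal(tab$fluctuation[i],
                 bf_dfa_fluctuation(counts, tab$n_bins[i]),
                 tolerance = 1e-10)
  }
})

test_that("DFA is exactly invariant to positive affine transforms", {
  set.seed(8)
  counts <- rpois(6000, 30)
  a1 <- dfa(activity_trace(counts, 60))$alpha
  a2 <- dfa(activity_trace(3.5 * counts + 11, 60))$alpha
  expect_equal(a1, a2, tolerance = 1e-12)
})

test_that("DFA recovers theoretical exponents for white and integrated noise", {
  set.seed(101)
  white <- matrix(rnorm(21600 * 4), ncol = 4)
  a_white <- apply(white, 2, function(w)
    dfa(activity_trace(w - min(w), 60))$alpha)
  expect_equal(mean(a_white), 0.5, tolerance = 0.05)
  a_brown <- apply(white, 2, function(w) {
    b <- cumsum(w)
    dfa(activity_trace(b - min(b), 60))$alpha
  })
  expect_equal(mean(a_brown), 1.5, tolerance = 0.1)
})

test_that("DFA result structure and degenerate inputs behave as contracted", {
  tr <- simulate_activity(activity_params(days = 3, seed = 2))
  res <- dfa(tr)
  tab <- tidy(res)
  expect_true(all(tab$fluctuation > 0))
  expect_true(all(tab$n_windows[tab$in_fit] >= 4))
  expect_true(is.finite(res$alpha))
  expect_gte(res$fit_r2, 0)
  expect_error(dfa(activity_trace(rep(5, 5000), 60)), "Constant")
  short <- activity_trace(rpois(600, 20), 60)  # 10 h: 3-h windows lack 4 reps
  expect_error(dfa(short), "not covered")
})

test_that("short traces drop unreliable window sizes with a warning", {
  set.seed(3)
  tr <- activity_trace(rpois(1500, 20), 60)   # 25 h < 4 x 8 h
  expect_warning(res <- dfa(tr), "fewer than 4 repetitions")
  expect_true(all(tidy(res)$n_windows[tidy(res)$in_fit] >= 4))
})

test_that("periodogram statistic matches the naive fold and is shift-invariant", {
  set.seed(12)
  counts <- rpois(4320, 20) + rep(c(30, 0), each = 720)  # 24-h square wave
  tr <- activity_trace(counts, 60)
  res <- periodogram(tr, period_grid_h = c(22, 24, 26))
  for (i in 1:3) {
    expect_equal(res$table$statistic[i],
                 bf_eta2(counts, round(res$table$period_h[i] * 60)),
                 tolerance = 1e-12)
  }
  shifted <- periodogram(activity_trace(counts + 100, 60),
                         period_grid_h = c(22, 24, 26))
  expect_equal(res$table$statistic, shifted$table$statistic,
               tolerance = 1e-12)
  expect_equal(res$peak_period_h, 24)
})

test_that("an injected non-24-h period is recovered within one grid step", {
  # free-run emulation: 24.4-h gate built directly into the intensity
  set.seed(77)
  n <- 15 * 1440
  t_h <- (seq_len(n) - 0.5) / 60
  lam <- 50 * (1 + 0.9 * cos(2 * pi * t_h / 24.4)) + 20 * rnorm(n)
  tr <- activity_trace(rpois(n, pmax(lam, 0)), 60)
  res <- periodogram(tr)
  expect_lte(abs(res$peak_period_h - 24.4), 0.05 + 1e-9)
})

test_that("white noise shows no significant rhythm", {
  set.seed(5)
  tr <- activity_trace(rpois(15 * 1440, 30), 60)
  res <- periodogram(tr)
  expect_false(res$peak_significant)
  expect_lt(res$strength, res$table$threshold[match(res$peak_period_h,
                                                    res$table$period_h)])
})

test_that("periodogram rejects short or constant traces and bad grids", {
  tr <- simulate_activity(activity_params(days = 2, seed = 1))
  expect_error(periodogram(tr), "2 cycles")
  expect_error(periodogram(activity_trace(rep(3, 21600), 60)), "Constant")
  long <- simulate_activity(activity_params(days = 3, seed = 1))
  expect_error(periodogram(long, period_grid_h = 24.0001), "whole number")
})
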