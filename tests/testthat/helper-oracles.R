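# Independent reference implementations used as oracles. These are kept
# deliberately naive (explicit loops, closed-form algebra) and independent of
# the package's vectorized code paths.

# brute-force DFA fluctuation: explicit loop over non-overlapping windows,
# per-window lm() detrend
bf_dfa_fluctuation <- function(x, n_win) {
  profile <- cumsum(x - mean(x))
  n_seg <- length(profile) %/% n_win
  ss <- 0
  for (w in seq_len(n_seg)) {
    seg <- profile[((w - 1) * n_win + 1):(w * n_win)]
    t <- seq_len(n_win)
    fit <- stats::lm(seg ~ t)
    ss <- ss + sum(stats::resid(fit)^2)
  }
  sqrt(ss / (n_seg * n_win))
}

# naive folded-periodogram statistic (variance explained at one period)
bf_eta2 <- function(x, m) {
  cls <- (seq_along(x) - 1) %% m
  gm <- mean(x)
  ssb <- 0
  for (h in 0:(m - 1)) {
    xi <- x[cls == h]
    ssb <- ssb + length(xi) * (mean(xi) - gm)^2
  }
  ssb / sum((x - gm)^2)
}

# from-scratch OLS residual sum of squares on an explicit design matrix
bf_rss <- function(y, X) {
  beta <- qr.solve(qr(X), y)
  sum((y - X %*% beta)^2)
}

# from-scratch Type-II main-effects ANOVA: SS(term | other terms) via RSS
# differences of hand-built dummy-coded design matrices
bf_anova_main <- function(y, factors) {
  dummies <- lapply(factors, function(f) {
    f <- factor(f)
    stats::model.matrix(~f)[, -1, drop = FALSE]
  })
  ones <- matrix(1, length(y), 1)
  full <- do.call(cbind, c(list(ones), dummies))
  rss_full <- bf_rss(y, full)
  df_res <- length(y) - ncol(full)
  out <- lapply(seq_along(dummies), function(i) {
    reduced <- do.call(cbind, c(list(ones), dummies[-i]))
    ss <- bf_rss(y, reduced) - rss_full
    df <- ncol(dummies[[i]])
    f_stat <- (ss / df) / (rss_full / df_res)
    c(sumsq = ss, df = df, statistic = f_stat,
      p.value = stats::pf(f_stat, df, df_res, lower.tail = FALSE))
  })
  list(terms = do.call(rbind, out), rss = rss_full, df_res = df_res)
}

# closed-form Welch t-test
bf_welch <- function(x, z) {
  vx <- var(x) / length(x); vz <- var(z) / length(z)
  t_stat <- (mean(x) - mean(z)) / sqrt(vx + vz)
  df <- (vx + vz)^2 / (vx^2 / (length(x) - 1) + vz^2 / (length(z) - 1))
  p <- 2 * stats::pt(-abs(t_stat), df)
  c(statistic = t_stat, df = df, p.value = p)
}

# closed-form simple-regression coefficients and standard errors
bf_ols <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  b <- sum((x - mean(x)) * (y - mean(y))) / sxx
  a <- mean(y) - b * mean(x)
  res <- y - a - b * x
  s2 <- sum(res^2) / (n - 2)
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  c(slope = b, intercept = a,
    slope_se = sqrt(s2 / sxx),
    intercept_se = sqrt(s2 * (1 / n + mean(x)^2 / sxx)),
    r_squared = r2)
}

# step-by-step homeostat integrator at fine resolution (dt_s seconds)
bf_process_s <- function(states, s0, tau_rise_h, tau_decay_h,
                         epoch_seconds = 4, dt_s = 4) {
  steps <- epoch_seconds / dt_s
  s <- s0
  out <- numeric(length(states))
  for (i in seq_along(states)) {
    for (k in seq_len(steps)) {
      if (states[i] == "NREM") {
        s <- s * exp(-dt_s / 3600 / tau_decay_h)
      } else {
        s <- 1 + (s - 1) * exp(-dt_s / 3600 / tau_rise_h)
      }
    }
    out[i] <- s
  }
  out
}

# wrap hand-built signals into the recording container
make_recording <- function(eeg, emg = NULL, fs = 128L,
                           schedule = light_schedule()) {
  if (is.null(emg)) emg <- numeric(length(eeg))
  structure(list(eeg = eeg, emg = emg, fs = fs,
                 start_zt_h = 0, schedule = schedule),
            class = "eeg_recording")
}

# one simulated day is the workhorse sleep fixture; cache it across files
.sim_cache <- new.env(parent = emptyenv())
cached_day_sim <- function(seed = 1, ...) {
  key <- paste(seed, ..., sep = "_")
  if (!exists(key, envir = .sim_cache)) {
    assign(key,
           simulate_recording(eeg_gen_params(days = 1, seed = seed, ...)),
           envir = .sim_cache)
  }
  get(key, envir = .sim_cache)
}

# hand-built hypnogram from state codes
make_hypnogram <- function(states, epoch_seconds = 4, start_zt_h = 0) {
  noxlux:::new_hypnogram(states, epoch_seconds = epoch_seconds,
                         start_zt_h = start_zt_h)
}
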