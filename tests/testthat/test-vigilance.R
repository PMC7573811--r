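test_that("the scorer reproduces simulator ground truth epoch by epoch", {
  sim <- cached_day_sim(seed = 1)
  sp <- detect_artifacts(epoch_and_fft(sim$recording), sim$recording)
  hyp <- score_epochs(sp)
  expect_identical(nrow(hyp), nrow(sim$hypnogram))
  expect_false(anyNA(hyp$state))
  expect_gt(scoring_agreement(hyp, sim$hypnogram), 0.9)
  # deterministic: no RNG involved
  expect_identical(as.character(score_epochs(sp)$state),
                   as.character(hyp$state))
})

test_that("the rule cascade ranks EMG above spectra and theta above delta", {
  sim <- cached_day_sim(seed = 1)
  sp <- epoch_and_fft(sim$recording)
  # force a huge EMG on an epoch the simulator made NREM: must score WAKE
  st <- as.character(sim$hypnogram$state)
  i_nrem <- which(st == "NREM")[100]
  sp2 <- sp
  sp2$epochs$emg_rms[i_nrem] <- 10 * max(sp$epochs$emg_rms)
  expect_identical(as.character(score_epochs(sp2, smooth = FALSE)$state[i_nrem]),
                   "WAKE")
  # low-EMG epoch with theta dominating delta must score REM
  i_rem <- which(st == "REM" & !zt_is_dark(sim$hypnogram$zt_h))[50]
  expect_identical(as.character(score_epochs(sp, smooth = FALSE)$state[i_rem]),
                   "REM")
})

test_that("degenerate distributions fall back to quantile thresholds", {
  # all epochs identical: no bimodality anywhere
  sp <- epoch_and_fft(make_recording(rep(sin(2 * pi * 2 * (0:511) / 128), 50),
                                     emg = rnorm(512 * 50)))
  expect_warning(score_epochs(sp), "not bimodal")
})

test_that("majority smoothing removes single-epoch flicker only", {
  s <- c("WAKE", "WAKE", "NREM", "WAKE", "WAKE", "NREM", "NREM", "REM", "REM")
  sm <- noxlux:::majority_smooth(s)
  expect_identical(sm[3], "WAKE")
  expect_identical(sm[6:9], s[6:9])
})

test_that("state percentages sum to 100 and conserve epochs", {
  hyp <- cached_day_sim(seed = 1)$hypnogram
  for (bh in c(2, 6, 12, 24)) {
    tc <- state_percent_timecourse(hyp, bh)
    sums <- tc |> dplyr::group_by(day, bin_start_zt) |>
      dplyr::summarise(s = sum(percent), n = sum(n_epochs), .groups = "drop")
    expect_equal(sums$s, rep(100, nrow(sums)), tolerance = 1e-9)
    expect_identical(sum(tc$n_epochs), nrow(hyp))
  }
  expect_error(state_percent_timecourse(hyp, 5), "one of")
  # interval labels follow light/dark halves and day index
  tc12 <- state_percent_timecourse(hyp, 12)
  expect_setequal(unique(tc12$interval), c("L1", "D1"))
})

test_that("an all-WAKE hypnogram is 100% waking in every bin", {
  hyp <- make_hypnogram(rep("WAKE", 21600))
  tc <- state_percent_timecourse(hyp, 6)
  expect_true(all(tc$percent[tc$state == "WAKE"] == 100))
  expect_true(all(tc$percent[tc$state != "WAKE"] == 0))
})

test_that("partial trailing bins are rejected unless allowed", {
  hyp <- make_hypnogram(rep("WAKE", 1000))    # 1000 epochs != whole 2-h bins
  expect_error(state_percent_timecourse(hyp, 2), "whole bins")
  tc <- state_percent_timecourse(hyp, 2, allow_partial = TRUE)
  expect_s3_class(tc, "state_timecourse")
})

test_that("waking peak uses bin midpoints with earliest-bin tie-breaking", {
  # hand-built day: wake maximal in ZT12-14, tie at ZT20-22
  states <- rep("NREM", 21600)
  zt <- (seq_len(21600) - 0.5) * 4 / 3600
  states[zt >= 12 & zt < 14] <- "WAKE"
  states[zt >= 20 & zt < 22] <- "WAKE"
  tc <- state_percent_timecourse(make_hypnogram(states), 2)
  pk <- waking_peak(tc)
  expect_equal(pk$peak_zt_h, 13)
  expect_equal(pk$peak_value, 100)
  expect_error(waking_peak(tc, interval = c(13, 13.5)), "Empty")
})

test_that("simulated gate delays move the ground-truth waking peak", {
  pks <- vapply(c(0, 4), function(d) {
    hyp <- simulate_recording(eeg_gen_params(days = 1, phase_delay_h = d,
                                             seed = 11))$hypnogram
    waking_peak(state_percent_timecourse(hyp, 2))$peak_zt_h
  }, numeric(1))
  expect_equal(pks[2] - pks[1], 4, tolerance = 2)
})

test_that("daily amplitude is dark minus light and needs both halves", {
  hyp <- cached_day_sim(seed = 1)$hypnogram
  tc <- state_percent_timecourse(hyp, 2)
  amp <- daily_amplitude(tc)
  wake_amp <- amp$amplitude[amp$state == "WAKE"]
  expect_gt(wake_amp, 0)                      # nocturnal animal
  expect_true(all(abs(amp$amplitude) <= 100))
  # arithmetic check against direct means
  dark <- tc$percent[tc$state == "WAKE" & tc$bin_start_zt >= 12]
  light <- tc$percent[tc$state == "WAKE" & tc$bin_start_zt < 12]
  expect_equal(wake_amp, mean(dark) - mean(light), tolerance = 1e-12)
  half <- state_percent_timecourse(make_hypnogram(rep("WAKE", 10800)), 2)
  expect_error(daily_amplitude(half), "both")
})

test_that("recovery-vs-baseline differences align bins and subtract", {
  hyp <- cached_day_sim(seed = 1)$hypnogram
  tc <- state_percent_timecourse(hyp, 2)
  self <- compare_recovery_to_baseline(tc, tc)
  expect_true(all(self$difference == 0))
  tc6 <- state_percent_timecourse(hyp, 6)
  expect_error(compare_recovery_to_baseline(tc, tc6), "Misaligned")
})

test_that("sleep deprivation produces an NREM rebound in the recovery light phase", {
  sim <- simulate_recording(eeg_gen_params(days = 2, seed = 5),
                            sd = sd_protocol(0, 6))
  tc <- state_percent_timecourse(sim$hypnogram, 2)
  diffs <- compare_recovery_to_baseline(tc, tc, baseline_day = 1,
                                        recovery_day = 2)
  post_sd_light <- diffs$bin_start_zt >= 6 & diffs$bin_start_zt < 12
  nrem_reb <- diffs$difference[post_sd_light & diffs$state == "NREM"]
  expect_gt(mean(nrem_reb), 0)
})
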