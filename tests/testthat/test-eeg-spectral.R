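test_that("a pure 2-Hz unit tone puts exactly 0.5 uV^2 in its bin", {
  t_s <- (0:511) / 128
  rec <- make_recording(sin(2 * pi * 2 * t_s))
  sp <- epoch_and_fft(rec)
  expect_identical(nrow(sp$power), 1L)
  expect_equal(sp$power[1, "2.00"], c("2.00" = 0.5), tolerance = 1e-12)
  expect_equal(sum(sp$power[1, ]), 0.5, tolerance = 1e-12)
  expect_equal(band_power(sp, "delta"), 0.5, tolerance = 1e-12)
  expect_equal(band_power(sp, "theta"), 0, tolerance = 1e-12)
})

test_that("zero signal yields all-zero spectra; non-finite input is rejected", {
  sp <- epoch_and_fft(make_recording(numeric(1024)))
  expect_true(all(sp$power == 0))
  expect_error(epoch_and_fft(make_recording(c(NA, numeric(511)))),
               "Non-finite")
  bad <- make_recording(numeric(512)); bad$fs <- 256L
  expect_error(epoch_and_fft(bad), "128")
  expect_error(epoch_and_fft(make_recording(numeric(100))), "one 4-s epoch")
})

test_that("Parseval holds per epoch to 1e-9 relative", {
  sim <- cached_day_sim(seed = 1)
  sp <- epoch_and_fft(sim$recording)
  idx <- seq(1, 21600, by = 97)
  eeg <- matrix(sim$recording$eeg, nrow = 512)
  for (e in idx) {
    v <- mean((eeg[, e] - mean(eeg[, e]))^2)
    expect_equal(sp$epochs$total_power[e], v, tolerance = 1e-9)
  }
})

test_that("white-noise mean spectrum is flat", {
  set.seed(2)
  sp <- epoch_and_fft(make_recording(rnorm(512 * 40000)))
  m <- colMeans(sp$power)
  expect_lt(max(abs(m / mean(m) - 1)), 0.02)
  expect_equal(mean(m), 2 / 256, tolerance = 0.02)   # unit variance spread evenly
})

test_that("band powers are additive and band edges validate", {
  sim <- cached_day_sim(seed = 1)
  sp <- epoch_and_fft(sim$recording)
  total <- band_power(sp, band_definition("all", 0.25, 25))
  lo <- band_power(sp, band_definition("lo", 0.25, 4))
  hi <- band_power(sp, band_definition("hi", 4.25, 25))
  expect_equal(total, lo + hi, tolerance = 1e-12)
  expect_equal(total, rowSums(sp$power), tolerance = 1e-12)
  expect_error(band_definition("x", 0.1, 4), "0.25")
  expect_error(band_definition("x", 1, 26), "25")
  expect_error(band_definition("x", 1.1, 4), "multiples")
})

test_that("artifact detection flags spikes and flatlines, not neighbours", {
  set.seed(11)
  eeg <- rnorm(512 * 50)
  spike_at <- 512 * 24 + 100                  # inside epoch 25
  eeg[spike_at:(spike_at + 5)] <- 10 * max(abs(eeg))
  rec <- make_recording(eeg)
  sp <- detect_artifacts(epoch_and_fft(rec), rec)
  expect_true(sp$epochs$artifact[25])
  expect_false(sp$epochs$artifact[24])
  expect_false(sp$epochs$artifact[26])
  flat <- detect_artifacts(epoch_and_fft(make_recording(numeric(1024))),
                           make_recording(numeric(1024)))
  expect_true(all(flat$epochs$artifact))
})

test_that("a clean simulated recording has under 1% flagged epochs", {
  sim <- cached_day_sim(seed = 1)
  sp <- detect_artifacts(epoch_and_fft(sim$recording), sim$recording)
  expect_lt(mean(sp$epochs$artifact), 0.01)
})

test_that("artifact epochs become missing in band power and spectra means", {
  sim <- cached_day_sim(seed = 1)
  sp <- epoch_and_fft(sim$recording)
  sp$epochs$artifact[5] <- TRUE
  expect_true(is.na(band_power(sp, "swa")[5]))
  ss1 <- state_spectra(sp, sim$hypnogram)
  sp$epochs$artifact[5] <- FALSE
  ss2 <- state_spectra(sp, sim$hypnogram)
  st5 <- as.character(sim$hypnogram$state[5])
  expect_false(isTRUE(all.equal(ss1$power[ss1$state == st5],
                                ss2$power[ss2$state == st5])))
})

test_that("state spectra are permutation-invariant and handle empty states", {
  sim <- cached_day_sim(seed = 1)
  sp <- epoch_and_fft(sim$recording)
  n <- 3000
  sp_small <- sp
  sp_small$power <- sp$power[seq_len(n), ]
  sp_small$epochs <- sp$epochs[seq_len(n), ]
  hyp <- sim$hypnogram[seq_len(n), ]
  class(hyp) <- class(sim$hypnogram)
  attr(hyp, "epoch_seconds") <- 4; attr(hyp, "start_zt_h") <- 0
  ss <- state_spectra(sp_small, hyp)
  set.seed(1); perm <- sample(n)
  sp_perm <- sp_small
  sp_perm$power <- sp_small$power[perm, ]
  sp_perm$epochs <- sp_small$epochs[perm, ]
  hyp_perm <- hyp[perm, ]
  class(hyp_perm) <- class(hyp)
  attr(hyp_perm, "epoch_seconds") <- 4; attr(hyp_perm, "start_zt_h") <- 0
  ss_perm <- state_spectra(sp_perm, hyp_perm)
  expect_equal(ss$power, ss_perm$power, tolerance = 1e-12)
  # all-NREM hypnogram: NREM spectrum equals the grand mean, others missing
  all_n <- make_hypnogram(rep("NREM", n))
  ss_n <- state_spectra(sp_small, all_n)
  expect_equal(ss_n$power[ss_n$state == "NREM"],
               unname(colMeans(sp_small$power)), tolerance = 1e-12)
  expect_true(all(is.na(ss_n$power[ss_n$state != "NREM"])))
})

test_that("SWA timecourse bins align to ZT and empty bins are missing", {
  sim <- simulate_recording(eeg_gen_params(days = 2, seed = 5),
                            sd = sd_protocol(0, 6))
  sp <- epoch_and_fft(sim$recording)
  swa <- swa_timecourse(sp, sim$hypnogram)
  expect_identical(nrow(swa), 24L)            # 2 days x 12 bins
  sd_bins <- swa$day == 2 & swa$bin_start_zt < 6
  expect_true(all(is.na(swa$swa[sd_bins])))
  expect_true(all(swa$n_epochs[sd_bins] == 0))
  expect_true(all(swa$swa[!sd_bins] > 0))
  # baseline day: SWA discharges across the light phase from its dark peak
  d1 <- swa[swa$day == 1 & swa$bin_start_zt < 12, ]
  expect_gt(d1$swa[1], d1$swa[6])
})
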