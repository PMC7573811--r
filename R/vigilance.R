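# Deterministic 1D two-class split (Otsu): threshold maximizing
# between-class variance. Returns the threshold and the fraction of total
# variance it explains (separation quality).
otsu_split <- function(x) {
  xs <- sort(x)
  n <- length(xs)
  cs <- cumsum(xs)
  tot <- cs[n]
  k <- seq_len(n - 1)
  m1 <- cs[k] / k
  m2 <- (tot - cs[k]) / (n - k)
  between <- k * (n - k) * (m1 - m2)^2 / n^2
  best <- which.max(between)
  list(threshold = (xs[best] + xs[best + 1]) / 2,
       quality = between[best] / max(var(x) * (n - 1) / n, .Machine$double.eps))
}

majority_smooth <- function(states) {
  n <- length(states)
  if (n < 3) return(states)
  prev <- c(states[1], states[-n])
  nxt <- c(states[-1], states[n])
  out <- states
  flip_prev <- prev == nxt & prev != states
  out[flip_prev] <- prev[flip_prev]
  out
}

#' Rule-based vigilance-state scoring of 4-s epochs
#'
#' Automated stand-in for visual scoring, cascading per epoch: integrated
#' EMG above its adaptive threshold scores WAKE; otherwise a
#' theta(6.25-9.0 Hz)/delta(0.75-4.0 Hz) power ratio above its adaptive
#' threshold scores REM; otherwise NREM. Thresholds are set per recording by
#' a deterministic bimodal split (Otsu) of the log EMG distribution and of
#' the log theta/delta ratio among low-EMG epochs; if a distribution shows
#' no usable bimodality the scorer falls back to fixed quantile thresholds
#' with a warning. A 3-epoch majority filter suppresses single-epoch
#' flicker. Every epoch receives a state, including artifact-flagged ones;
#' scoring involves no randomness.
#'
#' Accuracy is only ever measured against the simulator's ground truth; no
#' claim of replicating human visual scoring is made.
#'
#' @param spectra An `epoch_spectra` including `emg_rms`.
#' @param smooth Apply the 3-epoch majority filter (default TRUE).
#' @param min_quality Minimal Otsu between-class variance fraction before
#'   falling back to quantile thresholds (default 0.3).
#' @return A `hypnogram` tibble: `epoch`, `epoch_start_s`, `zt_h`, `state`,
#'   `artifact`.
#' @export
score_epochs <- function(spectra, smooth = TRUE, min_quality = 0.3) {
  stopifnot(inherits(spectra, "epoch_spectra"))
  n <- nrow(spectra$power)
  lemg <- log10(pmax(spectra$epochs$emg_rms, .Machine$double.xmin))
  sp_emg <- otsu_split(lemg)
  if (sp_emg$quality < min_quality) {
    warn("EMG distribution not bimodal; falling back to the median threshold.")
    thr_emg <- median(lemg)
  } else {
    thr_emg <- sp_emg$threshold
  }
  wake <- lemg > thr_emg
  delta <- rowSums(spectra$power[, band_bins(band_presets("delta")),
                                 drop = FALSE])
  theta <- rowSums(spectra$power[, band_bins(band_presets("theta")),
                                 drop = FALSE])
  ratio <- log10(pmax(theta, .Machine$double.xmin) /
                   pmax(delta, .Machine$double.xmin))
  states <- rep("NREM", n)
  states[wake] <- "WAKE"
  sleep_ratio <- ratio[!wake]
  if (length(sleep_ratio) >= 2) {
    sp_r <- otsu_split(sleep_ratio)
    if (sp_r$quality < min_quality) {
      warn("Theta/delta ratio not bimodal; falling back to the 0.9 quantile.")
      thr_r <- quantile(sleep_ratio, 0.9, names = FALSE)
    } else {
      thr_r <- sp_r$threshold
    }
    states[!wake][sleep_ratio > thr_r] <- "REM"
  }
  if (smooth) states <- majority_smooth(states)
  new_hypnogram(states, artifact = spectra$epochs$artifact,
                epoch_seconds = spectra$epoch_seconds,
                start_zt_h = spectra$start_zt_h)
}

#' Epoch agreement between two hypnograms
#'
#' @param scored,truth `hypnogram`s of equal length.
#' @return Fraction of epochs with identical state.
#' @export
scoring_agreement <- function(scored, truth) {
  stopifnot(nrow(scored) == nrow(truth))
  mean(as.character(scored$state) == as.character(truth$state))
}

#' Vigilance-state percentage timecourse
#'
#' Percentage of recording time spent in each state per ZT-aligned clock
#' bin. Interval labels follow the light schedule and day index: `L1`/`D1`
#' for the baseline light and dark/dim halves, `L2`/`D2` for the following
#' day, and so on. Within each bin the three percentages sum to 100.
#'
#' @param hypnogram A `hypnogram`.
#' @param bin_hours One of 2, 6, 12, 24.
#' @param allow_partial Keep a partial trailing bin (default FALSE:
#'   rejected).
#' @return A tibble (class `state_timecourse`), long format: `day`,
#'   `bin_start_zt`, `bin_mid_zt`, `interval`, `state`, `percent`,
#'   `n_epochs`.
#' @export
state_percent_timecourse <- function(hypnogram, bin_hours = 2,
                                     allow_partial = FALSE) {
  stopifnot(inherits(hypnogram, "hypnogram"))
  if (!bin_hours %in% c(2, 6, 12, 24)) {
    abort("`bin_hours` must be one of 2, 6, 12, 24.")
  }
  eps <- attr(hypnogram, "epoch_seconds")
  per_bin <- bin_hours * 3600 / eps
  if (nrow(hypnogram) %% per_bin != 0 && !allow_partial) {
    abort("Recording does not cover whole bins (set `allow_partial` to keep).")
  }
  ep_h <- (hypnogram$epoch - 1) * eps / 3600 + attr(hypnogram, "start_zt_h")
  df <- hypnogram |>
    dplyr::mutate(
      day = floor(ep_h / 24) + 1,
      bin_start_zt = floor((ep_h %% 24) / bin_hours) * bin_hours
    ) |>
    dplyr::count(.data$day, .data$bin_start_zt, .data$state,
                 .drop = FALSE, name = "n_epochs") |>
    dplyr::group_by(.data$day, .data$bin_start_zt) |>
    dplyr::mutate(percent = 100 * .data$n_epochs / sum(.data$n_epochs)) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.nan(.data$percent)) |>
    dplyr::mutate(
      bin_mid_zt = .data$bin_start_zt + bin_hours / 2,
      interval = paste0(ifelse(.data$bin_start_zt < 12, "L", "D"), .data$day)
    ) |>
    dplyr::select("day", "bin_start_zt", "bin_mid_zt", "interval", "state",
                  "percent", "n_epochs")
  structure(df, class = c("state_timecourse", class(df)),
            bin_hours = bin_hours, epoch_seconds = eps)
}

#' Waking-peak time within an interval
#'
#' The peak is reported as the midpoint of the 2-h bin with maximal WAKE
#' percentage inside the search interval (default: the dark/dim half,
#' ZT 12-24); ties go to the earliest bin.
#'
#' @param timecourse A `state_timecourse` at 2-h resolution.
#' @param interval `c(zt_lo, zt_hi)` search window (bins must lie fully
#'   inside).
#' @param day Which recording day to search (default 1).
#' @return A list (class `peak_result`): `peak_zt_h`, `peak_value`,
#'   `search_interval`.
#' @export
waking_peak <- function(timecourse, interval = c(12, 24), day = 1) {
  stopifnot(inherits(timecourse, "state_timecourse"))
  bh <- attr(timecourse, "bin_hours")
  if (bh != 2) abort("`waking_peak()` expects a 2-h timecourse.")
  zt_lo <- interval[1]; zt_hi <- interval[2]
  cand <- timecourse |>
    dplyr::filter(.data$state == "WAKE", .data$day == !!day,
                  .data$bin_start_zt >= !!zt_lo,
                  .data$bin_start_zt + bh <= !!zt_hi + 1e-9) |>
    dplyr::arrange(.data$bin_start_zt)
  if (nrow(cand) == 0) abort("Empty search interval.")
  best <- which.max(cand$percent)           # which.max takes the earliest tie
  structure(list(peak_zt_h = cand$bin_mid_zt[best],
                 peak_value = cand$percent[best],
                 search_interval = interval),
            class = "peak_result")
}

#' Day-night amplitude of vigilance-state rhythms
#'
#' Per state, the dark/dim 12-h mean percentage minus the light 12-h mean
#' percentage over one full baseline day. A strongly nocturnal animal has a
#' positive WAKE amplitude.
#'
#' @param timecourse A `state_timecourse` covering the full day.
#' @param day Which recording day (default 1).
#' @return A tibble: `state`, `dark_percent`, `light_percent`, `amplitude`.
#' @export
daily_amplitude <- function(timecourse, day = 1) {
  stopifnot(inherits(timecourse, "state_timecourse"))
  df <- dplyr::filter(timecourse, .data$day == !!day)
  halves <- sort(unique(ifelse(df$bin_start_zt < 12, "light", "dark")))
  if (!identical(halves, c("dark", "light"))) {
    abort("Need both the light and the dark/dim half of the day.")
  }
  df |>
    dplyr::mutate(half = ifelse(.data$bin_start_zt < 12, "light", "dark")) |>
    dplyr::group_by(.data$state, .data$half) |>
    dplyr::summarise(percent = mean(.data$percent), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "half", values_from = "percent",
                       names_glue = "{half}_percent") |>
    dplyr::mutate(amplitude = .data$dark_percent - .data$light_percent)
}

#' Paired recovery-minus-baseline differences
#'
#' Joins two state timecourses on clock bin and state and returns the
#' per-bin recovery minus baseline differences, ready for paired tests. The
#' post-deprivation 6-h light segment should be compared to the
#' corresponding clock-time baseline segment, which this alignment does by
#' construction.
#'
#' @param baseline,recovery `state_timecourse`s with identical bin
#'   structure (clock bins present in `recovery` must exist in `baseline`).
#' @param baseline_day,recovery_day Day indices to compare (defaults 1).
#' @return A tibble: `bin_start_zt`, `interval`, `state`,
#'   `baseline_percent`, `recovery_percent`, `difference`.
#' @export
compare_recovery_to_baseline <- function(baseline, recovery,
                                         baseline_day = 1, recovery_day = 1) {
  stopifnot(inherits(baseline, "state_timecourse"),
            inherits(recovery, "state_timecourse"))
  if (!identical(attr(baseline, "bin_hours"), attr(recovery, "bin_hours"))) {
    abort("Misaligned bins: the two timecourses use different bin widths.")
  }
  bl <- dplyr::filter(baseline, .data$day == !!baseline_day) |>
    dplyr::select("bin_start_zt", "interval", "state",
                  baseline_percent = "percent")
  rc <- dplyr::filter(recovery, .data$day == !!recovery_day) |>
    dplyr::select("bin_start_zt", "state", recovery_percent = "percent")
  out <- dplyr::inner_join(bl, rc, by = c("bin_start_zt", "state"))
  if (nrow(out) != nrow(rc)) {
    abort("Misaligned bins: recovery bins missing from the baseline.")
  }
  dplyr::mutate(out, difference = .data$recovery_percent -
                  .data$baseline_percent)
}
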