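#' Parameters for the rest-activity simulator
#'
#' Defaults describe a healthy, strongly nocturnal mouse recorded by a passive
#' infrared (PIR) detector for 15 days in 1-min bins: a circadian gate
#' confining activity to the dark/dim half of the 12:12 cycle, a pink
#' (1/f, `fractal_beta = 1`) fractal component, and Poisson count noise.
#'
#' @param days Number of recorded days (>= 2, default 15).
#' @param bin_seconds Bin length in seconds (default 60).
#' @param mean_rate Baseline counts per bin (> 0, default 50).
#' @param circadian_amplitude Relative day-night modulation depth in \[0, 1\]
#'   (default 0.9). 0 removes the circadian gate (and onset surge) entirely.
#' @param fractal_beta Spectral exponent beta of the 1/f^beta fractal
#'   component; the DFA scaling target is alpha = (beta + 1) / 2. Default 1.
#' @param fractal_sd_frac Standard deviation of the fractal component as a
#'   fraction of `mean_rate` (default 1.5, a within-night coefficient of
#'   variation near 1, as PIR count data show).
#' @param surge_frac Amplitude of the sharp dark-onset activity surge as a
#'   fraction of `mean_rate` (default 4.2, scaled by the effective
#'   amplitude); width set by `surge_width_h` (default 0.5 h).
#' @param surge_width_h Gaussian width of the onset surge in hours.
#' @param phase_delay_h Hours (>= 0) by which the nocturnal activity gate is
#'   delayed, emulating the activity-onset delay seen under dim light at
#'   night. Default 0.
#' @param disruption Rhythm degradation in \[0, 1\]: scales the circadian
#'   amplitude down by (1 - disruption) and adds white night-phase noise
#'   proportional to `disruption`. 0 = intact rhythm.
#' @param seed RNG seed (required; the simulator is bit-reproducible given it).
#' @return An object of class `activity_params`.
#' @export
activity_params <- function(days = 15, bin_seconds = 60, mean_rate = 50,
                            circadian_amplitude = 0.9, fractal_beta = 1,
                            fractal_sd_frac = 1.5, surge_frac = 4.2,
                            surge_width_h = 0.5, phase_delay_h = 0,
                            disruption = 0, seed = 1L) {
  if (!is.numeric(days) || days < 2) abort("`days` must be >= 2.")
  if (!is.numeric(bin_seconds) || bin_seconds <= 0 ||
      (86400 %% bin_seconds) != 0) {
    abort("`bin_seconds` must be a positive divisor of 86400.")
  }
  if (!is.numeric(mean_rate) || mean_rate <= 0) abort("`mean_rate` must be > 0.")
  if (circadian_amplitude < 0 || circadian_amplitude > 1) {
    abort("`circadian_amplitude` must lie in [0, 1].")
  }
  if (!is.finite(fractal_beta) || fractal_beta <= -1) {
    abort("`fractal_beta` must be > -1.")
  }
  if (phase_delay_h < 0) abort("`phase_delay_h` must be >= 0.")
  if (disruption < 0 || disruption > 1) abort("`disruption` must lie in [0, 1].")
  structure(
    list(days = as.integer(days), bin_seconds = as.integer(bin_seconds),
         mean_rate = mean_rate, circadian_amplitude = circadian_amplitude,
         fractal_beta = fractal_beta, fractal_sd_frac = fractal_sd_frac,
         surge_frac = surge_frac, surge_width_h = surge_width_h,
         phase_delay_h = phase_delay_h, disruption = disruption,
         seed = as.integer(seed)),
    class = "activity_params"
  )
}

# smooth nocturnal wave in [-1, 1]: cosine peaking mid-dark (ZT18 + delay)
activity_wave <- function(zt_h, phase_delay_h = 0) {
  cos(2 * pi * (zt_h - 18 - phase_delay_h) / 24)
}

# sharp dark-onset activity surge: gaussian burst at ZT12 + delay
activity_surge <- function(zt_h, phase_delay_h = 0, width_h = 0.5) {
  u <- (zt_h - 12 - phase_delay_h) %% 24
  exp(-(pmin(u, 24 - u) / width_h)^2 / 2)
}

#' Construct an activity trace from raw counts
#'
#' Wraps a vector of binned locomotor counts (e.g. read from a PIR logger)
#' into the `activity_trace` container used by [periodogram()], [dfa()] and
#' [bin_activity()]. Counts must be complete (no gaps: impute or reject
#' missing bins upstream), finite and non-negative.
#'
#' @param counts Non-negative numeric vector, one value per bin.
#' @param bin_seconds Bin length in seconds (default 60).
#' @param schedule A [light_schedule()].
#' @param start_zt_h Zeitgeber time of the first bin start (default 0 =
#'   lights-on).
#' @return An `activity_trace` tibble (`time_s`, `zt_h`, `dark`, `count`).
#' @export
activity_trace <- function(counts, bin_seconds = 60,
                           schedule = light_schedule(), start_zt_h = 0) {
  if (length(counts) == 0) abort("Empty counts.")
  if (anyNA(counts) || !all(is.finite(counts))) {
    abort("Counts contain missing values; impute or reject gaps upstream.")
  }
  if (any(counts < 0)) abort("Counts must be >= 0.")
  new_activity_trace(counts, as.integer(bin_seconds), schedule, start_zt_h)
}

new_activity_trace <- function(counts, bin_seconds, schedule, start_zt_h = 0) {
  n <- length(counts)
  time_s <- (seq_len(n) - 1L) * bin_seconds
  zt_h <- zt_wrap(start_zt_h + (time_s + bin_seconds / 2) / 3600)
  out <- tibble(
    time_s = time_s,
    zt_h = zt_h,
    dark = zt_is_dark(zt_h, schedule),
    count = as.numeric(counts)
  )
  structure(out,
            class = c("activity_trace", class(out)),
            bin_seconds = bin_seconds,
            start_zt_h = start_zt_h,
            schedule = schedule)
}

#' Simulate a PIR-like rest-activity trace
#'
#' Activity counts are generated as a Poisson draw around a continuous
#' intensity composed of (i) a smooth nocturnal circadian wave peaking
#' mid-dark, (ii) a sharp activity surge at dark onset (the classic
#' dark-onset burst of nocturnal rodents, which also carries the harmonic
#' content that pins the periodogram fold to the true period), (iii) a
#' standardized 1/f^beta fractal component scaled to `fractal_sd_frac *
#' mean_rate` and superposed on the gated mean, and (iv) optional
#' disruption noise confined to the night phase. The intensity is rectified
#' at zero before the Poisson draw, so counts are non-negative.
#' `phase_delay_h` shifts the circadian wave and surge (not the fractal
#' component), mirroring the delayed activity onset observed under dim
#' light at night; `disruption` both flattens the circadian waveform and
#' adds night-phase noise, degrading periodogram rhythm strength and the
#' DFA exponent together.
#'
#' @param params An [activity_params()] object.
#' @param schedule A [light_schedule()].
#' @return An `activity_trace`: a tibble with columns `time_s`, `zt_h`,
#'   `dark`, `count`, and attributes `bin_seconds`, `start_zt_h`, `schedule`.
#' @examples
#' tr <- simulate_activity(activity_params(days = 2, seed = 7))
#' dplyr::group_by(tr, dark) |> dplyr::summarise(mean = mean(count))
#' @export
simulate_activity <- function(params = activity_params(),
                              schedule = light_schedule()) {
  stopifnot(inherits(params, "activity_params"),
            inherits(schedule, "light_schedule"))
  p <- params
  n <- p$days * 86400L %/% p$bin_seconds
  set.seed(p$seed)
  zt_h <- zt_wrap(((seq_len(n) - 1L) + 0.5) * p$bin_seconds / 3600)
  a_eff <- p$circadian_amplitude * (1 - p$disruption)
  # disruption degrades the fractal correlation structure along with the
  # circadian waveform: the effective spectral exponent flattens toward white
  beta_eff <- p$fractal_beta * (1 - 0.5 * p$disruption)
  lambda <- p$mean_rate * (1 + a_eff * activity_wave(zt_h, p$phase_delay_h)) +
    p$surge_frac * p$mean_rate * a_eff *
      activity_surge(zt_h, p$phase_delay_h, p$surge_width_h) +
    p$fractal_sd_frac * p$mean_rate * fractal_noise(n, beta_eff)
  if (p$disruption > 0) {
    night <- as.numeric(zt_is_dark(zt_h, schedule))      # dark/dim-phase mask
    lambda <- lambda + p$disruption * 0.5 * p$mean_rate * rnorm(n) * night
  }
  counts <- rpois(n, pmax(lambda, 0))
  new_activity_trace(counts, p$bin_seconds, schedule)
}

#' Activity-weighted mean circadian phase
#'
#' Circular mean of zeitgeber time weighted by counts, in hours. Used to
#' verify nocturnality (mean phase in the dark half) and programmed phase
#' delays.
#'
#' @param trace An `activity_trace`.
#' @return Mean phase in hours, in \[0, 24).
#' @export
mean_activity_phase <- function(trace) {
  stopifnot(inherits(trace, "activity_trace"))
  ang <- trace$zt_h / 24 * 2 * pi
  zt_wrap(atan2(sum(trace$count * sin(ang)), sum(trace$count * cos(ang))) /
            (2 * pi) * 24)
}

#' @export
print.activity_trace <- function(x, ...) {
  cat(sprintf("<activity_trace> %d bins of %d s (%.1f days)\n",
              nrow(x), attr(x, "bin_seconds"),
              nrow(x) * attr(x, "bin_seconds") / 86400))
  NextMethod()
}
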