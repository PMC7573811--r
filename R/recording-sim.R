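#' Frequency grid of the 4-s epoch spectra
#'
#' 100 bins at 0.25-Hz spacing covering 0.25-25.0 Hz, the analysis range of
#' the 4-s epoch FFT at 128 samples/s.
#' @return Numeric vector of bin centre frequencies.
#' @export
spectral_freqs <- function() seq(0.25, 25, by = 0.25)

#' Default state-specific EEG spectral templates
#'
#' Per-state band-weight templates over the 0.25-25 Hz grid (unit:
#' microvolt^2 per 0.25-Hz bin). NREM is delta-rich (its maximal bin lies in
#' 0.75-4.0 Hz), REM is theta-rich (maximal bin in 6.25-9.0 Hz), and WAKE
#' carries moderate theta over a broad base. All templates add a 1/f-like
#' background.
#'
#' @return A 100 x 3 matrix with columns `WAKE`, `NREM`, `REM`.
#' @export
default_state_templates <- function() {
  f <- spectral_freqs()
  base <- 0.4 / f                                     # 1/f background
  nrem <- base + 8 * exp(-((f - 2) / 1.3)^2 / 2)
  rem  <- base + 5 * exp(-((f - 7.5) / 0.9)^2 / 2) + 0.4 * exp(-((f - 2) / 1.3)^2 / 2)
  wake <- base + 2 * exp(-((f - 8) / 1.2)^2 / 2) + 0.3 * exp(-((f - 2) / 1.5)^2 / 2)
  m <- cbind(WAKE = wake, NREM = nrem, REM = rem)
  rownames(m) <- sprintf("%.2f", f)
  m
}

#' Default per-phase vigilance-state transition matrices
#'
#' First-order Markov transition probabilities between WAKE/NREM/REM at 4-s
#' epoch resolution, one matrix for the light phase (sleep-dominated) and one
#' for the dark/dim phase (wake-dominated). Direct WAKE to REM transitions
#' are zero by default, following the usual rodent convention.
#'
#' @return Named list with 3 x 3 row-stochastic matrices `light` and `dark`.
#' @export
default_transition_matrices <- function() {
  st <- c("WAKE", "NREM", "REM")
  light <- matrix(c(0.920, 0.080, 0.000,
                    0.030, 0.945, 0.025,
                    0.060, 0.020, 0.920),
                  nrow = 3, byrow = TRUE, dimnames = list(st, st))
  dark <- matrix(c(0.975, 0.025, 0.000,
                   0.060, 0.925, 0.015,
                   0.080, 0.020, 0.900),
                 nrow = 3, byrow = TRUE, dimnames = list(st, st))
  list(light = light, dark = dark)
}

#' Parameters for the sleep-EEG/EMG recording simulator
#'
#' @param days Whole number of simulated days (default 2: a baseline day plus
#'   an intervention/recovery day).
#' @param state_templates 100 x 3 per-state spectral templates, see
#'   [default_state_templates()].
#' @param emg_level Named per-state EMG root-mean-square level in microvolts;
#'   must satisfy WAKE >> NREM >= REM.
#' @param transition_matrices List with row-stochastic `light` and `dark`
#'   3 x 3 matrices (rows sum to 1 within 1e-9).
#' @param homeostat A [homeostat_params()]; `gain * S` scales the NREM
#'   slow-wave (0.5-4 Hz) amplitude.
#' @param phase_delay_h Hours by which the dark-phase waking drive is delayed
#'   (default 0), emulating the waking-peak delay under dim light at night.
#' @param wake_drive_peak_offset_h Peak of the dark-phase waking drive,
#'   hours after dark onset (default 1).
#' @param wake_drive_width_h Gaussian width of the waking drive (default 1.5).
#' @param wake_drive_strength Fraction by which the drive pulls the dark
#'   WAKE self-transition toward 1 at its peak (default 0.8).
#' @param sleep_pressure_coupling Exponent coupling the homeostat level S to
#'   the wake/NREM transition probabilities (default 1; 0 decouples the
#'   chain from S). High S scales the wake-to-NREM entry up and the
#'   NREM-to-wake exit down, producing the post-deprivation sleep rebound.
#' @param artifact_rate Fraction of epochs receiving an injected movement
#'   artifact spike (default 0 = clean recording).
#' @param seed RNG seed.
#' @return An object of class `eeg_gen_params`.
#' @export
eeg_gen_params <- function(days = 2,
                           state_templates = default_state_templates(),
                           emg_level = c(WAKE = 40, NREM = 8, REM = 5),
                           transition_matrices = default_transition_matrices(),
                           homeostat = homeostat_params(),
                           phase_delay_h = 0,
                           wake_drive_peak_offset_h = 1,
                           wake_drive_width_h = 1.5,
                           wake_drive_strength = 0.8,
                           sleep_pressure_coupling = 1,
                           artifact_rate = 0,
                           seed = 1L) {
  if (days < 1 || days != round(days)) abort("`days` must be a whole number >= 1.")
  if (!is.matrix(state_templates) || nrow(state_templates) != 100 ||
      ncol(state_templates) != 3) {
    abort("`state_templates` must be a 100 x 3 matrix (WAKE, NREM, REM).")
  }
  if (any(state_templates < 0)) abort("Spectral template weights must be >= 0.")
  f <- spectral_freqs()
  pk_n <- f[which.max(state_templates[, "NREM"])]
  pk_r <- f[which.max(state_templates[, "REM"])]
  if (pk_n < 0.75 || pk_n > 4) {
    abort("NREM template's maximal band must lie within 0.75-4.0 Hz.")
  }
  if (pk_r < 6.25 || pk_r > 9) {
    abort("REM template's maximal band must lie within 6.25-9.0 Hz.")
  }
  if (!all(c("WAKE", "NREM", "REM") %in% names(emg_level)) ||
      !(emg_level["WAKE"] > emg_level["NREM"]) ||
      !(emg_level["NREM"] >= emg_level["REM"])) {
    abort("`emg_level` must satisfy WAKE > NREM >= REM.")
  }
  for (nm in c("light", "dark")) {
    tm <- transition_matrices[[nm]]
    if (is.null(tm) || !is.matrix(tm) || any(dim(tm) != 3)) {
      abort(sprintf("`transition_matrices$%s` must be a 3 x 3 matrix.", nm))
    }
    if (any(tm < 0) || any(abs(rowSums(tm) - 1) > 1e-9)) {
      abort(sprintf(
        "`transition_matrices$%s` rows must be probabilities summing to 1 (tol 1e-9).",
        nm))
    }
  }
  stopifnot(inherits(homeostat, "homeostat_params"))
  structure(
    list(days = as.integer(days), state_templates = state_templates,
         emg_level = emg_level, transition_matrices = transition_matrices,
         homeostat = homeostat, phase_delay_h = phase_delay_h,
         wake_drive_peak_offset_h = wake_drive_peak_offset_h,
         wake_drive_width_h = wake_drive_width_h,
         wake_drive_strength = wake_drive_strength,
         sleep_pressure_coupling = sleep_pressure_coupling,
         artifact_rate = artifact_rate, seed = as.integer(seed)),
    class = "eeg_gen_params"
  )
}

#' Sleep-deprivation protocol
#'
#' A forced-wake window expressed in zeitgeber time, applied on the last
#' simulated day; the default is the standard 6-h deprivation from light
#' onset (ZT0-6) by gentle handling.
#'
#' @param start_zt_h Start, hours after lights-on (default 0).
#' @param duration_h Duration in hours (default 6).
#' @return An object of class `sd_protocol`.
#' @export
sd_protocol <- function(start_zt_h = 0, duration_h = 6) {
  if (start_zt_h < 0 || duration_h <= 0 || start_zt_h + duration_h > 24) {
    abort("Need 0 <= start_zt_h and start_zt_h + duration_h <= 24.")
  }
  structure(list(start_zt_h = start_zt_h, duration_h = duration_h),
            class = "sd_protocol")
}

new_hypnogram <- function(states, artifact = NULL, epoch_seconds = 4,
                          start_zt_h = 0) {
  n <- length(states)
  zt_h <- zt_wrap(start_zt_h + ((seq_len(n) - 1) + 0.5) * epoch_seconds / 3600)
  out <- tibble(
    epoch = seq_len(n),
    epoch_start_s = (seq_len(n) - 1) * epoch_seconds,
    zt_h = zt_h,
    state = factor(states, levels = c("WAKE", "NREM", "REM")),
    artifact = artifact %||% rep(FALSE, n)
  )
  structure(out, class = c("hypnogram", class(out)),
            epoch_seconds = epoch_seconds, start_zt_h = start_zt_h)
}

# circular gaussian bump of the dark-phase waking drive
wake_drive <- function(zt_h, params) {
  peak <- 12 + params$wake_drive_peak_offset_h + params$phase_delay_h
  d <- abs((zt_h - peak + 12) %% 24 - 12)
  params$wake_drive_strength * exp(-(d / params$wake_drive_width_h)^2 / 2)
}

# draw the ground-truth hypnogram from the per-phase Markov chain, with the
# homeostat fed back into the wake<->NREM transitions (high S favours falling
# and staying asleep), so enforced waking is followed by a sleep rebound
simulate_hypnogram <- function(params, schedule, sd = NULL, epoch_seconds = 4) {
  n_epd <- 86400L %/% epoch_seconds
  n <- params$days * n_epd
  zt <- zt_wrap(((seq_len(n) - 1) + 0.5) * epoch_seconds / 3600)
  dark <- zt_is_dark(zt, schedule)
  drive <- wake_drive(zt, params)
  forced <- rep(FALSE, n)
  if (!is.null(sd)) {
    stopifnot(inherits(sd, "sd_protocol"))
    last_day <- (params$days - 1L) * n_epd
    ep_zt0 <- ((seq_len(n) - 1)) * epoch_seconds / 3600   # epoch start, h
    day_h <- ep_zt0 - (params$days - 1L) * 24
    forced <- seq_len(n) > last_day &
      day_h >= sd$start_zt_h & day_h < sd$start_zt_h + sd$duration_h
  }
  hp <- params$homeostat
  dt_h <- epoch_seconds / 3600
  dec_r <- exp(-dt_h / hp$tau_rise_h)
  dec_d <- exp(-dt_h / hp$tau_decay_h)
  k <- params$sleep_pressure_coupling
  tml <- params$transition_matrices$light
  tmd <- params$transition_matrices$dark
  states <- integer(n)
  s_out <- numeric(n)
  cur <- 1L                                   # start awake at lights-on
  s_cur <- hp$s0
  u <- runif(n)
  for (i in seq_len(n)) {
    if (forced[i]) {
      cur <- 1L
    } else {
      p <- if (dark[i]) tmd[cur, ] else tml[cur, ]
      if (k > 0 && cur <= 2L) {
        # sleep-pressure feedback: S above/below its midpoint scales the
        # wake-to-NREM entry up/down and the NREM-to-wake exit down/up
        m <- min(max((s_cur / 0.5)^k, 0.25), 3)
        if (cur == 1L) {
          p[2L] <- min(0.9, p[2L] * m)
          p[1L] <- 1 - p[2L] - p[3L]
        } else {
          p[1L] <- min(0.9, p[1L] / m)
          p[2L] <- 1 - p[1L] - p[3L]
        }
      }
      if (dark[i] && cur == 1L && drive[i] > 0) {
        # pull WAKE self-transition toward 1 near the waking-drive peak
        stay <- p[1L] + (1 - p[1L]) * drive[i]
        p <- c(stay, p[2:3] * (1 - stay) / max(1 - p[1L], 1e-12))
      }
      cs <- cumsum(p)
      cur <- 1L + sum(u[i] > cs[1:2])
    }
    states[i] <- cur
    s_cur <- if (cur == 2L) s_cur * dec_d else 1 + (s_cur - 1) * dec_r
    s_out[i] <- s_cur
  }
  list(hypnogram = new_hypnogram(c("WAKE", "NREM", "REM")[states],
                                 epoch_seconds = epoch_seconds),
       s = s_out)
}

#' Simulate an EEG/EMG recording with ground truth
#'
#' Draws a ground-truth hypnogram from the per-phase Markov chain in 4-s
#' epochs, integrates the two-exponential sleep homeostat over it, and
#' synthesizes 128-Hz EEG and EMG. Each 4-s EEG epoch is built in the
#' frequency domain as a sum of band-limited Gaussian components whose
#' expected per-bin power follows the state's spectral template, with the
#' NREM 0.5-4 Hz amplitude scaled by `gain * S(t)`; the EMG is Gaussian with
#' the state's RMS level. If `sd` is given, epochs in the forced-wake window
#' of the last day are set to WAKE and S accumulates accordingly. The whole
#' simulation is deterministic given `params$seed`.
#'
#' @param params An [eeg_gen_params()].
#' @param schedule A [light_schedule()].
#' @param sd Optional [sd_protocol()].
#' @return A list with `recording` (class `eeg_recording`: `eeg`, `emg`,
#'   128 samples/s, plus schedule metadata), `hypnogram` (ground truth,
#'   including injected-artifact flags), and `s` (per-epoch homeostat level).
#' @examples
#' sim <- simulate_recording(eeg_gen_params(days = 1, seed = 3))
#' table(sim$hypnogram$state)
#' @export
simulate_recording <- function(params = eeg_gen_params(),
                               schedule = light_schedule(),
                               sd = NULL) {
  stopifnot(inherits(params, "eeg_gen_params"),
            inherits(schedule, "light_schedule"))
  set.seed(params$seed)
  drawn <- simulate_hypnogram(params, schedule, sd)
  hyp <- drawn$hypnogram
  s <- drawn$s
  n_ep <- nrow(hyp)
  fs <- 128L
  spe <- 512L                                  # samples per 4-s epoch
  f <- spectral_freqs()
  swa_bins <- which(f >= 0.5 & f <= 4)
  templ <- params$state_templates
  # template rows beyond 25 Hz: small white tail so the signal is not
  # perfectly band-limited
  tail_bins <- 156L                            # 25.25-64 Hz at 0.25-Hz spacing
  state_idx <- as.integer(hyp$state)
  gain_s <- params$homeostat$gain * s
  eeg <- numeric(n_ep * spe)
  emg <- numeric(n_ep * spe)
  chunk <- 4096L
  for (st in seq_len(ceiling(n_ep / chunk))) {
    i0 <- (st - 1L) * chunk + 1L
    i1 <- min(st * chunk, n_ep)
    idx <- i0:i1
    m <- length(idx)
    pow <- templ[, state_idx[idx], drop = FALSE]          # 100 x m
    is_n <- state_idx[idx] == 2L
    if (any(is_n)) {
      pow[swa_bins, is_n] <- pow[swa_bins, is_n] *
        rep(gain_s[idx][is_n]^2, each = length(swa_bins))
    }
    pow_full <- rbind(pow, matrix(0.02, nrow = tail_bins, ncol = m))
    # Hermitian spectrum: E[2|X_k|^2 / N^2] = P_k for k = 1..255
    amp <- spe * sqrt(pow_full / 2)                       # 256 x m
    z_re <- matrix(rnorm(256L * m), 256L, m) / sqrt(2)
    z_im <- matrix(rnorm(256L * m), 256L, m) / sqrt(2)
    z_im[256L, ] <- 0                                     # Nyquist real
    spec <- complex(real = amp * z_re, imaginary = amp * z_im)
    dim(spec) <- c(256L, m)
    full <- matrix(complex(real = 0, imaginary = 0), spe, m)
    full[2:257, ] <- spec
    full[spe:258, ] <- Conj(spec[1:255, ])
    x <- Re(stats::mvfft(full, inverse = TRUE)) / spe
    eeg[((i0 - 1L) * spe + 1L):(i1 * spe)] <- as.numeric(x)
    emg[((i0 - 1L) * spe + 1L):(i1 * spe)] <-
      rnorm(m * spe) * rep(params$emg_level[state_idx[idx]], each = spe)
  }
  artifact <- rep(FALSE, n_ep)
  if (params$artifact_rate > 0) {
    hit <- which(runif(n_ep) < params$artifact_rate)
    artifact[hit] <- TRUE
    for (e in hit) {
      at <- (e - 1L) * spe + sample.int(spe - 8L, 1L)
      eeg[at:(at + 7L)] <- eeg[at:(at + 7L)] + 12 * sd_robust(eeg[1:spe])
    }
  }
  hyp$artifact <- artifact
  rec <- structure(
    list(eeg = eeg, emg = emg, fs = fs, start_zt_h = 0,
         schedule = schedule, days = params$days),
    class = "eeg_recording"
  )
  list(recording = rec, hypnogram = hyp, s = s)
}

sd_robust <- function(x) {
  s <- mad(x)
  if (s == 0) sd(x) else s
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> EEG+EMG, %d samples at %d Hz (%.2f days)\n",
              length(x$eeg), x$fs, length(x$eeg) / x$fs / 86400))
  invisible(x)
}
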