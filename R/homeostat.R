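#' Two-exponential sleep-homeostat parameters
#'
#' Process-S-style homeostat: sleep pressure S in \[0, 1\] rises toward 1
#' with time constant `tau_rise_h` during WAKE and REM epochs, and decays
#' toward 0 with time constant `tau_decay_h` during NREM epochs. In the
#' recording simulator, `gain * S` scales the NREM slow-wave (0.5-4 Hz)
#' amplitude, so S is expressed in measured slow-wave activity.
#'
#' @param s0 Initial level in \[0, 1\] (default 0.5).
#' @param tau_rise_h Rise time constant in hours (default 8).
#' @param tau_decay_h Decay time constant in hours (default 2).
#' @param gain Multiplier mapping S to the NREM slow-wave amplitude
#'   (default 2).
#' @return An object of class `homeostat_params`.
#' @export
homeostat_params <- function(s0 = 0.5, tau_rise_h = 8, tau_decay_h = 2,
                             gain = 2) {
  if (s0 < 0 || s0 > 1) abort("`s0` must lie in [0, 1].")
  if (tau_rise_h <= 0 || tau_decay_h <= 0) {
    abort("Time constants must be positive.")
  }
  if (gain < 0) abort("`gain` must be >= 0.")
  structure(list(s0 = s0, tau_rise_h = tau_rise_h, tau_decay_h = tau_decay_h,
                 gain = gain),
            class = "homeostat_params")
}

#' Sleep-pressure trajectory from a hypnogram
#'
#' Integrates the two-exponential homeostat across a hypnogram at epoch
#' resolution: within each epoch S relaxes exponentially toward 1 (WAKE/REM)
#' or 0 (NREM) with the corresponding time constant, continuously across
#' epoch boundaries. With an all-WAKE hypnogram and `s0 = 0` this is exactly
#' `1 - exp(-t / tau_rise_h)`; with all-NREM and `s0 = 1`, `exp(-t /
#' tau_decay_h)`.
#'
#' @param hypnogram A `hypnogram` (see [score_epochs()]), or any tibble with
#'   a `state` column of WAKE/NREM/REM labels and an `epoch_seconds`
#'   attribute.
#' @param params A [homeostat_params()].
#' @return Numeric vector: S at the *end* of each epoch.
#' @export
process_s_trajectory <- function(hypnogram, params = homeostat_params()) {
  stopifnot(inherits(params, "homeostat_params"))
  states <- hypnogram$state
  if (length(states) == 0L) abort("Empty hypnogram.")
  dt_h <- (attr(hypnogram, "epoch_seconds") %||% 4) / 3600
  up <- states != "NREM"
  decay <- ifelse(up, exp(-dt_h / params$tau_rise_h),
                  exp(-dt_h / params$tau_decay_h))
  target <- as.numeric(up)
  s <- numeric(length(states))
  cur <- params$s0
  for (i in seq_along(states)) {
    cur <- target[i] + (cur - target[i]) * decay[i]
    s[i] <- cur
  }
  s
}
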