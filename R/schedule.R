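#' Define a 12:12 light schedule
#'
#' A light schedule anchors all analyses to zeitgeber time (ZT), with ZT0 at
#' lights-on. The cycle is split into exactly 12 h of bright light and 12 h of
#' darkness (0 lux) or dim light at night (DLAN, conventionally 5 lux). Lux
#' values are labels carried through to outputs; no photoreceptor model is
#' attached to them.
#'
#' @param lights_on_clock Clock time of lights-on, `"HH:MM"` (default
#'   `"10:00"`).
#' @param light_lux Illuminance during the light phase (default 75).
#' @param night_lux Illuminance during the night phase: 0 for a light:dark
#'   (LD) schedule, 5 for light:DLAN.
#' @param cycle_hours Cycle length in hours (default 24).
#' @return An object of class `light_schedule`.
#' @examples
#' light_schedule()                 # control LD
#' light_schedule(night_lux = 5)    # DLAN arm
#' @export
light_schedule <- function(lights_on_clock = "10:00", light_lux = 75,
                           night_lux = 0, cycle_hours = 24) {
  if (!is.numeric(light_lux) || !is.numeric(night_lux) ||
      night_lux < 0 || night_lux >= light_lux) {
    abort("`night_lux` must satisfy 0 <= night_lux < light_lux.")
  }
  if (!identical(cycle_hours, 24) && !isTRUE(all.equal(cycle_hours, 24))) {
    abort("Only 24-h cycles are supported (12 h light : 12 h dark/dim).")
  }
  if (!grepl("^\\d{1,2}:\\d{2}$", lights_on_clock)) {
    abort("`lights_on_clock` must be \"HH:MM\".")
  }
  structure(
    list(
      lights_on_clock = lights_on_clock,
      light_lux = light_lux,
      night_lux = night_lux,
      cycle_hours = 24,
      light_hours = 12
    ),
    class = "light_schedule"
  )
}

#' @export
print.light_schedule <- function(x, ...) {
  kind <- if (x$night_lux > 0) "light:DLAN" else "light:dark"
  cat(sprintf("<light_schedule> 12:12 %s (%g:%g lux), lights on %s (= ZT0)\n",
              kind, x$light_lux, x$night_lux, x$lights_on_clock))
  invisible(x)
}

#' Is a zeitgeber time in the dark/dim phase?
#'
#' ZT0 is lights-on; the light phase is the half-open interval \[0, 12) and
#' the dark/dim phase \[12, 24).
#'
#' @param zt_h Zeitgeber time(s) in hours (any real; wrapped modulo 24).
#' @param schedule A [light_schedule()].
#' @return Logical vector.
#' @export
zt_is_dark <- function(zt_h, schedule = light_schedule()) {
  (zt_h %% schedule$cycle_hours) >= schedule$light_hours
}

# wrap hours into [0, 24)
zt_wrap <- function(zt_h) zt_h %% 24
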