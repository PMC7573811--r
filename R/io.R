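#' Write / read an activity trace as CSV
#'
#' Plain two-column CSV `timestamp_iso,count`; timestamps are derived from
#' the schedule's lights-on clock time on an arbitrary start date (the
#' analyses only use zeitgeber time).
#'
#' @param trace An `activity_trace`.
#' @param path Output file.
#' @param start_date Calendar date of the first bin (default
#'   `"2020-01-01"`).
#' @return `path`, invisibly.
#' @export
write_activity_csv <- function(trace, path, start_date = "2020-01-01") {
  stopifnot(inherits(trace, "activity_trace"))
  sch <- attr(trace, "schedule")
  origin <- as.POSIXct(paste(start_date, sch$lights_on_clock), tz = "UTC")
  df <- tibble(
    timestamp_iso = format(origin + trace$time_s, "%Y-%m-%dT%H:%M:%S"),
    count = trace$count
  )
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_activity_csv
#' @param bin_seconds,schedule Trace metadata to attach on read;
#'   `bin_seconds = NULL` infers the bin from the first two timestamps.
#' @export
read_activity_csv <- function(path, bin_seconds = NULL,
                              schedule = light_schedule()) {
  df <- readr::read_csv(path, col_types = readr::cols(
    timestamp_iso = readr::col_datetime(format = "%Y-%m-%dT%H:%M:%S"),
    count = readr::col_double()
  ))
  if (nrow(df) < 2) abort("Activity CSV needs >= 2 rows.")
  gaps <- as.numeric(diff(df$timestamp_iso), units = "secs")
  if (is.null(bin_seconds)) bin_seconds <- gaps[1]
  if (any(abs(gaps - bin_seconds) > 1e-6)) {
    abort("Missing or irregular bins; impute or reject upstream.")
  }
  if (any(df$count < 0)) abort("Negative counts.")
  on_h <- as.numeric(substr(schedule$lights_on_clock, 1, 2)) +
    as.numeric(substr(schedule$lights_on_clock, 4, 5)) / 60
  first_h <- as.numeric(format(df$timestamp_iso[1], "%H")) +
    as.numeric(format(df$timestamp_iso[1], "%M")) / 60
  start_zt <- zt_wrap(first_h - on_h)
  new_activity_trace(df$count, as.integer(bin_seconds), schedule,
                     start_zt_h = start_zt)
}

#' Write / read a hypnogram as CSV
#'
#' Three-column CSV `epoch_start_s,state,artifact` with states coded
#' W/N/R.
#'
#' @param hypnogram A `hypnogram`.
#' @param path File path.
#' @return `path` invisibly (write); a `hypnogram` (read).
#' @export
write_hypnogram_csv <- function(hypnogram, path) {
  stopifnot(inherits(hypnogram, "hypnogram"))
  code <- c(WAKE = "W", NREM = "N", REM = "R")
  df <- tibble(
    epoch_start_s = hypnogram$epoch_start_s,
    state = unname(code[as.character(hypnogram$state)]),
    artifact = as.integer(hypnogram$artifact)
  )
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_hypnogram_csv
#' @export
read_hypnogram_csv <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    epoch_start_s = readr::col_double(),
    state = readr::col_character(),
    artifact = readr::col_integer()
  ))
  if (!all(df$state %in% c("W", "N", "R"))) {
    abort("States must be coded W/N/R.")
  }
  eps <- if (nrow(df) > 1) df$epoch_start_s[2] - df$epoch_start_s[1] else 4
  decode <- c(W = "WAKE", N = "NREM", R = "REM")
  new_hypnogram(unname(decode[df$state]), artifact = df$artifact == 1L,
                epoch_seconds = eps)
}
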