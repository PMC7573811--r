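# Minimal plain-EDF (European Data Format) writer/reader for two-channel
# EEG/EMG recordings at 128 Hz. EDF stores an ASCII header (256 bytes + 256
# per signal) followed by data records of little-endian 16-bit integers;
# samples are mapped linearly between the physical and digital ranges, so a
# round trip is exact up to 16-bit quantization of the physical range.
# Written by hand because no EDF package is available in this R stack.

edf_pad <- function(x, width) {
  s <- as.character(x)
  if (nchar(s) > width) s <- substr(s, 1, width)
  formatC(s, width = -width, flag = " ")
}

edf_num <- function(x, width) {
  for (d in 7:1) {
    s <- formatC(signif(x, d), width = 1, format = "g", digits = d)
    if (nchar(s) <= width) return(edf_pad(s, width))
  }
  abort("Cannot format physical range in an 8-char EDF field.")
}

#' Write a two-channel recording to EDF
#'
#' Writes `eeg` and `emg` as two 128-Hz signals in 1-s data records,
#' 16-bit, with per-signal physical ranges taken from the data.
#'
#' @param recording An `eeg_recording`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path) {
  stopifnot(inherits(recording, "eeg_recording"))
  fs <- recording$fs
  sig <- list(EEG = recording$eeg, EMG = recording$emg)
  n_rec <- length(sig[[1]]) %/% fs
  if (n_rec * fs != length(sig[[1]]) ||
      length(sig[[1]]) != length(sig[[2]])) {
    abort("Signals must be equal length and a whole number of 1-s records.")
  }
  ns <- 2L
  pmin_ <- vapply(sig, function(s) signif(min(s) - 1e-6, 6), numeric(1))
  pmax_ <- vapply(sig, function(s) signif(max(s) + 1e-6, 6), numeric(1))
  pmax_ <- ifelse(pmax_ > pmin_, pmax_, pmin_ + 1)
  # use exactly the values the 8-char header fields will carry
  pmin_ <- as.numeric(vapply(pmin_, edf_num, character(1), width = 8))
  pmax_ <- as.numeric(vapply(pmax_, edf_num, character(1), width = 8))
  dmin <- -32768; dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),                                  # version
    edf_pad("X X X X", 80),                           # patient id
    edf_pad(sprintf("Startdate X noxlux synthetic ZT%g",
                    recording$start_zt_h %||% 0), 80),# recording id
    edf_pad("01.01.20", 8), edf_pad("10.00.00", 8),   # start date/time
    edf_pad(256 * (1 + ns), 8),                       # header bytes
    edf_pad("", 44),
    edf_pad(n_rec, 8), edf_pad(1, 8), edf_pad(ns, 4)
  )
  fields <- c(
    vapply(names(sig), edf_pad, character(1), width = 16),   # labels
    rep(edf_pad("", 80), ns),                                # transducer
    rep(edf_pad("uV", 8), ns),                               # dimension
    vapply(pmin_, edf_num, character(1), width = 8),
    vapply(pmax_, edf_num, character(1), width = 8),
    rep(edf_pad(dmin, 8), ns), rep(edf_pad(dmax, 8), ns),
    rep(edf_pad("", 80), ns),                                # prefilter
    rep(edf_pad(fs, 8), ns),                                 # samples/record
    rep(edf_pad("", 32), ns)
  )
  writeChar(paste0(hdr, paste0(fields, collapse = "")), con, eos = NULL)
  dig <- lapply(seq_len(ns), function(i) {
    v <- round((sig[[i]] - pmin_[i]) / (pmax_[i] - pmin_[i]) *
                 (dmax - dmin) + dmin)
    as.integer(pmin(pmax(v, dmin), dmax))
  })
  # interleave per record: fs samples of signal 1, then fs of signal 2
  m <- matrix(0L, nrow = 2L * fs, ncol = n_rec)
  m[seq_len(fs), ] <- matrix(dig[[1]], nrow = fs)
  m[fs + seq_len(fs), ] <- matrix(dig[[2]], nrow = fs)
  writeBin(as.integer(m), con, size = 2L, endian = "little")
  invisible(path)
}

#' Read a two-channel EDF written by [write_edf()]
#'
#' Parses the plain-EDF header and data records back into an
#' `eeg_recording`. Signals must share one sampling rate.
#'
#' @param path EDF file.
#' @param schedule Light schedule to attach (default LD control).
#' @return An `eeg_recording`.
#' @export
read_edf <- function(path, schedule = light_schedule()) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rd(8); rd(80); rd(80); rd(8); rd(8)
  hdr_bytes <- as.integer(rd(8))
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (ns != 2L) abort("Expected exactly 2 signals (EEG, EMG).")
  labels <- trimws(vapply(seq_len(ns), function(i) rd(16), character(1)))
  for (i in seq_len(ns)) rd(80)   # transducer
  for (i in seq_len(ns)) rd(8)    # dimension
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(80)   # prefilter
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(32)
  if (spr[1] != spr[2]) abort("Signals must share one sampling rate.")
  fs <- as.integer(spr[1] / rec_dur)
  seek(con, hdr_bytes)
  raw_all <- readBin(con, integer(), n = n_rec * sum(spr), size = 2L,
                     signed = TRUE, endian = "little")
  m <- matrix(raw_all, nrow = sum(spr))
  tophys <- function(d, i) {
    pmin_[i] + (d - dmin[i]) * (pmax_[i] - pmin_[i]) / (dmax[i] - dmin[i])
  }
  eeg <- tophys(as.numeric(m[seq_len(spr[1]), ]), 1L)
  emg <- tophys(as.numeric(m[spr[1] + seq_len(spr[2]), ]), 2L)
  structure(
    list(eeg = eeg, emg = emg, fs = fs, start_zt_h = 0,
         schedule = schedule, labels = labels,
         days = length(eeg) / fs / 86400),
    class = "eeg_recording"
  )
}
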