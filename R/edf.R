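#' Write a recording to EDF (16-bit) or BDF (24-bit)
#'
#' Minimal writer for continuous data: one data record per second, last
#' record zero-padded. Physical scaling is symmetric around zero and chosen
#' from the data range per channel. Events are not embedded (no EDF+
#' annotation signal); export them with [write_events_csv()].
#'
#' @param rec an [eeg_recording()] with an integer sampling rate.
#' @param path output path; format from `format`.
#' @param format `"edf"` or `"bdf"`.
#' @export
write_recording_edf <- function(rec, path, format = c("edf", "bdf")) {
  stopifnot(inherits(rec, "eeg_recording"))
  format <- match.arg(format)
  srate <- rec$srate
  if (srate != round(srate)) stopf("EDF export needs an integer sampling rate")
  ns <- nrow(rec$data)
  n_rec <- ceiling(ncol(rec$data) / srate)
  pad <- n_rec * srate - ncol(rec$data)
  dat <- cbind(rec$data, matrix(0, ns, pad))
  dig_max <- if (format == "edf") 32767 else 8388607
  # integer physical bounds: exactly representable in the 8-char header field
  pmax_ <- as.integer(ceiling(apply(abs(dat), 1L, max)))
  pmax_[pmax_ == 0] <- 1
  con <- file(path, "wb")
  on.exit(close(con))
  pad_field <- function(x, w) {
    s <- substr(as.character(x), 1L, w)
    paste0(s, strrep(" ", w - nchar(s)))
  }
  wf <- function(x, w) writeChar(pad_field(x, w), con, eos = NULL)
  if (format == "edf") wf("0", 8L) else {
    writeBin(as.raw(255), con); wf("BIOSEMI", 7L)
  }
  wf("simulated subject", 80L); wf("simulated recording", 80L)
  wf("01.01.26", 8L); wf("00.00.00", 8L)
  wf(256L * (1L + ns), 8L)
  wf(if (format == "edf") "EDF+C" else "24BIT", 44L)
  wf(n_rec, 8L); wf("1", 8L); wf(ns, 4L)
  for (ch in rec$channels) wf(ch, 16L)
  for (i in seq_len(ns)) wf("AgAgCl electrode", 80L)
  for (i in seq_len(ns)) wf("uV", 8L)
  for (i in seq_len(ns)) wf(sprintf("%d", -pmax_[i]), 8L)
  for (i in seq_len(ns)) wf(sprintf("%d", pmax_[i]), 8L)
  for (i in seq_len(ns)) wf(-dig_max, 8L)
  for (i in seq_len(ns)) wf(dig_max, 8L)
  for (i in seq_len(ns)) wf("HP:0.1Hz LP:500Hz", 80L)
  for (i in seq_len(ns)) wf(srate, 8L)
  for (i in seq_len(ns)) wf("", 32L)
  scale <- dig_max / pmax_
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * srate + 1L):(r * srate)
    for (i in seq_len(ns)) {
      v <- as.integer(round(dat[i, cols] * scale[i]))
      if (format == "edf") {
        writeBin(v, con, 2L, endian = "little")
      } else {
        writeBin(int_to_int24(v), con)
      }
    }
  }
  invisible(path)
}

int_to_int24 <- function(v) {
  u <- ifelse(v < 0, v + 16777216, v)  # two's complement in 24 bits
  r <- raw(3L * length(u))
  r[seq(1L, length(r), 3L)] <- as.raw(u %% 256)
  r[seq(2L, length(r), 3L)] <- as.raw((u %/% 256) %% 256)
  r[seq(3L, length(r), 3L)] <- as.raw(u %/% 65536)
  r
}

int24_to_int <- function(r) {
  b0 <- as.integer(r[seq(1L, length(r), 3L)])
  b1 <- as.integer(r[seq(2L, length(r), 3L)])
  b2 <- as.integer(r[seq(3L, length(r), 3L)])
  v <- b0 + 256L * b1 + 65536L * b2
  ifelse(v >= 8388608, v - 16777216, v)
}

#' Read an EDF or BDF file written by [write_recording_edf()]
#'
#' Requires a uniform sampling rate across signals; returns physical units.
#'
#' @param path file path.
#' @return an [eeg_recording()] (empty event table).
#' @export
read_recording_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  first <- readBin(con, "raw", 1L)
  format <- if (as.integer(first) == 255L) "bdf" else "edf"
  readChar(con, 7L)
  readChar(con, 160L)                 # patient + recording
  readChar(con, 16L)                  # date + time
  readChar(con, 8L)                   # header bytes
  readChar(con, 44L)                  # reserved
  n_rec <- as.integer(readChar(con, 8L))
  rec_dur <- as.numeric(readChar(con, 8L))
  ns <- as.integer(readChar(con, 4L))
  rd <- function(w) vapply(seq_len(ns), function(i)
    trimws(readChar(con, w)), character(1))
  labels <- rd(16L); rd(80L); rd(8L)
  pmin_ <- as.numeric(rd(8L)); pmax_ <- as.numeric(rd(8L))
  dmin <- as.numeric(rd(8L)); dmax <- as.numeric(rd(8L))
  rd(80L)
  spr <- as.integer(rd(8L)); rd(32L)
  if (length(unique(spr)) != 1L) stopf("mixed sampling rates not supported")
  srate <- spr[1L] / rec_dur
  gain <- (pmax_ - pmin_) / (dmax - dmin)
  dat <- matrix(0, ns, n_rec * spr[1L])
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * spr[1L] + 1L):(r * spr[1L])
    for (i in seq_len(ns)) {
      v <- if (format == "edf")
        readBin(con, "integer", spr[i], 2L, signed = TRUE,
                endian = "little")
      else int24_to_int(readBin(con, "raw", 3L * spr[i]))
      dat[i, cols] <- pmin_[i] + gain[i] * (v - dmin[i])
    }
  }
  eeg_recording(dat, srate, labels)
}

#' Export / import the event table as CSV
#'
#' Columns: `sample`, `onset_s`, `code`, `condition`, `hand`.
#'
#' @param rec an [eeg_recording()].
#' @param path CSV path.
#' @export
write_events_csv <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  ev <- rec$events
  out <- data.frame(sample = ev$sample,
                    onset_s = (ev$sample - 1L) / rec$srate,
                    code = ev$code,
                    condition = if ("condition" %in% names(ev))
                      ev$condition else NA,
                    hand = if ("hand" %in% names(ev)) ev$hand else NA)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @param path CSV path.
#' @export
read_events_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
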