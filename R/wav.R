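#' Audio track container
#'
#' @param samples numeric vector (mono) or channels x samples matrix, in
#'   [-1, 1].
#' @param srate sampling rate Hz.
#' @return object of class `audio_track`.
#' @export
audio_track <- function(samples, srate) {
  if (is.vector(samples)) samples <- matrix(samples, nrow = 1L)
  if (srate <= 0) stopf("srate must be positive")
  structure(list(samples = samples, srate = srate,
                 duration = ncol(samples) / srate), class = "audio_track")
}

#' @export
print.audio_track <- function(x, ...) {
  cat(sprintf("Audio track: %d channel(s), %.2f s @ %g Hz, peak %.3f\n",
              nrow(x$samples), x$duration, x$srate, max(abs(x$samples))))
  invisible(x)
}

#' Read a RIFF/WAVE file
#'
#' Supports 16-bit PCM and 32-bit IEEE float, the two encodings the package
#' writes.
#'
#' @param path file path.
#' @return an [audio_track()].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (rawToChar(readBin(con, "raw", 4L)) != "RIFF") stopf("not a RIFF file")
  readBin(con, "integer", 1L, 4L, endian = "little")
  if (rawToChar(readBin(con, "raw", 4L)) != "WAVE") stopf("not a WAVE file")
  fmt <- NULL; dat <- NULL
  repeat {
    id <- readBin(con, "raw", 4L)
    if (length(id) < 4L) break
    sz <- readBin(con, "integer", 1L, 4L, endian = "little")
    tag <- rawToChar(id)
    if (tag == "fmt ") {
      fmt <- list(
        audio_format = readBin(con, "integer", 1L, 2L, endian = "little"),
        n_channels = readBin(con, "integer", 1L, 2L, endian = "little"),
        srate = readBin(con, "integer", 1L, 4L, endian = "little"),
        byte_rate = readBin(con, "integer", 1L, 4L, endian = "little"),
        block_align = readBin(con, "integer", 1L, 2L, endian = "little"),
        bits = readBin(con, "integer", 1L, 2L, endian = "little"))
      if (sz > 16L) readBin(con, "raw", sz - 16L)
    } else if (tag == "data") {
      dat <- readBin(con, "raw", sz)
      if (sz %% 2L == 1L) readBin(con, "raw", 1L)
    } else {
      readBin(con, "raw", sz + sz %% 2L)
    }
    if (!is.null(fmt) && !is.null(dat)) break
  }
  if (is.null(fmt) || is.null(dat)) stopf("malformed WAV: missing chunk")
  x <- if (fmt$audio_format == 1L && fmt$bits == 16L) {
    readBin(dat, "integer", length(dat) / 2L, 2L, signed = TRUE,
            endian = "little") / 32767
  } else if (fmt$audio_format == 3L && fmt$bits == 32L) {
    readBin(dat, "double", length(dat) / 4L, 4L, endian = "little")
  } else stopf("unsupported WAV encoding (format %d, %d bits)",
               fmt$audio_format, fmt$bits)
  audio_track(matrix(x, nrow = fmt$n_channels), fmt$srate)
}

#' Write a RIFF/WAVE file
#'
#' @param track an [audio_track()].
#' @param path output path.
#' @param bits 16 (PCM) or 32 (IEEE float).
#' @export
write_wav <- function(track, path, bits = 16L) {
  stopifnot(inherits(track, "audio_track"), bits %in% c(16L, 32L))
  x <- as.vector(track$samples)           # interleaved: channels are rows
  nch <- nrow(track$samples)
  bytes_per <- bits / 8L
  data_sz <- length(x) * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  wle <- function(v, size) writeBin(as.integer(v), con, size,
                                    endian = "little")
  writeChar("RIFF", con, eos = NULL); wle(36L + data_sz, 4L)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL); wle(16L, 4L)
  wle(if (bits == 16L) 1L else 3L, 2L); wle(nch, 2L)
  wle(track$srate, 4L); wle(track$srate * nch * bytes_per, 4L)
  wle(nch * bytes_per, 2L); wle(bits, 2L)
  writeChar("data", con, eos = NULL); wle(data_sz, 4L)
  if (bits == 16L) {
    writeBin(as.integer(round(pmax(pmin(x, 1), -1) * 32767)), con, 2L,
             endian = "little")
  } else {
    writeBin(as.double(x), con, 4L, endian = "little")
  }
  invisible(path)
}
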