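# Minimal RIFF/WAVE reader and writer for mono ultrasonic recordings.
# Supports PCM 16-bit (format code 1) and IEEE float32 (format code 3).

#' Read a mono WAV file
#'
#' Reads a mono RIFF/WAVE file (PCM 16-bit or IEEE float 32-bit) into an
#' audio recording. Samples are returned as dimensionless amplitudes in
#' `[-1, 1]` (PCM samples are divided by 32768).
#'
#' @param path Path to a `.wav` file.
#' @param id Recording identifier; defaults to the file name without extension.
#' @return An [audio_recording()] object.
#' @export
read_wav <- function(path, id = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) abort("not a RIFF file")
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) abort("not a WAVE file")

  fmt <- NULL
  samples <- NULL
  repeat {
    tag <- readChar(con, 4, useBytes = TRUE)
    if (length(tag) == 0 || nchar(tag) < 4) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(tag, "fmt ")) {
      raw_fmt <- readBin(con, "raw", size)
      fmt <- list(
        code       = readBin(raw_fmt[1:2], "integer", 1, size = 2, endian = "little"),
        channels   = readBin(raw_fmt[3:4], "integer", 1, size = 2, endian = "little"),
        fs         = readBin(raw_fmt[5:8], "integer", 1, size = 4, endian = "little"),
        bit_depth  = readBin(raw_fmt[15:16], "integer", 1, size = 2, endian = "little")
      )
    } else if (identical(tag, "data")) {
      if (is.null(fmt)) abort("malformed WAV: data chunk before fmt chunk")
      if (fmt$channels != 1L) {
        abort(sprintf("only mono WAV is supported (file has %d channels)", fmt$channels))
      }
      if (fmt$code == 1L && fmt$bit_depth == 16L) {
        raw <- readBin(con, "integer", size / 2, size = 2, signed = TRUE,
                       endian = "little")
        samples <- raw / 32768
      } else if (fmt$code == 3L && fmt$bit_depth == 32L) {
        samples <- readBin(con, "double", size / 4, size = 4, endian = "little")
      } else {
        abort(sprintf("unsupported WAV encoding (format %d, %d bit)",
                      fmt$code, fmt$bit_depth))
      }
      if (size %% 2 == 1) invisible(readBin(con, "raw", 1))
    } else {
      invisible(readBin(con, "raw", size + size %% 2))
    }
    if (!is.null(samples)) break
  }
  if (is.null(samples)) abort("malformed WAV: no data chunk")
  audio_recording(samples, fs = fmt$fs,
                  id = id %||% sub("\\.wav$", "", basename(path), ignore.case = TRUE))
}

#' Write a mono WAV file
#'
#' @param rec An [audio_recording()] or a numeric vector of samples.
#' @param path Output path.
#' @param fs Sampling rate in Hz (taken from `rec` if it is an audio recording).
#' @param bit_depth 16 for PCM integer, 32 for IEEE float.
#' @return `path`, invisibly.
#' @export
write_wav <- function(rec, path, fs = NULL, bit_depth = 16) {
  if (inherits(rec, "usv_audio")) {
    fs <- rec$fs
    x <- rec$samples
  } else {
    x <- as.numeric(rec)
  }
  if (is.null(fs)) abort("fs is required when writing a bare sample vector")
  stopifnot(bit_depth %in% c(16, 32))
  n <- length(x)
  bytes_per <- bit_depth / 8
  data_size <- n * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(as.integer(if (bit_depth == 16) 1 else 3), con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")                      # mono
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * bytes_per), con, size = 4, endian = "little")
  writeBin(as.integer(bytes_per), con, size = 2, endian = "little")
  writeBin(as.integer(bit_depth), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (bit_depth == 16) {
    q <- as.integer(pmax(-32768, pmin(32767, round(x * 32768))))
    writeBin(q, con, size = 2, endian = "little")
  } else {
    writeBin(x, con, size = 4, endian = "little")
  }
  invisible(path)
}
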