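#' Construct a recording object
#'
#' A recording is a timestamped, duty-cycle-aware mono audio segment.
#'
#' @param samples Numeric waveform in `[-1, 1)`.
#' @param fs Sampling rate, Hz.
#' @param start Recording start time (`POSIXct`, UTC) or `NA`.
#' @param id Recording identifier.
#' @param duty_cycle `c(minutes_on, cycle_minutes)` or `NULL`.
#' @return A list of class `fw_recording`.
#' @export
recording <- function(samples, fs, start = NA, id = "rec",
                      duty_cycle = NULL) {
  if (!is.numeric(samples)) abort("`samples` must be numeric")
  if (!is.numeric(fs) || fs <= 0) abort("`fs` must be a positive number")
  structure(list(id = id, start = start, fs = fs,
                 samples = as.numeric(samples), duty_cycle = duty_cycle),
            class = "fw_recording")
}

#' @export
print.fw_recording <- function(x, ...) {
  cat(sprintf("<fw_recording> %s: %.1f s @ %g Hz, start %s\n",
              x$id, length(x$samples) / x$fs, x$fs,
              format(x$start)))
  invisible(x)
}

#' Read a mono 16-bit PCM WAV file
#'
#' Minimal RIFF/WAVE reader for the monitoring hardware's output format
#' (mono, PCM, 16 bit). Samples are returned as doubles scaled by
#' 1/32768, so a write/read round trip is bit-exact at 16-bit precision.
#'
#' @param path File path.
#' @param start Optional recording start time; defaults to the UTC
#'   timestamp encoded in filenames of the form `FW_%Y%m%dT%H%M%SZ.wav`
#'   when present.
#' @return An [recording()].
#' @export
read_wav <- function(path, start = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) abort("not a RIFF file")
  readBin(con, "integer", 1, 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) abort("not a WAVE file")
  fs <- NULL; bits <- NULL; channels <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 2, 2, endian = "little", signed = FALSE)
      audio_format <- fmt[1]; channels <- fmt[2]
      fs <- readBin(con, "integer", 1, 4, endian = "little")
      readBin(con, "integer", 1, 4, endian = "little")  # byte rate
      readBin(con, "integer", 1, 2, endian = "little")  # block align
      bits <- readBin(con, "integer", 1, 2, endian = "little")
      if (size > 16) readBin(con, "raw", size - 16)
      if (audio_format != 1) abort("unsupported WAV encoding: not PCM")
      if (channels != 1) abort("unsupported WAV layout: not mono")
      if (bits != 16) abort("unsupported WAV bit depth: not 16-bit")
    } else if (identical(id, "data")) {
      samples <- readBin(con, "integer", size / 2, 2, endian = "little",
                         signed = TRUE)
      break
    } else {
      readBin(con, "raw", size + size %% 2)
    }
  }
  if (is.null(fs) || is.null(samples)) abort("malformed WAV: missing fmt/data chunk")
  if (is.null(start)) {
    m <- regmatches(basename(path),
                    regexpr("\\d{8}T\\d{6}Z", basename(path)))
    start <- if (length(m) == 1) {
      as.POSIXct(m, format = "%Y%m%dT%H%M%SZ", tz = "UTC")
    } else NA
  }
  recording(samples / 32768, fs = fs, start = start,
            id = sub("\\.wav$", "", basename(path), ignore.case = TRUE))
}

#' Write a recording as a mono 16-bit PCM WAV file
#'
#' Samples are quantised by `round(x * 32768)` and clamped to the
#' 16-bit range, so any in-range sample survives a write/read round
#' trip bit-exactly.
#'
#' @param x An [recording()] or numeric waveform.
#' @param path Output path.
#' @param fs Sampling rate (taken from the recording when omitted).
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, path, fs = NULL) {
  if (inherits(x, "fw_recording")) {
    fs <- x$fs
    samples <- x$samples
  } else {
    if (is.null(fs)) abort("`fs` is required when writing a bare waveform")
    samples <- x
  }
  q <- as.integer(pmin(pmax(round(samples * 32768), -32768), 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_size <- 2L * length(q)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(1L, con, 2, endian = "little")             # PCM
  writeBin(1L, con, 2, endian = "little")             # mono
  writeBin(as.integer(fs), con, 4, endian = "little")
  writeBin(as.integer(fs * 2), con, 4, endian = "little")
  writeBin(2L, con, 2, endian = "little")
  writeBin(16L, con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, 4, endian = "little")
  writeBin(q, con, 2, endian = "little")
  invisible(path)
}
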