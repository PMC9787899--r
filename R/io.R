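# Minimal RIFF/WAVE I/O (16-bit PCM and 32-bit IEEE float, mono or
# multichannel) plus the force-plate CSV layout. Kept deliberately small:
# only the chunk types produced by standard acquisition software are read.

#' Read a WAV file
#'
#' Supports 16-bit PCM and 32-bit IEEE-float RIFF/WAVE files with any
#' channel count. PCM samples are scaled to \[-1, 1\].
#'
#' @param path Path to a `.wav` file.
#' @return A list with `samples` (numeric matrix, one column per channel)
#'   and `rate` (Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path, call. = FALSE)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path, call. = FALSE)
  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_raw <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = readBin(fmt_raw[1:2], "integer", 1, 2,
                               signed = FALSE, endian = "little"),
        channels = readBin(fmt_raw[3:4], "integer", 1, 2,
                           signed = FALSE, endian = "little"),
        rate = readBin(fmt_raw[5:8], "integer", 1, 4, endian = "little"),
        bits = readBin(fmt_raw[15:16], "integer", 1, 2,
                       signed = FALSE, endian = "little"))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      invisible(readBin(con, "raw", size + size %% 2))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw))
    stop("missing fmt/data chunk in ", path, call. = FALSE)
  if (fmt$audio_format == 1L && fmt$bits == 16L) {
    x <- readBin(data_raw, "integer", length(data_raw) / 2, 2,
                 signed = TRUE, endian = "little") / 32768
  } else if (fmt$audio_format == 3L && fmt$bits == 32L) {
    x <- readBin(data_raw, "double", length(data_raw) / 4, 4,
                 endian = "little")
  } else {
    stop("unsupported WAV encoding (format ", fmt$audio_format, ", ",
         fmt$bits, " bits)", call. = FALSE)
  }
  list(samples = matrix(x, ncol = fmt$channels, byrow = TRUE),
       rate = fmt$rate)
}

#' Write a WAV file (32-bit IEEE float)
#'
#' @param samples Numeric vector (mono) or matrix (one column per channel).
#' @param rate Sampling rate in Hz.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, rate, path) {
  if (is.null(dim(samples))) samples <- matrix(samples, ncol = 1)
  nch <- ncol(samples)
  interleaved <- as.numeric(t(samples))
  data_size <- length(interleaved) * 4L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(c(3L, nch), con, 2, endian = "little")           # IEEE float
  writeBin(as.integer(rate), con, 4, endian = "little")
  writeBin(as.integer(rate * nch * 4L), con, 4, endian = "little")
  writeBin(c(nch * 4L, 32L), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, 4, endian = "little")
  writeBin(interleaved, con, 4, endian = "little")
  invisible(path)
}

#' Read a force-plate CSV
#'
#' Expects columns `time_s` and `fz_n` (vertical force in Newtons). The
#' sampling rate is inferred from the median time step unless given.
#'
#' @param path CSV path.
#' @param rate Sampling rate in Hz; inferred from `time_s` when `NULL`.
#' @param subject_id Optional subject label.
#' @return A [force_recording()].
#' @export
read_force_csv <- function(path, rate = NULL, subject_id = NA_character_) {
  d <- read.csv(path)
  if (!all(c("time_s", "fz_n") %in% names(d)))
    stop("force CSV must have columns time_s and fz_n: ", path, call. = FALSE)
  if (is.null(rate)) rate <- 1 / stats::median(diff(d$time_s))
  force_recording(d$fz_n, rate = round(rate), subject_id = subject_id)
}

#' Write a stance or envelope curve as CSV
#'
#' Two columns, `time_s` and `value`, with fixed 9-digit formatting so
#' identical curves produce byte-identical files.
#'
#' @param curve A `stance_curve` or `envelope_curve`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(curve, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines("time_s,value", con)
  writeLines(sprintf("%.9g,%.9g", curve$times, curve$values), con)
  invisible(path)
}

#' Read a curve CSV written by [write_curve_csv()]
#'
#' @param path CSV path.
#' @param body_weight,normalized Passed to [stance_curve()].
#' @return A `stance_curve`.
#' @export
read_curve_csv <- function(path, body_weight = NA_real_, normalized = TRUE) {
  d <- read.csv(path)
  stance_curve(d$value, d$time_s, body_weight = body_weight,
               normalized = normalized)
}
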