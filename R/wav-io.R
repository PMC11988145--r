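# Minimal RIFF/WAVE reader and writer (PCM 16-bit and IEEE float32),
# sufficient for the mono/stereo vocalization clips this package
# consumes and produces.

#' Construct an audio clip
#'
#' @param samples numeric vector (mono) or matrix with one column per
#'   channel, amplitudes nominally in \[-1, 1\].
#' @param sample_rate sampling rate in Hz.
#' @return list of class `audio_clip` with fields `samples`,
#'   `sample_rate`, `duration` (seconds).
#' @export
audio_clip <- function(samples, sample_rate) {
  if (is.matrix(samples) && ncol(samples) == 1L) samples <- as.vector(samples)
  stopifnot(all(is.finite(samples)), sample_rate > 0)
  n <- if (is.matrix(samples)) nrow(samples) else length(samples)
  structure(list(samples = samples, sample_rate = sample_rate,
                 duration = n / sample_rate),
            class = "audio_clip")
}

clip_length <- function(clip) {
  if (is.matrix(clip$samples)) nrow(clip$samples) else length(clip$samples)
}

#' Mix an audio clip down to mono
#'
#' Multi-channel clips are averaged across channels; mono clips pass
#' through unchanged.
#'
#' @param clip an `audio_clip`.
#' @return mono `audio_clip`.
#' @export
as_mono <- function(clip) {
  if (is.matrix(clip$samples)) {
    clip <- audio_clip(rowMeans(clip$samples), clip$sample_rate)
  }
  clip
}

#' Read a WAV file
#'
#' Supports canonical RIFF/WAVE files with PCM 16-bit or IEEE float32
#' samples, any channel count.
#'
#' @param path WAV file path.
#' @return an [audio_clip()].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) rlang::abort("not a RIFF file")
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) rlang::abort("not a WAVE file")
  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw_fmt <- readBin(con, "raw", sz)
      fmt <- list(
        format = readBin(raw_fmt[1:2], "integer", 1, 2, signed = FALSE, endian = "little"),
        channels = readBin(raw_fmt[3:4], "integer", 1, 2, signed = FALSE, endian = "little"),
        sample_rate = readBin(raw_fmt[5:8], "integer", 1, 4, endian = "little"),
        bits = readBin(raw_fmt[15:16], "integer", 1, 2, signed = FALSE, endian = "little")
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz + sz %% 2L))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) rlang::abort("malformed WAV: missing fmt or data chunk")
  x <- if (fmt$format == 1L && fmt$bits == 16L) {
    readBin(data_raw, "integer", length(data_raw) %/% 2L, 2,
            signed = TRUE, endian = "little") / 32768
  } else if (fmt$format == 3L && fmt$bits == 32L) {
    readBin(data_raw, "double", length(data_raw) %/% 4L, 4, endian = "little")
  } else {
    rlang::abort("unsupported WAV encoding (need PCM16 or float32)")
  }
  if (fmt$channels > 1L) {
    x <- matrix(x, ncol = fmt$channels, byrow = TRUE)
  }
  audio_clip(x, fmt$sample_rate)
}

#' Write a WAV file
#'
#' @param clip an [audio_clip()] (mono or multi-channel).
#' @param path output path.
#' @param bits 16 (PCM, default) or 32 (IEEE float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(clip, path, bits = 16L) {
  stopifnot(bits %in% c(16L, 32L))
  x <- clip$samples
  if (!is.matrix(x)) x <- matrix(x, ncol = 1)
  nch <- ncol(x)
  inter <- as.vector(t(x))  # interleave channels
  bytes_per <- bits %/% 8L
  data_len <- length(inter) * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_len), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(c(if (bits == 16L) 1L else 3L, nch), con, 2, endian = "little")
  writeBin(as.integer(clip$sample_rate), con, 4, endian = "little")
  writeBin(as.integer(clip$sample_rate * nch * bytes_per), con, 4, endian = "little")
  writeBin(c(as.integer(nch * bytes_per), as.integer(bits)), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_len), con, 4, endian = "little")
  if (bits == 16L) {
    writeBin(as.integer(round(pmin(pmax(inter, -1), 32767 / 32768) * 32768)),
             con, 2, endian = "little")
  } else {
    writeBin(inter, con, 4, endian = "little")
  }
  invisible(path)
}
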