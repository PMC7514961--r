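# Minimal RIFF/WAVE reader and writer for mono PCM recordings.
# Supports 8/16/24/32-bit integer PCM and 32/64-bit IEEE float; integer
# samples are scaled to [-1, 1] so that downstream scale-dependent features
# (subband two-norms) are computed on a fixed amplitude convention.

#' Read a mono PCM WAV file
#'
#' Reads a mono WAV file and returns a [heart_sound_record()]. Integer PCM
#' samples are rescaled to the interval \eqn{[-1, 1]}; float samples are
#' taken as stored. Multi-channel files are rejected: heart-sound analysis
#' here is defined on single-channel recordings.
#'
#' @param path Path to a mono PCM WAV file.
#' @param record_id Identifier for the record; defaults to the file name
#'   without extension.
#' @return A `heart_sound_record` with `label` unset.
#' @export
read_wav <- function(path, record_id = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("WAV file not found: '%s'", path), call. = FALSE)
  }
  con <- file(path, "rb")
  on.exit(close(con))

  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) {
    stop(sprintf("'%s' is not a RIFF/WAVE file", path), call. = FALSE)
  }
  readBin(con, "integer", 1, 4, endian = "little")  # chunk size, unused
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) {
    stop(sprintf("'%s' is not a RIFF/WAVE file", path), call. = FALSE)
  }

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (length(size) == 0L || is.na(size) || size < 0) {
      stop(sprintf("corrupt chunk header in '%s'", path), call. = FALSE)
    }
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", size)
      if (length(body) < 16L) {
        stop(sprintf("corrupt fmt chunk in '%s'", path), call. = FALSE)
      }
      u16 <- function(i) sum(as.integer(body[i:(i + 1L)]) * c(1L, 256L))
      u32 <- function(i) sum(as.numeric(body[i:(i + 3L)]) * 256^(0:3))
      fmt <- list(
        audio_format = u16(1L), n_channels = u16(3L),
        sample_rate = u32(5L), bits = u16(15L)
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      readBin(con, "raw", size)
    }
    if (size %% 2L == 1L) readBin(con, "raw", 1L)  # chunks are word-aligned
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    stop(sprintf("'%s' is missing fmt or data chunk", path), call. = FALSE)
  }
  if (fmt$n_channels != 1L) {
    stop(sprintf("mono required: '%s' has %d channels", path, fmt$n_channels),
         call. = FALSE)
  }

  bytes <- fmt$bits %/% 8L
  n <- length(data_raw) %/% bytes
  if (n == 0L) stop(sprintf("'%s' contains no samples", path), call. = FALSE)
  data_raw <- data_raw[seq_len(n * bytes)]

  samples <- switch(
    as.character(fmt$audio_format),
    "1" = {  # integer PCM
      if (fmt$bits == 8L) {
        # 8-bit WAV is unsigned, midpoint 128
        (as.numeric(data_raw) - 128) / 128
      } else if (fmt$bits == 16L) {
        readBin(data_raw, "integer", n, 2, signed = TRUE,
                endian = "little") / 32768
      } else if (fmt$bits == 24L) {
        m <- matrix(as.numeric(data_raw), nrow = 3L)
        v <- m[1L, ] + 256 * m[2L, ] + 65536 * m[3L, ]
        ifelse(v >= 2^23, v - 2^24, v) / 2^23
      } else if (fmt$bits == 32L) {
        readBin(data_raw, "integer", n, 4, endian = "little") / 2^31
      } else {
        stop(sprintf("unsupported PCM bit depth: %d", fmt$bits), call. = FALSE)
      }
    },
    "3" = {  # IEEE float
      readBin(data_raw, "double", n, bytes, endian = "little")
    },
    stop(sprintf("unsupported WAV audio format code: %d", fmt$audio_format),
         call. = FALSE)
  )
  if (is.null(record_id)) {
    record_id <- tools::file_path_sans_ext(basename(path))
  }
  heart_sound_record(samples, fmt$sample_rate, record_id)
}

#' Write a record to a 16-bit mono PCM WAV file
#'
#' Amplitudes are clipped to \eqn{[-1, 1]} and quantised to 16-bit PCM.
#'
#' @param record A [heart_sound_record()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(record, path) {
  stopifnot(inherits(record, "heart_sound_record"))
  x <- pmin(1, pmax(-1, record$samples))
  pcm <- as.integer(round(x * 32767))
  n_bytes <- length(pcm) * 2L
  rate <- as.integer(round(record$sampling_rate))

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")       # PCM
  writeBin(1L, con, size = 2, endian = "little")       # mono
  writeBin(rate, con, size = 4, endian = "little")
  writeBin(rate * 2L, con, size = 4, endian = "little")  # byte rate
  writeBin(2L, con, size = 2, endian = "little")       # block align
  writeBin(16L, con, size = 2, endian = "little")      # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(n_bytes), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
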