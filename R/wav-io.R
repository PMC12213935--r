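#' Write a waveform to a PCM WAV file
#'
#' Writes full-scale-normalized samples (amplitudes in `[-1, 1]`) to a
#' RIFF/WAVE file. Integer PCM encoding maps amplitude `x` to
#' `round(x * 2^(bit_depth - 1))`, clamped to the representable range, so the
#' quantization round-trip error is at most `2^-(bit_depth - 1)`.
#'
#' @param samples Numeric vector (mono) or matrix with one column per channel.
#' @param sample_rate Sampling rate in Hz.
#' @param path Output file path.
#' @param bit_depth One of 8, 16, 24, 32 (integer PCM) or "float32".
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, sample_rate, path, bit_depth = 16) {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1)
  stopifnot(is.matrix(samples), nrow(samples) > 0, sample_rate > 0)
  n_ch <- ncol(samples)
  n <- nrow(samples)
  is_float <- identical(bit_depth, "float32")
  bd <- if (is_float) 32L else as.integer(bit_depth)
  if (!is_float && !bd %in% c(8L, 16L, 24L, 32L)) {
    abort_vrt("bit_depth must be 8, 16, 24, 32 or 'float32'", "wav_format_error")
  }
  block_align <- n_ch * bd / 8L
  data_bytes <- n * block_align
  # interleave channels
  x <- as.numeric(t(samples))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(if (is_float) 3L else 1L, con, size = 2, endian = "little")
  writeBin(as.integer(n_ch), con, size = 2, endian = "little")
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * block_align), con, size = 4, endian = "little")
  writeBin(as.integer(block_align), con, size = 2, endian = "little")
  writeBin(bd, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  if (is_float) {
    writeBin(x, con, size = 4, endian = "little")
  } else {
    full <- 2^(bd - 1)
    ints <- pmin(pmax(round(x * full), -full), full - 1)
    if (bd == 8L) {
      writeBin(as.raw(ints + 128), con)
    } else if (bd == 24L) {
      u <- ifelse(ints < 0, ints + 16777216, ints)
      raw3 <- rbind(u %% 256, (u %/% 256) %% 256, (u %/% 65536) %% 256)
      writeBin(as.raw(as.vector(raw3)), con)
    } else {
      writeBin(as.integer(ints), con, size = bd / 8L, endian = "little")
    }
  }
  invisible(path)
}

#' Read a PCM WAV file
#'
#' Parses a RIFF/WAVE file (integer PCM 8/16/24/32-bit or IEEE float) and
#' returns full-scale-normalized amplitudes: integer sample `v` maps to
#' `v / 2^(bit_depth - 1)` (so the most negative 16-bit value -32768 maps to
#' exactly -1.0); float data are clipped to `[-1, 1]`.
#'
#' @param path Path to a WAV file.
#' @return A list with `samples` (numeric matrix, one column per channel),
#'   `sample_rate`, `bit_depth` and `encoding` ("pcm" or "float").
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) {
    abort_vrt(paste0("cannot read WAV file: ", path), "wav_io_error")
  }
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  invisible(readBin(con, "integer", size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE")) {
    abort_vrt(paste0("not a RIFF/WAVE file: ", path), "wav_format_error")
  }
  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", size = 4, endian = "little")
    if (id == "fmt ") {
      body <- readBin(con, "raw", n = size)
      u16 <- function(i) as.integer(body[i]) + 256L * as.integer(body[i + 1])
      u32 <- function(i) sum(as.numeric(body[i:(i + 3)]) * 256^(0:3))
      fmt <- list(audio_format = u16(1), n_channels = u16(3),
                  sample_rate = u32(5), bit_depth = u16(15))
    } else if (id == "data") {
      data_raw <- readBin(con, "raw", n = size)
    } else {
      invisible(readBin(con, "raw", n = size + size %% 2))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    abort_vrt(paste0("missing fmt/data chunk in WAV file: ", path), "wav_format_error")
  }
  bd <- fmt$bit_depth
  n_ch <- fmt$n_channels
  if (fmt$audio_format == 1L) {
    x <- switch(as.character(bd),
      "8"  = (as.integer(data_raw) - 128) / 128,
      "16" = readBin(data_raw, "integer", n = length(data_raw) / 2,
                     size = 2, signed = TRUE, endian = "little") / 32768,
      "24" = {
        m <- matrix(as.integer(data_raw), nrow = 3)
        v <- m[1, ] + 256 * m[2, ] + 65536 * m[3, ]
        ifelse(v >= 8388608, v - 16777216, v) / 8388608
      },
      "32" = readBin(data_raw, "integer", n = length(data_raw) / 4,
                     size = 4, endian = "little") / 2147483648,
      abort_vrt(paste0("unsupported PCM bit depth: ", bd), "wav_format_error")
    )
    enc <- "pcm"
  } else if (fmt$audio_format == 3L) {
    x <- readBin(data_raw, "numeric", n = length(data_raw) / (bd / 8),
                 size = bd / 8, endian = "little")
    x <- pmin(pmax(x, -1), 1)
    enc <- "float"
  } else {
    abort_vrt(paste0("unsupported WAV encoding code: ", fmt$audio_format),
              "wav_format_error")
  }
  samples <- matrix(x, ncol = n_ch, byrow = TRUE)
  list(samples = samples, sample_rate = fmt$sample_rate,
       bit_depth = bd, encoding = enc)
}
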