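#' Audio recording container
#'
#' Holds full-scale-normalized samples for one test-attempt recording:
#' amplitudes lie in `[-1, 1]`, one matrix column per channel.
#'
#' @param samples Numeric vector (mono) or matrix (one column per channel).
#' @param sample_rate Sampling rate in Hz.
#' @param bit_depth Source bit depth (metadata; samples are already
#'   normalized).
#' @param source_id Opaque identifier for the attempt.
#' @return An `audio_recording` object.
#' @export
audio_recording <- function(samples, sample_rate, bit_depth = 16,
                            source_id = NA_character_) {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1)
  stopifnot(is.matrix(samples), ncol(samples) >= 1, sample_rate > 0)
  if (nrow(samples) > 0 && max(abs(samples)) > 1 + 1e-9) {
    abort_vrt("normalized amplitudes must lie in [-1, 1]", "argument_error")
  }
  structure(list(samples = samples,
                 sample_rate = sample_rate,
                 n_channels = ncol(samples),
                 bit_depth = bit_depth,
                 source_id = source_id),
            class = "audio_recording")
}

#' @export
print.audio_recording <- function(x, ...) {
  cat(sprintf("<audio_recording %s: %d samples x %d ch @ %g Hz>\n",
              x$source_id, nrow(x$samples), x$n_channels, x$sample_rate))
  invisible(x)
}

#' Read a WAV file as a normalized recording
#'
#' Integer PCM samples are converted to `[-1, 1]` by dividing by the full
#' scale `2^(bit_depth - 1)`; float-encoded WAV data are passed through
#' clipped to `[-1, 1]`. This full-scale conversion (rather than per-file
#' peak scaling) preserves absolute amplitude differences across recordings,
#' which the threshold rule depends on: peak scaling would force every
#' recording's maximum to 1 and make every file cross any threshold below 1.
#'
#' @param path Path to a PCM or IEEE-float WAV file.
#' @return An [audio_recording()]; `source_id` is the file name without
#'   extension.
#' @export
read_recording <- function(path) {
  w <- read_wav(path)
  audio_recording(w$samples, w$sample_rate, w$bit_depth,
                  source_id = sub("\\.[Ww][Aa][Vv]$", "", basename(path)))
}

#' Select one channel of a recording
#'
#' The analysis uses the left channel (channel 1) of each recording; mono
#' input with the default channel is returned unchanged.
#'
#' @param rec An [audio_recording()].
#' @param channel 1-based channel index (1 = left).
#' @return A mono [audio_recording()].
#' @export
select_channel <- function(rec, channel = 1L) {
  stopifnot(inherits(rec, "audio_recording"))
  if (channel < 1 || channel > rec$n_channels) {
    abort_vrt(sprintf("channel %d not present (recording has %d)",
                      channel, rec$n_channels), "argument_error")
  }
  if (rec$n_channels == 1L && channel == 1L) return(rec)
  audio_recording(rec$samples[, channel, drop = FALSE], rec$sample_rate,
                  rec$bit_depth, rec$source_id)
}

#' Optional high-pass prefilter
#'
#' A Butterworth high-pass applied forward-backward (zero phase). No filter
#' is applied by default anywhere in the pipeline; this exists to suppress
#' low-frequency rumble when recordings warrant it.
#'
#' @param rec A mono [audio_recording()].
#' @param cutoff_hz Cutoff frequency in Hz.
#' @param order Filter order.
#' @return A filtered [audio_recording()] (clipped to `[-1, 1]`).
#' @export
highpass <- function(rec, cutoff_hz, order = 4L) {
  stopifnot(inherits(rec, "audio_recording"), rec$n_channels == 1L,
            cutoff_hz > 0, cutoff_hz < rec$sample_rate / 2)
  bf <- signal::butter(order, cutoff_hz / (rec$sample_rate / 2), type = "high")
  y <- signal::filtfilt(bf, as.numeric(rec$samples))
  audio_recording(pmin(pmax(y, -1), 1), rec$sample_rate, rec$bit_depth,
                  rec$source_id)
}

#' Detect speech onset by amplitude threshold
#'
#' The onset is the first sample whose absolute normalized amplitude strictly
#' exceeds `threshold` (default 0.3 of full scale); ties at exactly the
#' threshold are not onsets. With `min_duration_samples > 0` the exceedance
#' must additionally begin a run of at least that many consecutive samples
#' with absolute amplitude at or above the threshold, which guards against
#' single-sample click artifacts. A recording with no qualifying sample is
#' classified non-speech. The verbal reaction time (VRT) is the time from
#' recording start to the onset: `onset_index / sample_rate`, with
#' `onset_index` counted zero-based.
#'
#' @param rec A mono [audio_recording()] with normalized amplitudes.
#' @param threshold Amplitude threshold in (0, 1).
#' @param min_duration_samples Minimum run length at/above threshold (0
#'   disables the run requirement).
#' @return A one-row tibble: `source_id`, `is_speech`, `onset_index`
#'   (zero-based, `NA` for non-speech), `vrt_seconds`, `threshold`,
#'   `min_duration_samples`.
#' @export
#' @examples
#' rec <- audio_recording(c(0.1, 0.2, 0.9, 0.9), 4)
#' detect_onset(rec)
detect_onset <- function(rec, threshold = 0.3, min_duration_samples = 0L) {
  stopifnot(inherits(rec, "audio_recording"))
  if (rec$n_channels != 1L) {
    abort_vrt("detect_onset needs a mono recording; use select_channel()",
              "argument_error")
  }
  x <- as.numeric(rec$samples)
  if (length(x) == 0) abort_vrt("empty signal", "argument_error")
  if (threshold <= 0 || threshold >= 1) {
    abort_vrt("threshold must lie strictly inside (0, 1)", "argument_error")
  }
  a <- abs(x)
  strict <- a > threshold
  need <- max(1L, as.integer(min_duration_samples))
  if (need > 1L) {
    ge <- a >= threshold
    r <- rle(ge)
    run_end <- rep.int(cumsum(r$lengths), r$lengths)
    fwd <- ifelse(ge, run_end - seq_along(x) + 1L, 0L)
    ok <- strict & fwd >= need
  } else {
    ok <- strict
  }
  i <- which(ok)[1]
  is_speech <- !is.na(i)
  tibble::tibble(
    source_id = rec$source_id,
    is_speech = is_speech,
    onset_index = if (is_speech) i - 1L else NA_integer_,
    vrt_seconds = if (is_speech) (i - 1L) / rec$sample_rate else NA_real_,
    threshold = threshold,
    min_duration_samples = as.integer(min_duration_samples))
}

#' Extract onsets from a batch of recordings
#'
#' Runs channel selection and onset detection over WAV paths or in-memory
#' recordings, returning one row per input in input order. Per-file failures
#' are recorded in the `error` column and do not abort the batch. A summary
#' of speech/non-speech counts is emitted as a message.
#'
#' @param x Character vector of WAV paths, or a list of
#'   [audio_recording()]s.
#' @param threshold Amplitude threshold, see [detect_onset()].
#' @param min_duration_samples See [detect_onset()].
#' @param channel Channel used for detection (1 = left).
#' @param highpass_hz Optional high-pass cutoff applied before detection
#'   (`NULL`, the default, applies no filter).
#' @return A tibble of onset results with an `error` column (`NA` on
#'   success).
#' @export
batch_extract <- function(x, threshold = 0.3, min_duration_samples = 0L,
                          channel = 1L, highpass_hz = NULL) {
  get_rec <- if (is.character(x)) {
    function(i) read_recording(x[i])
  } else {
    function(i) x[[i]]
  }
  n <- length(x)
  if (n == 0) {
    return(tibble::tibble(source_id = character(0), is_speech = logical(0),
                          onset_index = integer(0), vrt_seconds = numeric(0),
                          threshold = numeric(0),
                          min_duration_samples = integer(0),
                          error = character(0)))
  }
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    rows[[i]] <- tryCatch({
      rec <- select_channel(get_rec(i), channel)
      if (!is.null(highpass_hz)) rec <- highpass(rec, highpass_hz)
      res <- detect_onset(rec, threshold, min_duration_samples)
      res$error <- NA_character_
      res
    }, error = function(e) {
      tibble::tibble(
        source_id = if (is.character(x)) {
          sub("\\.[Ww][Aa][Vv]$", "", basename(x[i]))
        } else NA_character_,
        is_speech = NA, onset_index = NA_integer_, vrt_seconds = NA_real_,
        threshold = threshold,
        min_duration_samples = as.integer(min_duration_samples),
        error = conditionMessage(e))
    })
  }
  out <- dplyr::bind_rows(rows)
  message(sprintf("batch_extract: %d speech, %d non-speech, %d failed (n = %d)",
                  sum(out$is_speech, na.rm = TRUE),
                  sum(!out$is_speech, na.rm = TRUE),
                  sum(!is.na(out$error)), nrow(out)))
  out
}

#' Mel-frequency cepstral coefficients
#'
#' Computes MFCCs for audit plots during manual validation (they play no role
#' in speech classification, which uses the amplitude threshold alone).
#' Frames are Hamming-windowed, the power spectrum is passed through a
#' triangular mel filterbank spanning 0 to Nyquist, and log filterbank
#' energies are decorrelated with an orthonormal DCT-II. The frame count is
#' `floor((N - frame_length) / hop_length) + 1`.
#'
#' @param rec A mono [audio_recording()].
#' @param frame_length Frame length in samples.
#' @param hop_length Hop between frame starts in samples.
#' @param n_coefficients Number of cepstral coefficients returned per frame.
#' @param n_mels Number of mel filterbank bands.
#' @return A frames-by-coefficients numeric matrix.
#' @export
compute_mfcc <- function(rec, frame_length = 512L, hop_length = 256L,
                         n_coefficients = 13L, n_mels = 26L) {
  stopifnot(inherits(rec, "audio_recording"), rec$n_channels == 1L)
  x <- as.numeric(rec$samples)
  N <- length(x)
  if (frame_length > N) {
    abort_vrt("signal shorter than one frame", "argument_error")
  }
  n_frames <- (N - frame_length) %/% hop_length + 1L
  win <- 0.54 - 0.46 * cos(2 * pi * seq_len(frame_length) / (frame_length - 1))
  n_fft_bins <- frame_length %/% 2 + 1L

  hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
  mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)
  mel_pts <- mel_to_hz(seq(hz_to_mel(0), hz_to_mel(rec$sample_rate / 2),
                           length.out = n_mels + 2))
  bin_hz <- (seq_len(n_fft_bins) - 1) * rec$sample_rate / frame_length
  fbank <- matrix(0, n_mels, n_fft_bins)
  for (m in seq_len(n_mels)) {
    lo <- mel_pts[m]; mid <- mel_pts[m + 1]; hi <- mel_pts[m + 2]
    up <- (bin_hz - lo) / (mid - lo)
    down <- (hi - bin_hz) / (hi - mid)
    fbank[m, ] <- pmax(0, pmin(up, down))
  }
  # orthonormal DCT-II basis (n_coefficients x n_mels)
  j <- seq_len(n_mels) - 0.5
  dct <- sapply(seq_len(n_mels), function(jj) {
    cos(pi * (seq_len(n_coefficients) - 1) * j[jj] / n_mels)
  })
  dct <- dct * sqrt(2 / n_mels)
  dct[1, ] <- dct[1, ] / sqrt(2)

  out <- matrix(NA_real_, n_frames, n_coefficients)
  for (f in seq_len(n_frames)) {
    seg <- x[((f - 1L) * hop_length + 1L):((f - 1L) * hop_length + frame_length)]
    spec <- Mod(stats::fft(seg * win))[seq_len(n_fft_bins)]^2
    mel_e <- as.numeric(fbank %*% spec)
    out[f, ] <- as.numeric(dct %*% log(mel_e + 1e-12))
  }
  out
}
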