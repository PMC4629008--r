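#' Construct an audio signal object
#'
#' Lightweight container for a mono sampled waveform. Samples are real-valued
#' amplitudes in `[-1, 1]`; `sample_rate` is in Hz.
#'
#' @param samples numeric vector of amplitudes.
#' @param sample_rate sampling rate in Hz (>= 8000).
#' @return An object of class `audio_signal` with fields `samples`,
#'   `sample_rate` and `duration` (seconds).
#' @export
audio_signal <- function(samples, sample_rate) {
  if (!is.numeric(samples) || length(samples) == 0L)
    stop("degenerate input: empty or non-numeric sample vector", call. = FALSE)
  if (any(!is.finite(samples)))
    stop("samples must all be finite", call. = FALSE)
  sample_rate <- as.integer(sample_rate)
  if (is.na(sample_rate) || sample_rate < 8000L)
    stop("sample_rate must be an integer >= 8000 Hz", call. = FALSE)
  peak <- max(abs(samples))
  if (peak > 1) samples <- samples / peak   # peak-normalize out-of-range float input
  structure(
    list(samples = as.numeric(samples),
         sample_rate = sample_rate,
         duration = length(samples) / sample_rate),
    class = "audio_signal")
}

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf("<audio_signal> %d samples @ %d Hz (%.3f s), peak %.3f\n",
              length(x$samples), x$sample_rate, x$duration, max(abs(x$samples))))
  invisible(x)
}

## ---- RIFF/WAV parsing -------------------------------------------------------
## No WAV reader ships with base R; this is a minimal RIFF PCM parser covering
## 8/16/24/32-bit integer and 32-bit IEEE float, mono or stereo.

read_wav_raw <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("format error: not a RIFF file: ", path, call. = FALSE)
  readBin(con, "integer", 1, 4, endian = "little")   # overall size, unused
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("format error: not a WAVE file: ", path, call. = FALSE)

  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (length(sz) == 0L) break
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", sz)
      hdr <- function(off, w) {
        v <- 0
        for (k in seq_len(w)) v <- v + as.integer(body[off + k]) * 256^(k - 1)
        v
      }
      fmt <- list(code = hdr(0L, 2L), channels = hdr(2L, 2L),
                  rate = hdr(4L, 4L), bits = hdr(14L, 2L))
      if (fmt$code == 65534 && sz >= 26) # WAVE_FORMAT_EXTENSIBLE: sub-format GUID head
        fmt$code <- hdr(24L, 2L)
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      readBin(con, "raw", sz + (sz %% 2L))           # skip unknown chunk (word aligned)
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw))
    stop("format error: missing fmt/data chunk in ", path, call. = FALSE)
  list(fmt = fmt, data = data_raw)
}

decode_pcm <- function(raw, fmt) {
  bits <- fmt$bits; code <- fmt$code
  if (code == 1L && bits == 8L) {
    x <- (as.integer(raw) - 128L) / 128
  } else if (code == 1L && bits == 16L) {
    x <- readBin(raw, "integer", length(raw) / 2L, 2L, signed = TRUE,
                 endian = "little") / 32768
  } else if (code == 1L && bits == 24L) {
    n <- length(raw) %/% 3L
    b <- matrix(as.integer(raw[seq_len(3L * n)]), nrow = 3L)
    v <- b[1L, ] + b[2L, ] * 256 + b[3L, ] * 65536
    v <- ifelse(v >= 8388608, v - 16777216, v)
    x <- v / 8388608
  } else if (code == 1L && bits == 32L) {
    x <- readBin(raw, "integer", length(raw) / 4L, 4L, signed = TRUE,
                 endian = "little") / 2147483648
  } else if (code == 3L && bits == 32L) {
    x <- readBin(raw, "numeric", length(raw) / 4L, 4L, endian = "little")
  } else {
    stop("format error: unsupported WAV encoding (format code ", code,
         ", ", bits, "-bit)", call. = FALSE)
  }
  x
}

#' Load a WAV file as a mono audio signal
#'
#' Reads a RIFF PCM WAV file (8/16/24/32-bit integer or 32-bit float, mono or
#' stereo) and returns a mono [audio_signal]. For stereo recordings made with
#' separate patient/clinician microphones the patient channel is conventionally
#' the left one, which is the default selection.
#'
#' @param path path to a `.wav` file.
#' @param channel for stereo input: `"left"`, `"right"`, or `"mix"`
#'   (average of the two channels). Ignored for mono files.
#' @return An [audio_signal].
#' @export
load_audio <- function(path, channel = c("left", "right", "mix")) {
  channel <- match.arg(channel)
  if (!file.exists(path)) stop("input error: file not found: ", path, call. = FALSE)
  w <- read_wav_raw(path)
  x <- decode_pcm(w$data, w$fmt)
  nch <- w$fmt$channels
  if (length(x) == 0L) stop("degenerate input: zero-length audio in ", path, call. = FALSE)
  if (nch >= 2L) {
    n <- length(x) %/% nch
    x <- matrix(x[seq_len(n * nch)], nrow = nch)
    x <- switch(channel, left = x[1L, ], right = x[2L, ], mix = colMeans(x[1:2, , drop = FALSE]))
  }
  audio_signal(x, w$fmt$rate)
}

#' Write a mono or stereo signal as 16-bit PCM WAV
#'
#' @param samples numeric vector (mono) or 2-row matrix (stereo) in `[-1, 1]`.
#' @param sample_rate sampling rate in Hz.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, sample_rate, path) {
  if (inherits(samples, "audio_signal")) {
    sample_rate <- samples$sample_rate
    samples <- samples$samples
  }
  if (is.matrix(samples)) {
    nch <- nrow(samples)
    x <- as.vector(samples)                          # column-major = interleaved frames
  } else {
    nch <- 1L
    x <- samples
  }
  q <- as.integer(pmax(pmin(round(x * 32768), 32767), -32768))
  bytes_data <- length(q) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + bytes_data), con, 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4L, endian = "little")
  writeBin(c(1L, nch), con, 2L, endian = "little")               # PCM, channels
  writeBin(as.integer(sample_rate), con, 4L, endian = "little")
  writeBin(as.integer(sample_rate * nch * 2L), con, 4L, endian = "little")
  writeBin(c(as.integer(nch * 2L), 16L), con, 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(bytes_data, con, 4L, endian = "little")
  writeBin(q, con, 2L, endian = "little")
  invisible(path)
}

#' Slice a signal into overlapping analysis frames
#'
#' Frame length and hop are `floor(seconds * sample_rate)` samples, so at
#' 44.1 kHz a 5 ms hop is exactly 220 samples. Only frames lying fully inside
#' the signal are kept: `n_frames = floor((N - L) / H) + 1`.
#'
#' @param signal an [audio_signal].
#' @param window_s frame length in seconds.
#' @param hop_s hop (frame step) in seconds; `0 < hop_s <= window_s`.
#' @return A `frame_series`: list with `frames` (L x n matrix, one frame per
#'   column), `frame_times` (frame centers, seconds), `window_s`, `hop_s`.
#' @export
frame_signal <- function(signal, window_s, hop_s) {
  stopifnot(inherits(signal, "audio_signal"))
  fs <- signal$sample_rate
  L <- floor(window_s * fs)
  H <- floor(hop_s * fs)
  if (H <= 0L || L < H) stop("require 0 < hop_s <= window_s", call. = FALSE)
  N <- length(signal$samples)
  if (L > N) stop("degenerate input: window longer than signal", call. = FALSE)
  nf <- (N - L) %/% H + 1L
  starts <- (seq_len(nf) - 1L) * H + 1L
  idx <- outer(seq_len(L) - 1L, starts, "+")
  structure(
    list(frames = matrix(signal$samples[idx], nrow = L),
         frame_times = (starts - 1 + L / 2) / fs,
         window_s = window_s, hop_s = hop_s,
         sample_rate = fs, frame_length = L, hop_length = H),
    class = "frame_series")
}
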