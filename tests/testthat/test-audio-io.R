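test_that("16-bit PCM WAV round-trips bit-exactly, mono and stereo", {
  fs <- 16000
  x <- round(runif(2000, -1, 1) * 32767) / 32768
  p <- withr::local_tempfile(fileext = ".wav")
  write_wav(x, fs, p)
  sig <- load_audio(p)
  expect_identical(sig$samples, x)
  expect_equal(sig$sample_rate, fs)

  left <- round(runif(500, -1, 1) * 32767) / 32768
  right <- round(runif(500, -1, 1) * 32767) / 32768
  write_wav(rbind(left, right), 44100, p)
  expect_identical(load_audio(p, "left")$samples, left)
  expect_identical(load_audio(p, "right")$samples, right)
  expect_equal(load_audio(p, "mix")$samples, (left + right) / 2)
  expect_equal(load_audio(p, "left")$sample_rate, 44100)
})

test_that("integer full-scale maps to 32767/32768 and duration = N/rate", {
  p <- withr::local_tempfile(fileext = ".wav")
  write_wav(c(1, -1, 0), 16000, p)  # clipped to int16 full scale
  s <- load_audio(p)
  expect_equal(s$samples[1], 32767 / 32768)
  expect_equal(s$samples[2], -1)
  write_wav(rep(0.1, 44100), 44100, p)
  expect_equal(load_audio(p)$duration, 1.0)
})

test_that("8-bit, 24-bit and 32-bit float encodings decode", {
  p <- withr::local_tempfile(fileext = ".wav")
  write_wav_generic <- function(path, payload, code, bits, rate = 16000) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar("RIFF", con, eos = NULL)
    writeBin(as.integer(36L + length(payload)), con, 4L, endian = "little")
    writeChar("WAVEfmt ", con, eos = NULL)
    writeBin(16L, con, 4L, endian = "little")
    writeBin(c(as.integer(code), 1L), con, 2L, endian = "little")
    writeBin(as.integer(rate), con, 4L, endian = "little")
    writeBin(as.integer(rate * bits / 8), con, 4L, endian = "little")
    writeBin(c(as.integer(bits / 8), as.integer(bits)), con, 2L, endian = "little")
    writeChar("data", con, eos = NULL)
    writeBin(length(payload), con, 4L, endian = "little")
    writeBin(payload, con)
  }
  # 8-bit unsigned: 128 -> 0, 255 -> 127/128
  write_wav_generic(p, as.raw(c(128, 255, 0)), 1, 8)
  expect_equal(load_audio(p)$samples, c(0, 127 / 128, -1))
  # 32-bit float
  write_wav_generic(p, writeBin(c(0.5, -0.25), raw(), 4, endian = "little"), 3, 32)
  expect_equal(load_audio(p)$samples, c(0.5, -0.25), tolerance = 1e-7)
  # 24-bit: value 2^23 - 1 -> ~1
  write_wav_generic(p, as.raw(c(0xFF, 0xFF, 0x7F, 0x00, 0x00, 0x80)), 1, 24)
  expect_equal(load_audio(p)$samples, c((2^23 - 1) / 2^23, -1))
  # unsupported format code
  write_wav_generic(p, as.raw(c(1, 2)), 2, 8)
  expect_error(load_audio(p), "unsupported")
})

test_that("loader rejects missing and degenerate input", {
  expect_error(load_audio("/nonexistent/x.wav"), "not found")
  p <- withr::local_tempfile(fileext = ".wav")
  write_wav(numeric(0), 16000, p)
  expect_error(load_audio(p), "zero-length")
})

test_that("frame count formula holds and frames stay inside the signal", {
  fs <- 1000
  set.seed(11)
  for (rep in 1:20) {
    N <- sample(100:5000, 1)
    L <- sample(10:min(N, 400), 1)
    H <- sample(1:L, 1)
    sig <- audio_signal(runif(N, -0.5, 0.5), 16000)
    # +0.1 sample guards against float round-down in floor(seconds * rate)
    fr <- frame_signal(sig, (L + 0.1) / 16000, (H + 0.1) / 16000)
    expect_equal(ncol(fr$frames), (N - L) %/% H + 1L)
    last_start <- (ncol(fr$frames) - 1L) * H + 1L
    expect_lte(last_start + L - 1L, N)
    expect_equal(diff(fr$frame_times), rep(H / 16000, ncol(fr$frames) - 1L))
  }
  # worked case: 1 s at 44.1 kHz, 10 ms / 5 ms -> L=441, H=220, 199 frames
  sig <- audio_signal(rep(0.1, 44100), 44100)
  fr <- frame_signal(sig, 0.010, 0.005)
  expect_equal(fr$frame_length, 441L)
  expect_equal(fr$hop_length, 220L)
  expect_equal(ncol(fr$frames), 199L)
  # window = hop -> non-overlapping
  fr2 <- frame_signal(sig, 0.010, 0.010)
  expect_equal(fr2$hop_length, fr2$frame_length)
  # window longer than signal
  expect_error(frame_signal(audio_signal(rep(0.1, 100), 16000), 2, 0.5),
               "window longer")
})
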