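test_that("envelope of silence is zero and resolution follows the floor rule", {
  env <- compute_envelope(audio_signal(numeric(44100), 44100))
  expect_true(all(env$values == 0))
  expect_equal(diff(env$frame_times)[1], 220 / 44100, tolerance = 1e-12)
})

test_that("envelope peaks where a Hann tone burst is centered (brute-force RMS oracle)", {
  fs <- 16000
  x <- numeric(fs)
  L <- round(0.150 * fs)
  i0 <- round(0.5 * fs) - round(L / 2)
  burst <- sin(2 * pi * 440 * seq_len(L) / fs) *
    (0.5 - 0.5 * cos(2 * pi * (seq_len(L) - 1) / (L - 1)))
  x[i0:(i0 + L - 1)] <- 0.8 * burst
  sig <- audio_signal(x, fs)
  env <- compute_envelope(sig, band = c(100, 3000))
  expect_lt(abs(env$frame_times[which.max(env$values)] - 0.5), 0.010)
  # independent oracle: plain per-frame RMS of the raw signal
  Lf <- floor(0.010 * fs); H <- floor(0.005 * fs)
  starts <- seq(1, length(x) - Lf + 1, by = H)
  rms <- vapply(starts, function(s) sqrt(mean(x[s:(s + Lf - 1)]^2)), 1)
  t_oracle <- (starts - 1 + Lf / 2)[which.max(rms)] / fs
  expect_lt(abs(t_oracle - 0.5), 0.010)
})

test_that("peak detection handles flat and two-bump envelopes", {
  expect_equal(length(detect_peaks(make_envelope(rep(1, 100)))), 0)
  bump <- c(rep(0.01, 10), 0.2, 0.6, 1.0, 0.6, 0.2, rep(0.01, 60),
            0.2, 0.6, 1.0, 0.6, 0.2, rep(0.01, 10))
  pk <- detect_peaks(make_envelope(bump), rel_threshold = 0.3, min_gap_s = 0.06)
  expect_equal(length(pk), 2)
})

test_that("peak detection is amplitude-scale invariant and monotone in threshold", {
  u <- synth_utterance(utterance_spec(n_syllables = 8, seed = 5))
  env1 <- compute_envelope(u$signal)
  half <- audio_signal(u$signal$samples * 0.4, u$signal$sample_rate)
  env2 <- compute_envelope(half)
  expect_equal(detect_peaks(env1), detect_peaks(env2))
  counts <- vapply(seq(0.1, 0.9, by = 0.1),
                   function(th) length(detect_peaks(env1, th)), 1)
  expect_true(all(diff(counts) <= 0))
})

test_that("boundaries come from envelope minima clipped by voicing limits", {
  # envelope on t = 0.90..1.10: minima at 0.95 and 1.06, peak at 1.00
  tt <- seq(0.90, 1.10, by = 0.005)
  v <- rep(0.8, length(tt))
  shape <- function(t0, val) v[which.min(abs(tt - t0))] <<- val
  shape(0.95, 0.05); shape(1.00, 1.2); shape(1.06, 0.02)
  # smooth-ish flanks so the argmin is unique
  v[tt > 0.95 & tt < 1.00] <- seq(0.1, 1.1, length.out = sum(tt > 0.95 & tt < 1.00))
  v[tt > 1.00 & tt < 1.06] <- seq(1.1, 0.1, length.out = sum(tt > 1.00 & tt < 1.06))
  env <- make_envelope(v, t0 = 0.90)
  env$frame_times <- tt
  nuc <- estimate_boundaries(1.00, env, data.frame(start = 0.90, end = 1.10))
  expect_equal(nuc$onset, 0.95, tolerance = 1e-9)
  expect_equal(nuc$offset, 1.06, tolerance = 1e-9)
  # vocal activity ends earlier -> offset clipped to 1.03
  nuc2 <- estimate_boundaries(1.00, env, data.frame(start = 0.90, end = 1.03))
  expect_equal(nuc2$offset, 1.03, tolerance = 1e-9)
  # rising envelope with a peak near t = 0: onset clips to the envelope start
  env3 <- make_envelope(c(0.5, 1.0, 0.4, 0.05, 0.04, 0.03, 0.02, 0.01, 0.005, 0.004))
  nuc3 <- estimate_boundaries(env3$frame_times[2], env3, NULL)
  expect_equal(nuc3$onset, 0)
  # peak outside the envelope span is inconsistent
  expect_error(estimate_boundaries(9.9, env, NULL), "consistency")
})

test_that("per-nucleus F0 annotation averages voiced frames and flags unvoiced nuclei", {
  tr <- make_track(c(NA, 100, 110, 120, NA, NA, NA, NA))
  nuc <- make_nuclei(onset = c(0.0025, 0.025), offset = c(0.0225, 0.0375))
  out <- annotate_f0(nuc, tr)
  expect_equal(out$mean_f0_hz[1], 110)
  expect_false(out$unvoiced[1])
  expect_true(is.na(out$mean_f0_hz[2]))
  expect_true(out$unvoiced[2])
})

test_that("clean synthetic utterances are recovered exactly with consistent nuclei", {
  u <- synth_utterance(utterance_spec(n_syllables = 10, f0_base_hz = c(140, 140),
                                      gap_s = c(0.08, 0.15), seed = 3))
  env <- compute_envelope(u$signal)
  expect_equal(length(detect_peaks(env)), 10)
  nuc <- detect_syllables(u$signal)
  expect_equal(nrow(nuc), 10)
  expect_true(all(nuc$onset <= nuc$peak_time & nuc$peak_time <= nuc$offset))
  expect_true(all(diff(nuc$onset) > 0))
  expect_true(all(nuc$offset[-nrow(nuc)] <= nuc$onset[-1] + 1e-9))  # disjoint
  expect_true(all(abs(12 * log2(nuc$mean_f0_hz / 140)) < 1))
})

test_that("TextGrid and nuclei table exports are well-formed", {
  nuc <- make_nuclei(c(0.2, 0.6), c(0.4, 0.8), f0_means = c(120, 130))
  p <- withr::local_tempfile(fileext = ".TextGrid")
  write_textgrid(nuc, 1.0, p)
  txt <- readLines(p)
  expect_true(any(grepl("IntervalTier", txt)))
  expect_equal(sum(grepl('text = "syl"', txt)), 2)
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_nuclei_table(nuc, p2)
  tab <- read.delim(p2)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$mean_f0_hz, c(120, 130))
})
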