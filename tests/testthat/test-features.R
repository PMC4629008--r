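test_that("pause rule is strictly 'over 0.3 s'", {
  # consecutive gaps 0.25, 0.35, 0.80 s
  on <- c(0, 0.45, 1.0, 2.0); off <- on + 0.2
  on[-1] <- off[-4] + c(0.25, 0.35, 0.80)
  off <- on + 0.2
  nuc <- make_nuclei(on, off, f0_means = 100)
  ps <- detect_pauses(nuc)
  expect_equal(nrow(ps$gaps), 2)
  expect_equal(ps$total_pause_s, 1.15, tolerance = 1e-12)
  # single nucleus: no pauses
  ps1 <- detect_pauses(make_nuclei(0, 0.2, f0_means = 100))
  expect_equal(nrow(ps1$gaps), 0)
  expect_equal(ps1$total_pause_s, 0)
  # a gap of exactly 0.3 s is not a pause
  nuc2 <- make_nuclei(c(0, 0.5), c(0.2, 0.7), f0_means = 100)
  expect_equal(nrow(detect_pauses(nuc2)$gaps), 0)
  expect_error(detect_pauses(make_nuclei(numeric(0), numeric(0))), "degenerate")
})

test_that("the three-nucleus worked example reproduces every hand-computed value", {
  nuc <- make_nuclei(c(0.0, 0.5, 1.2), c(0.2, 0.7, 1.4),
                     f0_means = c(100, 120, 140))
  fv <- compute_features(nuc)
  expect_equal(fv$SPT, 1.4)
  expect_equal(fv$NPU, 1)                       # gaps 0.3 (not a pause) and 0.5
  expect_equal(fv$PHT, 0.9)
  expect_equal(fv$PPU, 100 * 0.5 / 1.4)
  expect_equal(fv$PPH, 100 * 0.9 / 1.4)
  expect_equal(fv$SPR, 3 / 1.4)
  expect_equal(fv$ARR, 3 / 0.9)
  expect_equal(fv$NSY, 3)
  expect_equal(fv$MSD, 0.2)
  expect_equal(fv$MFF, 120)
  expect_equal(fv$SDF, 20)
  expect_equal(fv$MVF, 40)
})

test_that("feature algebra holds on random nucleus timelines", {
  set.seed(21)
  for (r in 1:100) {
    k <- sample(2:30, 1)
    dur <- runif(k, 0.05, 0.3)
    gap <- runif(k - 1, 0.02, 0.9)
    on <- cumsum(c(0.3, dur[-k] + gap))
    nuc <- make_nuclei(on, on + dur, f0_means = runif(k, 90, 250))
    fv <- compute_features(nuc)
    expect_equal(fv$PPU + fv$PPH, 100, tolerance = 1e-9)
    expect_equal(fv$SPT, fv$PHT + detect_pauses(nuc)$total_pause_s, tolerance = 1e-9)
    expect_gte(fv$ARR, fv$SPR)
    expect_lte(fv$SDF, fv$MVF)
  }
})

test_that("features are invariant to a global time shift", {
  nuc <- make_nuclei(c(0.1, 0.8, 2.0), c(0.3, 1.1, 2.2), f0_means = c(110, 130, 150))
  sh <- nuc
  sh$onset <- sh$onset + 13.7; sh$offset <- sh$offset + 13.7
  sh$peak_time <- sh$peak_time + 13.7
  f1 <- compute_features(nuc); f2 <- compute_features(sh)
  expect_equal(unlist(f1[feature_names]), unlist(f2[feature_names]))
})

test_that("self-concatenation doubles NSY and keeps ARR within 1%", {
  nuc <- synth_timeline(utterance_spec(n_syllables = 30, pause_positions = c(9, 21),
                                       seed = 12))$nuclei
  shift <- max(nuc$offset) - min(nuc$onset) + 0.05   # inter-copy gap 0.05 s < 0.3 s
  dbl <- rbind(nuc, within(nuc, { onset <- onset + shift
                                  offset <- offset + shift
                                  peak_time <- peak_time + shift }))
  class(dbl) <- class(nuc)
  f1 <- compute_features(nuc); f2 <- compute_features(dbl)
  expect_equal(f2$NSY, 2 * f1$NSY)
  expect_lt(abs(f2$ARR / f1$ARR - 1), 0.01)
})

test_that("semitone mode maps Hz features through 12*log2(f/f_ref)", {
  nuc <- make_nuclei(c(0, 0.5, 1.0), c(0.2, 0.7, 1.2), f0_means = c(100, 150, 200))
  fhz <- compute_features(nuc, f0_unit = "hz")
  fst <- compute_features(nuc, f0_unit = "st", f_ref = 100)
  expect_equal(fst$MFF, mean(12 * log2(c(100, 150, 200) / 100)))
  # a constant-F0 recording maps its MFF exactly through the ST transform
  ncst <- make_nuclei(c(0, 0.5), c(0.2, 0.7), f0_means = 150)
  expect_equal(compute_features(ncst, f0_unit = "st")$MFF,
               12 * log2(compute_features(ncst, f0_unit = "hz")$MFF / 100))
})

test_that("degenerate feature input is rejected or flagged", {
  expect_error(compute_features(make_nuclei(numeric(0), numeric(0))), "degenerate")
  nuc <- make_nuclei(c(0, 0.5), c(0.2, 0.7))
  nuc$mean_f0_hz <- c(NA_real_, NA_real_)
  nuc$f0 <- I(list(numeric(0), numeric(0)))
  fv <- compute_features(nuc)
  expect_false(fv$f0_defined)
  expect_true(is.na(fv$MFF) && is.na(fv$SDF) && is.na(fv$MVF))
  expect_equal(fv$NSY, 2)
})
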