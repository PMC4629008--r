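## Run expr with a temporary RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

#' Specification for a synthetic read-speech utterance
#'
#' Describes a train of voiced syllable bursts separated by short gaps, with
#' selected gaps replaced by silent pauses, plus additive white noise. The
#' seed fully determines the waveform.
#'
#' @param n_syllables number of syllables (>= 1).
#' @param syllable_duration_s `c(lo, hi)` uniform range of syllable durations.
#' @param gap_s `c(lo, hi)` uniform range of inter-syllable gaps.
#' @param pause_positions integer indices `i`: the gap after syllable `i` is
#'   drawn from `pause_s` instead of `gap_s`.
#' @param pause_s `c(lo, hi)` uniform range of pause durations.
#' @param f0_base_hz per-syllable base F0: `c(lo, hi)` uniform range, or
#'   `list(mean =, sd =, min =, max =)` truncated normal.
#' @param f0_glide_st within-syllable linear F0 glide in semitones (total
#'   excursion, centered on the base).
#' @param amplitude_range `c(lo, hi)` uniform per-syllable relative level.
#' @param snr_db additive white-noise level relative to speech RMS.
#' @param sample_rate sampling rate in Hz.
#' @param edge_silence_s leading/trailing silence in seconds.
#' @param seed integer RNG seed.
#' @return list of class `utterance_spec`.
#' @export
utterance_spec <- function(n_syllables = 10L,
                           syllable_duration_s = c(0.10, 0.25),
                           gap_s = c(0.05, 0.15),
                           pause_positions = integer(0),
                           pause_s = c(0.4, 1.0),
                           f0_base_hz = c(110, 180),
                           f0_glide_st = 0,
                           amplitude_range = c(0.7, 1.0),
                           snr_db = 30,
                           sample_rate = 16000L,
                           edge_silence_s = 0.25,
                           seed = 1L) {
  if (n_syllables < 1L) stop("validation error: n_syllables >= 1", call. = FALSE)
  for (rng in list(syllable_duration_s, gap_s, pause_s, amplitude_range))
    if (length(rng) != 2L || any(rng <= 0) || rng[1] > rng[2])
      stop("validation error: bad range parameter", call. = FALSE)
  if (any(pause_positions < 1L | pause_positions >= n_syllables))
    stop("validation error: pause_positions must lie in 1..(n_syllables-1)", call. = FALSE)
  structure(as.list(environment()), class = "utterance_spec")
}

## Draw a per-syllable base F0 vector from the spec's distribution.
draw_f0_base <- function(f0_base_hz, k) {
  if (is.list(f0_base_hz)) {
    lo <- f0_base_hz$min %||% 20
    hi <- f0_base_hz$max %||% Inf
    out <- numeric(k)
    for (i in seq_len(k)) {
      repeat {
        v <- stats::rnorm(1, f0_base_hz$mean, f0_base_hz$sd)
        if (v >= lo && v <= hi) break
      }
      out[i] <- v
    }
    out
  } else {
    stats::runif(k, f0_base_hz[1], f0_base_hz[2])
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sample the ground-truth timeline of an utterance spec
#'
#' Draws syllable durations, gaps/pauses, per-syllable F0 contours and
#' amplitudes, and returns the analytic ground truth (no waveform). The F0
#' contour of syllable `i` is `base_i * 2^(glide * (u - 1/2) / 12)` for
#' position `u` in `[0, 1]`.
#'
#' @param spec an [utterance_spec()].
#' @return list of class `ground_truth`: `nuclei` (data.frame `onset`,
#'   `offset`, `duration`, `mean_f0_hz`, list column `f0` sampled at 1 ms),
#'   `gaps` (the drawn gap lengths), `amplitudes`, `features` (the twelve
#'   features computed from the timeline), `spec`.
#' @export
synth_timeline <- function(spec) {
  stopifnot(inherits(spec, "utterance_spec"))
  with_local_seed(spec$seed, {
    k <- spec$n_syllables
    dur <- stats::runif(k, spec$syllable_duration_s[1], spec$syllable_duration_s[2])
    gaps <- if (k > 1L) stats::runif(k - 1L, spec$gap_s[1], spec$gap_s[2]) else numeric(0)
    if (length(spec$pause_positions))
      gaps[spec$pause_positions] <-
        stats::runif(length(spec$pause_positions), spec$pause_s[1], spec$pause_s[2])
    base <- draw_f0_base(spec$f0_base_hz, k)
    amp <- stats::runif(k, spec$amplitude_range[1], spec$amplitude_range[2])
    onset <- spec$edge_silence_s + c(0, cumsum(dur[-k] + gaps))
    offset <- onset + dur
    f0 <- vector("list", k)
    mean_f0 <- numeric(k)
    for (i in seq_len(k)) {
      u <- seq(0, 1, by = 0.001 / dur[i])
      f0[[i]] <- base[i] * 2^(spec$f0_glide_st * (u - 0.5) / 12)
      mean_f0[i] <- mean(f0[[i]])
    }
    nuc <- structure(
      data.frame(onset = onset, peak_time = (onset + offset) / 2,
                 offset = offset, duration = dur, mean_f0_hz = mean_f0),
      class = c("syllable_nuclei", "data.frame"))
    nuc$f0 <- I(f0)
    feats <- compute_features(nuc, detect_pauses(nuc))
    structure(list(nuclei = nuc, gaps = gaps, amplitudes = amp,
                   features = feats, spec = spec),
              class = "ground_truth")
  })
}

#' Synthesize a read-speech utterance with known ground truth
#'
#' The waveform is a concatenation of voiced syllable bursts — a harmonic
#' source at the specified F0 contour with 1/h spectral tilt and a Hann
#' amplitude envelope — separated by the drawn gaps, plus white noise at
#' `snr_db` relative to the speech RMS. Ground truth is computed analytically
#' from the timeline, never from the detector.
#'
#' @param spec an [utterance_spec()].
#' @return list with `signal` (an [audio_signal]) and `truth` (a
#'   `ground_truth`, see [synth_timeline()]).
#' @export
synth_utterance <- function(spec) {
  truth <- synth_timeline(spec)
  fs <- spec$sample_rate
  nuc <- truth$nuclei
  total <- nuc$offset[nrow(nuc)] + spec$edge_silence_s
  N <- ceiling(total * fs)
  x <- numeric(N)
  hmax_hz <- min(0.45 * fs, 5000)
  for (i in seq_len(nrow(nuc))) {
    i0 <- floor(nuc$onset[i] * fs) + 1L
    L <- max(8L, round(nuc$duration[i] * fs))
    u <- (seq_len(L) - 1) / (L - 1)
    f <- nuc$f0[[i]][pmin(floor(u * (length(nuc$f0[[i]]) - 1L)) + 1L, length(nuc$f0[[i]]))]
    phase <- 2 * pi * cumsum(f) / fs
    H <- max(1L, floor(hmax_hz / max(f)))
    s <- 0
    for (h in seq_len(H)) s <- s + sin(h * phase) / h
    s <- s * hann_window(L) * truth$amplitudes[i]
    idx <- i0:(i0 + L - 1L)
    ok <- idx <= N
    x[idx[ok]] <- x[idx[ok]] + s[ok]
  }
  rms_speech <- sqrt(mean(x[x != 0]^2))
  noise_sd <- rms_speech * 10^(-spec$snr_db / 20)
  x <- with_local_seed(if (is.null(spec$seed)) NULL else spec$seed + 10007L,
                       x + stats::rnorm(N, 0, noise_sd))
  x <- 0.9 * x / max(abs(x))
  list(signal = audio_signal(x, fs), truth = truth)
}

#' Reference two-group prosodic feature statistics
#'
#' Group-wise mean, SD and observed range for the twelve prosodic features in
#' a mild-dementia (MD) versus healthy-control (non-MD) read-speech cohort,
#' used as defaults by [synth_feature_cohort()]. Units: seconds (SPT, PHT,
#' MSD), counts (NPU, NSY), percent (PPU, PPH), syllables/s (SPR, ARR), Hz
#' (SDF, MVF, MFF).
#'
#' @return data.frame with columns `feature`, `group`, `mean`, `sd`, `lo`, `hi`.
#' @export
reference_cohort_stats <- function() {
  md <- data.frame(
    feature = feature_names, group = "MD",
    mean = c(156.4, 81.3, 54.7, 63.2, 45.2, 2.1, 4.8, 306.6, 0.1, 42.0, 279.3, 174.4),
    sd   = c(56.4, 38.2, 16.6, 13.4, 16.6, 0.8, 0.7, 67.6, 0.0, 13.5, 80.2, 40.6),
    lo   = c(75.0, 32, 30.1, 50.3, 21.7, 1.2, 3.6, 225, 0.0, 24.5, 143, 108.0),
    hi   = c(234.2, 132.0, 78.2, 90.1, 69.8, 3.8, 5.9, 449, 0.1, 68.6, 377, 219.9))
  ctl <- data.frame(
    feature = feature_names, group = "non-MD",
    mean = c(127.9, 62.1, 52.2, 55.3, 47.7, 2.3, 4.8, 266.8, 0.1, 29.3, 232.9, 138.2),
    sd   = c(64.6, 33.7, 10.8, 16.9, 10.8, 0.5, 0.6, 75.1, 0.0, 8.7, 109.2, 27.7),
    lo   = c(59.2, 27.0, 30.7, 33.5, 35.1, 1.6, 4.3, 133, 0.0, 17.6, 99, 105.9),
    hi   = c(249.7, 124.0, 64.8, 107.2, 69.2, 3.6, 6.3, 401, 0.1, 46.6, 375, 192.3))
  rbind(md, ctl)
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  if (sd <= 0) return(rep(mean, n))
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      v <- stats::rnorm(1, mean, sd)
      if (v >= lo && v <= hi) break
    }
    out[i] <- v
  }
  out
}

#' Generate a synthetic two-group prosodic feature cohort
#'
#' Each feature is drawn independently per subject from a truncated normal
#' with the group's mean/SD and range. Defaults reproduce the marginal
#' statistics of [reference_cohort_stats()]. Feature draws are independent,
#' so cross-feature constraints (e.g. PPU + PPH = 100) hold only in
#' expectation, not per row.
#'
#' @param n_per_group subjects per group (>= 2).
#' @param stats data.frame as returned by [reference_cohort_stats()].
#' @param seed integer RNG seed.
#' @return data.frame with `subject_id`, `label` (`MD` / `non-MD`) and the
#'   twelve feature columns.
#' @export
synth_feature_cohort <- function(n_per_group = 10L,
                                 stats = reference_cohort_stats(),
                                 seed = 1L) {
  if (n_per_group < 2L) stop("n_per_group >= 2", call. = FALSE)
  with_local_seed(seed, {
    groups <- unique(stats$group)
    rows <- lapply(groups, function(g) {
      st <- stats[stats$group == g, , drop = FALSE]
      cols <- lapply(seq_len(nrow(st)), function(i)
        rtruncnorm1(n_per_group, st$mean[i], st$sd[i], st$lo[i], st$hi[i]))
      names(cols) <- st$feature
      cbind(data.frame(subject_id = paste0(g, "_", seq_len(n_per_group)),
                       label = g), as.data.frame(cols))
    })
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  })
}

#' Generate a synthetic two-group audio cohort
#'
#' Produces seeded synthetic recordings for an MD-like group (more and longer
#' pauses, higher and more dispersed per-syllable F0) and a control group,
#' with analytic ground truth per recording. Defaults are sized as a short
#' read passage (30 syllables) so the rate, duration and F0 features fall in
#' the reference cohort's ranges.
#'
#' @param n_per_group recordings per group (>= 2).
#' @param md_overrides,ctl_overrides named lists overriding [utterance_spec()]
#'   fields for each group.
#' @param seed integer seed; per-recording seeds are derived from it.
#' @return list of records, each with `signal`, `label`, `truth`.
#' @export
synth_audio_cohort <- function(n_per_group = 10L,
                               md_overrides = list(),
                               ctl_overrides = list(),
                               seed = 1L) {
  if (n_per_group < 2L) stop("n_per_group >= 2", call. = FALSE)
  base <- list(n_syllables = 30L,
               syllable_duration_s = c(0.07, 0.17),
               gap_s = c(0.06, 0.13),
               f0_glide_st = 2,
               snr_db = 30, sample_rate = 16000L)
  md_def <- utils::modifyList(base, list(
    f0_base_hz = list(mean = 174, sd = 42, min = 85, max = 350),
    n_pauses = 8L, pause_s = c(0.75, 1.25)))
  ctl_def <- utils::modifyList(base, list(
    f0_base_hz = list(mean = 138, sd = 29, min = 85, max = 350),
    n_pauses = 6L, pause_s = c(0.6, 1.1)))
  md_def <- utils::modifyList(md_def, md_overrides)
  ctl_def <- utils::modifyList(ctl_def, ctl_overrides)
  make_group <- function(def, label, seed0) {
    lapply(seq_len(n_per_group), function(i) {
      si <- (seed0 + 131L * i) %% .Machine$integer.max
      n_pauses <- def$n_pauses %||% 0L
      def2 <- def[setdiff(names(def), "n_pauses")]
      pp <- with_local_seed(si + 1L,
        sort(sample(seq_len(def2$n_syllables - 1L), min(n_pauses, def2$n_syllables - 1L))))
      spec <- do.call(utterance_spec,
                      c(def2, list(pause_positions = pp, seed = si)))
      u <- synth_utterance(spec)
      list(signal = u$signal, label = label, truth = u$truth)
    })
  }
  c(make_group(md_def, "MD", seed), make_group(ctl_def, "non-MD", seed + 500000L))
}
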