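#' Canonical order of the twelve prosodic features
#'
#' Timing features: SPT (speech time, s), NPU (number of pauses), PPU
#' (pause-time proportion, % of SPT), PHT (phonation time, s), PPH
#' (phonation-time proportion, %), SPR (speech rate, syllables/s including
#' pauses), ARR (articulation rate, syllables/s excluding pauses), NSY
#' (number of syllables), MSD (mean nucleus duration, s). F0 features: SDF
#' (SD of per-nucleus F0), MVF (max minus min F0 over voiced frames inside
#' nuclei), MFF (mean of per-nucleus F0); F0 features in Hz by default, or in
#' semitones re a reference.
#'
#' @export
feature_names <- c("SPT", "NPU", "PPU", "PHT", "PPH", "SPR",
                   "ARR", "NSY", "MSD", "SDF", "MVF", "MFF")

#' Detect silent pauses between consecutive syllable nuclei
#'
#' A gap between nucleus `i`'s offset and nucleus `i+1`'s onset counts as a
#' pause iff it is strictly longer than `threshold_s` (default 0.3 s).
#'
#' @param nuclei a sorted `syllable_nuclei` data.frame with >= 1 row.
#' @param threshold_s pause threshold in seconds.
#' @return A `pause_set`: list with `gaps` (data.frame `start`, `end`,
#'   `length_s` of the pauses only), `pause_threshold_s`, `total_pause_s`.
#' @export
detect_pauses <- function(nuclei, threshold_s = 0.3) {
  if (is.null(nrow(nuclei)) || nrow(nuclei) < 1L)
    stop("degenerate input: no nuclei", call. = FALSE)
  if (nrow(nuclei) >= 2L) {
    gs <- nuclei$offset[-nrow(nuclei)]
    ge <- nuclei$onset[-1L]
    len <- ge - gs
    keep <- len > threshold_s               # strictly over the threshold
    gaps <- data.frame(start = gs[keep], end = ge[keep], length_s = len[keep])
  } else {
    gaps <- data.frame(start = numeric(0), end = numeric(0), length_s = numeric(0))
  }
  structure(list(gaps = gaps, pause_threshold_s = threshold_s,
                 total_pause_s = sum(gaps$length_s)),
            class = "pause_set")
}

#' Compute the twelve prosodic features for one recording
#'
#' All timing is derived from the nucleus timeline: `SPT` spans first onset to
#' last offset, `PHT = SPT - total pause time`, proportions are percentages of
#' `SPT`, and rates are nucleus counts per second of `SPT` (SPR) or `PHT`
#' (ARR). Per-nucleus F0 means feed `MFF` (their mean) and `SDF` (their
#' sample SD); `MVF` is the range (max minus min) over all voiced-frame F0
#' samples inside nuclei.
#'
#' @param nuclei annotated `syllable_nuclei` (see [annotate_f0()]); at least
#'   one row.
#' @param pauses a `pause_set` from [detect_pauses()]; computed from `nuclei`
#'   if `NULL`.
#' @param f0_unit `"hz"` (default) or `"st"` (semitones re `f_ref`).
#' @param f_ref semitone reference frequency in Hz.
#' @return A `prosodic_features` object: named list with the twelve features,
#'   `f0_unit`, and `f0_defined` (FALSE when every nucleus was unvoiced, in
#'   which case the F0 features are `NA`).
#' @export
compute_features <- function(nuclei, pauses = NULL, f0_unit = c("hz", "st"),
                             f_ref = 100) {
  f0_unit <- match.arg(f0_unit)
  if (is.null(nrow(nuclei)) || nrow(nuclei) < 1L)
    stop("degenerate input: no nuclei", call. = FALSE)
  if (is.null(pauses)) pauses <- detect_pauses(nuclei)
  spt <- nuclei$offset[nrow(nuclei)] - nuclei$onset[1L]
  if (spt <= 0) stop("degenerate input: zero speech time", call. = FALSE)
  pht <- spt - pauses$total_pause_s
  if (pht <= 0) stop("degenerate input: zero phonation time", call. = FALSE)
  nsy <- nrow(nuclei)

  f0_means <- nuclei$mean_f0_hz
  f0_all <- if (!is.null(nuclei$f0)) unlist(nuclei$f0) else f0_means
  f0_means <- f0_means[is.finite(f0_means)]
  f0_all <- f0_all[is.finite(f0_all)]
  f0_defined <- length(f0_means) > 0L
  if (f0_defined && f0_unit == "st") {
    f0_means <- hz_to_semitones(f0_means, f_ref)
    f0_all <- hz_to_semitones(f0_all, f_ref)
  }

  out <- list(
    SPT = spt,
    NPU = nrow(pauses$gaps),
    PPU = 100 * pauses$total_pause_s / spt,
    PHT = pht,
    PPH = 100 * pht / spt,
    SPR = nsy / spt,
    ARR = nsy / pht,
    NSY = nsy,
    MSD = mean(nuclei$duration),
    SDF = if (!f0_defined) NA_real_ else if (length(f0_means) > 1L) stats::sd(f0_means) else 0,
    MVF = if (!f0_defined) NA_real_ else max(f0_all) - min(f0_all),
    MFF = if (!f0_defined) NA_real_ else mean(f0_means),
    f0_unit = f0_unit,
    f0_defined = f0_defined)
  class(out) <- "prosodic_features"
  out
}

#' @export
print.prosodic_features <- function(x, ...) {
  cat("<prosodic_features> (F0 unit:", x$f0_unit, ")\n")
  v <- unlist(x[feature_names])
  print(round(v, 3))
  invisible(x)
}

#' @export
as.data.frame.prosodic_features <- function(x, ...) {
  as.data.frame(x[feature_names], ...)
}

#' Extract the twelve prosodic features from a waveform
#'
#' Full single-recording pipeline: nucleus detection ([detect_syllables()]),
#' pause detection and feature computation.
#'
#' @param signal an [audio_signal].
#' @param config pipeline configuration, see [default_config()].
#' @return A `prosodic_features` object with the detected nuclei attached as
#'   attribute `"nuclei"`.
#' @export
extract_features <- function(signal, config = default_config()) {
  nuc <- detect_syllables(signal, config)
  if (nrow(nuc) < 1L)
    stop("degenerate input: no syllable nuclei detected", call. = FALSE)
  pauses <- detect_pauses(nuc, config$features$pause_threshold_s)
  fv <- compute_features(nuc, pauses, config$features$f0_unit,
                         config$pitch$f_ref)
  attr(fv, "nuclei") <- nuc
  fv
}
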