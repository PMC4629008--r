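---
title: "Transcript-free prosodic analysis: models, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transcript-free prosodic analysis: models, parameters, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prosodyscreen)
```

## The problem

Language production degrades early in dementia, and prosody — the timing and
melody of speech — carries measurable traces of that degradation. Most
computational approaches to scoring it require a manual transcript, which
defeats the purpose of a low-burden screening instrument. `prosodyscreen`
implements a fully automatic alternative: syllable nuclei (the vowel-centered
high-energy cores of syllables) are detected directly from the waveform, and
every prosodic measure is derived from the nucleus timeline and a fundamental
frequency (F0) track. The intended input is a read-speech recording of an
elderly subject (a standard reading passage), and the intended output is a
twelve-dimensional prosodic feature vector per recording, plus cohort-level
tools for ranking those features between a mild-dementia (MD) group and
healthy controls and for evaluating classifiers over feature subsets.

## Nucleus detection model

The detector works on the band-limited RMS energy envelope of the signal:

1. **Band-pass** to the vowel-energy band, 300–2500 Hz by default. Vowels
   concentrate harmonic energy here; most frication and low-frequency rumble
   fall outside. Implemented as cascaded zero-phase Butterworth high-pass
   (order 2) and low-pass (order 4) filters: a single narrow-band 8-pole
   band-pass is numerically fragile at 44.1 kHz, the cascade is not.
2. **RMS envelope** at full signal rate (no downsampling) with a Hann-tapered
   10 ms window hopped every 5 ms, then a 3-frame moving average. The short
   window keeps boundary resolution at the 5 ms scale; the taper and smoother
   suppress the within-vowel ripple the RMS shows when the window spans only
   ~1–2 glottal periods.
3. **Peak picking** with a purely relative threshold: candidates are local
   maxima above `floor + rel_threshold * (max - floor)` where `floor` is the
   5th envelope percentile (a robust noise-floor estimate) and
   `rel_threshold = 0.3` by default. Candidate pairs whose intervening dip
   does not drop at least the same margin below the smaller peak are merged,
   as are peaks closer than `min_gap_s = 0.06` s (faster than any plausible
   syllable rate). Because every quantity is relative, detection is exactly
   invariant to amplitude scaling, and raising the threshold can only remove
   peaks.
4. **Boundaries**: each nucleus extends to the envelope minimum between its
   peak and the neighboring peak (the argmin on that side; ties resolved
   toward the peak), or to the envelope edge for the outermost peaks, and is
   then clipped by the vocal-activity limits of the voiced region covering
   the peak. We deliberately use the *argmin between peaks* rather than the
   literal nearest local minimum: with a 10 ms RMS window the envelope
   ripples at the F0 rate, and the nearest ripple dip would produce
   arbitrarily small nuclei and corrupt pause measurement. The argmin rule
   makes adjacent nuclei split at their shared minimum and leaves the
   voicing limits — which are ripple-free — to set the outer edges.

## Pitch tracking

F0 is tracked with a normalized cross-correlation (NCCF) front end and
dynamic-programming smoothing. Per 5 ms frame, NCCF is computed over lags
covering 60–400 Hz (a range covering elderly male and female voices), local
NCCF maxima above the voicing threshold 0.3 become voiced candidates
(parabolically interpolated in lag), and a Viterbi pass selects one candidate
or "unvoiced" per frame with three cost terms: `1 - NCCF` plus a small
short-lag preference (0.05, scaled by lag) as the local cost, an octave cost
of `0.35 * |log2(f2/f1)|` between consecutive voiced frames, and a
voiced/unvoiced transition cost of 0.2. Frames whose best NCCF falls below
the threshold are unconditionally unvoiced; unvoiced frames carry no F0 value
at all, so they can never contaminate F0 statistics. The correlation is
normalized, so tracking is exactly amplitude invariant.

These are standard operating points for NCCF trackers rather than fitted
values; all are exposed in the configuration. On synthetic harmonic glides
the tracker stays well inside 1 semitone of the generating contour, and on
white noise the voiced fraction stays under 20%.

## The twelve features

All timing comes from the nucleus timeline. With nuclei
`[onset_i, offset_i]`, `i = 1..NSY`:

* `SPT = offset_NSY - onset_1` (speech time; leading/trailing silence excluded),
* a gap between consecutive nuclei is a **pause** iff strictly longer than
  0.3 s (`detect_pauses`),
* `NPU` = pause count, `PHT = SPT - total pause time` (phonation time),
* `PPU = 100 * pause_time / SPT`, `PPH = 100 * PHT / SPT` — proportions of
  time, so `PPU + PPH = 100` identically,
* `SPR = NSY / SPT`, `ARR = NSY / PHT` (speech vs articulation rate;
  `ARR >= SPR` always), `MSD` = mean nucleus duration.

F0 features use the per-nucleus voiced-frame F0 samples: `MFF` is the mean of
per-nucleus means, `SDF` their sample standard deviation, and `MVF` the range
(max minus min) over all voiced-frame samples inside nuclei. The published
descriptive statistics this package emulates are only plausible in Hz, so Hz
is the default F0 unit; a semitone mode (`12 * log2(f / f_ref)`, reference
100 Hz by default) is provided because semitones suppress gender differences.
`PPU`'s printed verbal definition in the source literature (a count divided
by a time) contradicts its tabulated values, which sum with `PPH` to 100; we
follow the arithmetic and define both as time proportions.

## Cohort statistics

Feature ranking uses the two-sample Kolmogorov–Smirnov test:
`D = sup_t |F1(t) - F2(t)|` over the pooled points. The null p-value is
computed **exactly** for small samples by lattice-path counting — the number
of monotone paths from `(0,0)` to `(n,m)` keeping `|i/n - j/m| < D`, over all
`C(n+m, n)` equally likely orderings — and by the classical asymptotic series
`2 * sum (-1)^(k-1) exp(-2 k^2 lambda^2)` otherwise; `auto` switches at
`n + m = 30`. At the 10-vs-10 study size the exact test is the defensible
choice and is the default; it is validated in the test suite against full
enumeration of assignments for all `n, m <= 6` and against `stats::ks.test`.
Features are ranked by ascending p and partitioned into tiers: significant
(`p < 0.05`), possibly significant (`0.05 <= p < 0.5`), nonsignificant
(`p >= 0.5`); a boundary p of exactly 0.5 is nonsignificant. No
multiple-testing adjustment is applied, deliberately mirroring the screening
workflow this reimplements.

## Classification

Group membership (MD vs non-MD) is evaluated with a support vector machine
under leave-one-out cross-validation: `n` folds, each training on `n - 1`
subjects with features z-scored by training-fold statistics only, so no
information from the held-out subject leaks into standardization. Defaults
are the smallest-assumption choices: linear kernel, `C = 1` (an RBF kernel is
available in the configuration). Two additions matter:

* **Balanced class weights.** A leave-one-out training fold is structurally
  imbalanced — the held-out subject's class is one short — which biases a
  margin classifier against that class and drags chance-level accuracy below
  50%. Each class is therefore weighted by `n / (2 * n_class)` within the
  fold. With this, pure-noise data scores indistinguishably from 50% and
  separable data still scores 100%.
* **Metric conventions.** `Accu = 100 (TP+TN)/n` always. The `standard`
  convention reports sensitivity `TP/(TP+FN)` and specificity `TN/(TN+FP)`;
  the `predictive_value` convention reports PPV `TP/(TP+FP)` and NPV
  `TN/(TN+FN)` in the same slots. Both are computed for every evaluation
  because published screening tables are frequently consistent only with the
  predictive-value reading; on a 10-vs-10 cohort the triple
  (85.0, 81.8, 88.9) arises from exactly one confusion matrix
  (TP=9, FN=1, FP=2, TN=8), whose standard-convention metrics are
  (85.0, 90.0, 80.0).

The exhaustive subset search evaluates all `2^K - 1` non-empty feature
subsets (4095 for the twelve features) and reports the best accuracy per
subset size, ties broken toward the lexicographically first subset in
canonical feature order. Best-per-size accuracy is intentionally *not*
monotonized: adding features can and does hurt, and the report must show it.

## Synthetic data: what it emulates and what it does not

Two generators make the pipeline testable without clinical recordings.

`synth_utterance` builds a syllable train: per-syllable durations, gaps,
pauses, base F0 and amplitude are drawn from configurable ranges; each
syllable is a harmonic source (1/h spectral tilt, harmonics to ~5 kHz)
following its F0 contour under a Hann amplitude envelope; white noise is
added at a configured SNR (30 dB by default). Ground truth — nucleus
timeline, per-syllable F0, and all twelve features — is computed analytically
from the drawn timeline, never from the detector, so detector recovery is a
genuine end-to-end check. Defaults: 0.10–0.25 s syllables, 0.05–0.15 s gaps,
0.4–1.0 s pauses, 110–180 Hz base F0, 16 kHz sampling.

`synth_feature_cohort` draws feature *tables* directly: each feature
independently from a truncated normal with the group's published mean/SD and
range. Independence is a documented simplification (no covariances are
published); consequently cross-feature identities such as `PPU + PPH = 100`
hold only in expectation in these tables.

`synth_audio_cohort` generates audio for an MD-like group (more and longer
pauses: 8 pauses of 0.75–1.25 s; per-syllable F0 ~ N(174, 42) Hz) and a
control group (6 pauses of 0.6–1.1 s; F0 ~ N(138, 29) Hz), 30 syllables of
0.07–0.17 s per recording with a 2-semitone within-syllable glide. These
choices reproduce the published groups' pause proportions (~52–55%),
articulation rate (~4.8 syll/s) and F0 statistics at a scaled-down passage
length: 30 syllables rather than the ~300 of a full reading passage, keeping
a 20-recording cohort tractable on one CPU. Count and total features (NSY,
SPT, NPU, PHT) and the range statistic MVF scale with passage length and
therefore sit below the published absolute ranges; the length-invariant
features (PPU, PPH, SPR, ARR, SDF, MFF) fall inside them, and that is what
the validation asserts.

None of the generators model consonants, coarticulation, formant structure,
clinician crosstalk, or room acoustics. Passing tests therefore demonstrate
correctness of the *pipeline* under its stated acoustic assumptions
(energy-cohesive vowel nuclei, quasi-periodic voicing, stationary noise), not
field performance on clinical recordings.

## Numerical choices and degenerate inputs

* Frame and hop lengths are `floor(seconds * rate)` samples — at 44.1 kHz a
  5 ms hop is exactly 220 samples — making frame counts exactly
  `floor((N - L)/H) + 1`.
* Stereo recordings default to the left channel (the patient microphone in a
  two-headset setup); `right` and `mix` are available.
* The pause rule is strict (`> 0.3 s`): a gap of exactly 0.3 s is speech.
* Exact-KS lattice counting uses a `1e-7` slack on the strict boundary
  `|i/n - j/m| < D` to absorb float error; achievable D values are spaced at
  least `1/(nm)` apart, so the slack cannot flip a path.
* Silence is handled without error end to end: an all-zero signal yields an
  all-zero envelope, an all-unvoiced track, and a flagged no-nucleus row in
  `cmd_extract` output.
* Ties in peak merging keep the earlier (larger-valued) peak; ties in
  boundary argmins resolve toward the peak, giving the smaller nucleus.
* A LOOCV fold in which every selected feature is constant across the
  training subjects carries no information; it predicts the training-fold
  majority class rather than fitting a degenerate SVM (whose tie-break would
  otherwise systematically — and spuriously — favor the held-out class).
  Under leave-one-out with balanced groups this conventionally scores 0%,
  so uninformative subsets can never win the subset search.

## Problem sizes used in validation

The shipped validation runs at sizes chosen to exercise every claim while
staying desk-scale: 500 random timelines for the feature algebra; 100
utterances of 5–40 syllables at 30 dB SNR for detector recovery; full
enumeration for all `n, m <= 6` plus 2000 null replicates for the exact KS
test; 200 null replicates of n = 40 for classifier calibration; the full
4095-subset search on a 10-vs-10 cohort; and 20 replicates of the 10+10
end-to-end audio cohort.

## Known limitations

* The nucleus detector is validated against synthetic ground truth only; on
  real speech, nasals and liquids adjacent to vowels can merge into one
  nucleus, and breathy terminations can shorten voicing limits.
* The NCCF tracker omits per-sample lag refinement and the two-pass
  downsampled search of full RAPT; creak and diplophonia are not modeled.
* Independence of features in `synth_feature_cohort` understates the
  collinearity a real cohort would show; subset-search results on such
  tables measure the machinery, not clinical effect sizes.
* With 10 subjects per group, LOOCV accuracy has a granularity of 5
  percentage points; differences smaller than that are noise.
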