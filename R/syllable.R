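#' Compute the band-limited RMS energy envelope
#'
#' The signal is band-pass filtered to the vowel-energy band (cascaded
#' Butterworth high-pass and low-pass, zero-phase via `filtfilt`), then the
#' per-frame RMS is computed at the full signal rate (no downsampling) with a
#' Hann-tapered temporal weighting window, and finally smoothed with a short
#' moving average. Default resolution is a 10 ms window with a 5 ms hop.
#'
#' @param signal an [audio_signal].
#' @param window_s,hop_s analysis window and hop in seconds.
#' @param band numeric `c(low, high)` pass band in Hz.
#' @param smooth_frames length of the moving-average smoother (frames).
#' @return An `envelope`: list with `frame_times`, `values` (>= 0), `window_s`,
#'   `hop_s`.
#' @export
compute_envelope <- function(signal, window_s = 0.010, hop_s = 0.005,
                             band = c(300, 2500), smooth_frames = 3L) {
  stopifnot(inherits(signal, "audio_signal"))
  fs <- signal$sample_rate
  if (!(band[1] > 0 && band[1] < band[2] && band[2] < fs / 2))
    stop("band must lie within (0, sample_rate/2)", call. = FALSE)
  x <- signal$samples
  if (any(x != 0)) {
    hp <- signal::butter(2, band[1] / (fs / 2), type = "high")
    lp <- signal::butter(4, band[2] / (fs / 2), type = "low")
    x <- signal::filtfilt(lp, signal::filtfilt(hp, x))
  }
  fr <- frame_signal(audio_signal0(x, fs), window_s, hop_s)
  w <- hann_window(fr$frame_length)
  vals <- sqrt(colSums(fr$frames^2 * w) / sum(w))
  if (smooth_frames > 1L && length(vals) >= smooth_frames) {
    vals <- stats::filter(vals, rep(1 / smooth_frames, smooth_frames), sides = 2)
    vals <- as.numeric(vals)
    # fill the NA ends left by the centered filter with the nearest value
    na <- is.na(vals)
    if (any(na)) {
      idx <- which(!na)
      vals[na] <- vals[idx[pmin(pmax(findInterval(which(na), idx), 1L), length(idx))]]
      vals[seq_len(idx[1] - 1)] <- vals[idx[1]]
    }
  }
  structure(
    list(frame_times = fr$frame_times, values = pmax(vals, 0),
         window_s = window_s, hop_s = hop_s),
    class = "envelope")
}

## audio_signal constructor bypassing the [-1,1] re-normalization (internal,
## used for filtered intermediates whose scale must be preserved).
audio_signal0 <- function(samples, sample_rate) {
  structure(list(samples = samples, sample_rate = sample_rate,
                 duration = length(samples) / sample_rate),
            class = "audio_signal")
}

hann_window <- function(L) {
  if (L == 1L) return(1)
  0.5 - 0.5 * cos(2 * pi * (seq_len(L) - 1) / (L - 1))
}

#' Detect syllable-nucleus peaks on an energy envelope
#'
#' Candidate peaks are local envelope maxima above
#' `floor + rel_threshold * (max - floor)`, where `floor` is the envelope's
#' 5th percentile. Consecutive candidates whose intervening dip does not fall
#' at least the same threshold margin below the smaller of the two are merged
#' (keeping the larger), as are candidates closer than `min_gap_s`. The
#' thresholding is relative, so detection is invariant to amplitude scaling.
#'
#' @param env an `envelope`.
#' @param rel_threshold relative height threshold in (0, 1).
#' @param min_gap_s minimum peak separation in seconds.
#' @return Numeric vector of peak times (seconds), sorted.
#' @export
detect_peaks <- function(env, rel_threshold = 0.3, min_gap_s = 0.06) {
  stopifnot(inherits(env, "envelope"))
  v <- env$values
  if (!length(v)) stop("empty envelope", call. = FALSE)
  if (!(rel_threshold > 0 && rel_threshold < 1) || min_gap_s <= 0)
    stop("require 0 < rel_threshold < 1 and min_gap_s > 0", call. = FALSE)
  lo <- stats::quantile(v, 0.05, names = FALSE)
  hi <- max(v)
  if (hi - lo <= 0) return(numeric(0))             # constant envelope
  margin <- rel_threshold * (hi - lo)
  thr <- lo + margin
  cand <- local_maxima(v)
  cand <- cand[v[cand] > thr]
  if (!length(cand)) return(numeric(0))

  merge_pass <- function(cand, ok_fun) {
    repeat {
      if (length(cand) < 2L) return(cand)
      drop <- integer(0)
      for (i in seq_len(length(cand) - 1L)) {
        if (!ok_fun(cand[i], cand[i + 1L])) {
          drop <- c(drop, if (v[cand[i]] >= v[cand[i + 1L]]) i + 1L else i)
        }
      }
      if (!length(drop)) return(cand)
      cand <- cand[-unique(drop)]
    }
  }
  # dip (prominence) merge: the valley between two kept peaks must drop at
  # least `margin` below the smaller peak
  cand <- merge_pass(cand, function(a, b) {
    min(v[a:b]) <= min(v[a], v[b]) - margin
  })
  # minimum temporal separation
  cand <- merge_pass(cand, function(a, b) {
    env$frame_times[b] - env$frame_times[a] >= min_gap_s
  })
  env$frame_times[cand]
}

#' Estimate syllable-nucleus boundaries from envelope minima and voicing
#'
#' For each detected peak the raw boundaries are the envelope minima between
#' it and its neighboring peaks (the argmin of the envelope on either side;
#' ties broken toward the peak), or the envelope edges for the outermost
#' peaks. Boundaries are then clipped by the vocal-activity limits of the
#' voiced region covering the peak, so a nucleus never extends into unvoiced
#' territory. Adjacent nuclei therefore split at their shared minimum.
#'
#' @param peaks peak times from [detect_peaks()] (sorted).
#' @param env the `envelope` the peaks came from.
#' @param regions voiced regions from [voiced_regions()] (may be empty).
#' @return A `syllable_nuclei` data.frame with columns `onset`, `peak_time`,
#'   `offset`, `duration`, `peak_value`.
#' @export
estimate_boundaries <- function(peaks, env, regions = NULL) {
  stopifnot(inherits(env, "envelope"))
  tt <- env$frame_times; v <- env$values
  if (length(peaks) == 0L)
    return(structure(data.frame(onset = numeric(0), peak_time = numeric(0),
                                offset = numeric(0), duration = numeric(0),
                                peak_value = numeric(0)),
                     class = c("syllable_nuclei", "data.frame")))
  if (any(peaks < tt[1] - 1e-9) || any(peaks > tt[length(tt)] + 1e-9))
    stop("consistency error: peak outside envelope span", call. = FALSE)
  pi_ <- vapply(peaks, function(p) which.min(abs(tt - p)), 1L)
  n <- length(pi_)
  onset <- offset <- numeric(n)
  argmin_near_peak <- function(lo, hi, toward_hi) {
    # argmin of v on lo:hi; ties broken toward the peak side
    seg <- v[lo:hi]
    cand <- which(seg == min(seg))
    lo - 1L + if (toward_hi) max(cand) else min(cand)
  }
  for (i in seq_len(n)) {
    lo <- if (i == 1L) 1L else pi_[i - 1L]
    hi <- if (i == n) length(v) else pi_[i + 1L]
    li <- argmin_near_peak(lo, pi_[i], toward_hi = TRUE)
    ri <- argmin_near_peak(pi_[i], hi, toward_hi = FALSE)
    onset[i] <- tt[li]
    offset[i] <- tt[ri]
  }
  onset[1] <- max(onset[1], 0)
  # clip by vocal activity limits
  if (!is.null(regions) && nrow(regions)) {
    for (i in seq_len(n)) {
      p <- peaks[i]
      inside <- which(regions$start <= p & regions$end >= p)
      if (length(inside)) {
        r <- inside[1]
      } else {
        d <- pmax(regions$start - p, p - regions$end)
        r <- which.min(d)
        if (regions$start[r] > offset[i] || regions$end[r] < onset[i]) next
      }
      onset[i] <- max(onset[i], regions$start[r])
      offset[i] <- min(offset[i], regions$end[r])
    }
  }
  keep <- offset - onset > 1e-9 & onset <= peaks + 1e-9 & offset >= peaks - 1e-9
  # a peak clipped outside its own nucleus would be inconsistent; keep the
  # nucleus only when the peak lies inside it
  out <- data.frame(onset = onset, peak_time = peaks, offset = offset,
                    duration = offset - onset,
                    peak_value = v[pi_])[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("syllable_nuclei", "data.frame"))
}

#' Attach per-nucleus F0 statistics from a pitch track
#'
#' Each nucleus gains the voiced-frame F0 samples falling inside
#' `[onset, offset)` and their arithmetic mean. Nuclei with no voiced frame
#' get `NA` mean and `unvoiced = TRUE`.
#'
#' @param nuclei a `syllable_nuclei` data.frame.
#' @param track a `pitch_track` covering the nuclei.
#' @return `nuclei` with added columns `mean_f0_hz`, `unvoiced`, and a list
#'   column `f0` of per-nucleus voiced-frame F0 samples.
#' @export
annotate_f0 <- function(nuclei, track) {
  stopifnot(inherits(track, "pitch_track"))
  n <- nrow(nuclei)
  f0s <- vector("list", n)
  m <- rep(NA_real_, n)
  tt <- track$frame_times
  for (i in seq_len(n)) {
    sel <- track$voiced & tt >= nuclei$onset[i] - 1e-9 & tt < nuclei$offset[i] - 1e-9
    f <- track$f0_hz[sel]
    f <- f[is.finite(f)]
    f0s[[i]] <- f
    if (length(f)) m[i] <- mean(f)
  }
  nuclei$mean_f0_hz <- m
  nuclei$unvoiced <- vapply(f0s, length, 1L) == 0L
  nuclei$f0 <- I(f0s)
  nuclei
}

#' Detect annotated syllable nuclei in one pass
#'
#' Convenience wrapper chaining [compute_envelope()], [detect_peaks()],
#' [track_pitch()], [voiced_regions()], [estimate_boundaries()] and
#' [annotate_f0()] with a pipeline configuration (see [default_config()]).
#'
#' @param signal an [audio_signal].
#' @param config pipeline configuration list.
#' @return Annotated `syllable_nuclei` data.frame; the pitch track is attached
#'   as attribute `"pitch_track"`.
#' @export
detect_syllables <- function(signal, config = default_config()) {
  e <- config$envelope
  p <- config$pitch
  env <- compute_envelope(signal, e$window_s, e$hop_s, c(e$band_low, e$band_high))
  peaks <- detect_peaks(env, e$rel_threshold, e$min_gap_s)
  track <- track_pitch(signal, p$f_min, p$f_max, e$hop_s, p$voicing_threshold)
  regions <- voiced_regions(track, p$min_voiced_s)
  nuc <- estimate_boundaries(peaks, env, regions)
  nuc <- annotate_f0(nuc, track)
  attr(nuc, "pitch_track") <- track
  nuc
}

#' Export nuclei as a Praat TextGrid interval tier
#'
#' Writes a one-tier TextGrid (`"nucleus"`) where each nucleus interval is
#' labeled `"syl"` and gaps are empty.
#'
#' @param nuclei a `syllable_nuclei` data.frame.
#' @param duration total recording duration in seconds.
#' @param path output path.
#' @export
write_textgrid <- function(nuclei, duration, path) {
  b <- c(0, as.vector(rbind(nuclei$onset, nuclei$offset)), duration)
  b <- b[!duplicated(round(b, 9))]
  b <- b[b <= duration + 1e-9]
  labs <- character(length(b) - 1L)
  for (i in seq_len(nrow(nuclei)))
    labs[which.min(abs(b - nuclei$onset[i]))] <- "syl"
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w('File type = "ooTextFile"')
  w('Object class = "TextGrid"')
  w('')
  w('xmin = 0')
  w('xmax = %.6f', duration)
  w('tiers? <exists>')
  w('size = 1')
  w('item []:')
  w('    item [1]:')
  w('        class = "IntervalTier"')
  w('        name = "nucleus"')
  w('        xmin = 0')
  w('        xmax = %.6f', duration)
  w('        intervals: size = %d', length(labs))
  for (i in seq_along(labs)) {
    w('        intervals [%d]:', i)
    w('            xmin = %.6f', b[i])
    w('            xmax = %.6f', b[i + 1L])
    w('            text = "%s"', labs[i])
  }
  invisible(path)
}

#' Write nuclei as delimited text
#'
#' @param nuclei annotated `syllable_nuclei`.
#' @param path output path.
#' @export
write_nuclei_table <- function(nuclei, path) {
  df <- data.frame(onset_s = nuclei$onset, peak_s = nuclei$peak_time,
                   offset_s = nuclei$offset,
                   mean_f0_hz = if (is.null(nuclei$mean_f0_hz)) NA else nuclei$mean_f0_hz)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
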