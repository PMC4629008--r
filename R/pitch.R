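#' Convert frequency to semitones relative to a reference
#'
#' @param f frequency in Hz (> 0); vectorized.
#' @param f_ref reference frequency in Hz (> 0), default 100.
#' @return `12 * log2(f / f_ref)` semitones.
#' @export
hz_to_semitones <- function(f, f_ref = 100) {
  if (any(!is.na(f) & f <= 0) || f_ref <= 0)
    stop("domain error: frequencies must be positive", call. = FALSE)
  12 * log2(f / f_ref)
}

## NCCF over a block of frames. x: full signal; starts: frame start indices
## (1-based); n: correlation window; kmax: max lag. Returns (kmax+1) x nframes
## matrix of normalized cross-correlation values for lags 0..kmax.
nccf_block <- function(x, starts, n, kmax) {
  seg_len <- n + kmax
  nf <- length(starts)
  idx <- outer(seq_len(seg_len) - 1L, starts, "+")
  S <- matrix(x[idx], nrow = seg_len)
  M <- 2^ceiling(log2(seg_len + kmax + 1L))
  A <- matrix(0, M, nf); A[seq_len(n), ] <- S[seq_len(n), ]
  B <- matrix(0, M, nf); B[seq_len(seg_len), ] <- S
  Cc <- Re(stats::mvfft(Conj(stats::mvfft(A)) * stats::mvfft(B), inverse = TRUE)) / M
  Cc <- Cc[seq_len(kmax + 1L), , drop = FALSE]          # lag k in row k+1
  e0 <- colSums(S[seq_len(n), , drop = FALSE]^2)
  cs <- apply(S^2, 2L, cumsum)
  cs <- rbind(0, cs)
  ek <- cs[(0:kmax) + n + 1L, , drop = FALSE] - cs[(0:kmax) + 1L, , drop = FALSE]
  den <- sqrt(outer(rep(1, kmax + 1L), e0) * ek)
  out <- Cc / (den + 1e-30)
  out[den <= 0] <- 0
  out
}

## Local maxima (strict left, >= right) of a vector; returns indices.
local_maxima <- function(v) {
  n <- length(v)
  if (n < 3L) return(integer(0))
  i <- 2:(n - 1L)
  i[v[i] > v[i - 1L] & v[i] >= v[i + 1L]]
}

#' Track fundamental frequency with an NCCF + dynamic-programming tracker
#'
#' Per-frame candidate F0 values are the local maxima of the normalized
#' cross-correlation function (NCCF) between `1/f_max` and `1/f_min` lags,
#' refined by parabolic interpolation. A Viterbi pass selects one candidate
#' (or "unvoiced") per frame, penalizing octave jumps and voicing
#' transitions. Frames whose best NCCF falls below `voicing_threshold` are
#' always unvoiced.
#'
#' @param signal an [audio_signal].
#' @param f_min,f_max F0 search range in Hz; `20 <= f_min < f_max <= rate/4`.
#' @param hop_s analysis hop in seconds (default 5 ms, matching the envelope).
#' @param voicing_threshold minimum NCCF for a frame to be voiceable.
#' @param octave_cost weight on `|log2(f2/f1)|` between consecutive voiced frames.
#' @param voicing_transition_cost cost of switching voiced/unvoiced.
#' @param lag_weight small preference for shorter lags (suppresses period
#'   multiples), scaled by `lag / lag_max`.
#' @param max_candidates candidates retained per frame.
#' @return A `pitch_track`: list with `frame_times` (s), `f0_hz` (NA where
#'   unvoiced), `voiced` (logical), `nccf` (best candidate score), `hop_s`.
#' @export
track_pitch <- function(signal, f_min = 60, f_max = 400, hop_s = 0.005,
                        voicing_threshold = 0.3, octave_cost = 0.35,
                        voicing_transition_cost = 0.2, lag_weight = 0.05,
                        max_candidates = 5L) {
  stopifnot(inherits(signal, "audio_signal"))
  fs <- signal$sample_rate
  if (!(f_min >= 20 && f_min < f_max && f_max <= fs / 4))
    stop("require 20 <= f_min < f_max <= sample_rate/4", call. = FALSE)
  x <- signal$samples
  kmin <- max(2L, floor(fs / f_max))
  kmax <- ceiling(fs / f_min)
  n <- kmax                                        # correlation window = max period
  seg_len <- n + kmax
  H <- floor(hop_s * fs)
  N <- length(x)
  if (seg_len > N) stop("degenerate input: signal shorter than one analysis window", call. = FALSE)
  nf <- (N - seg_len) %/% H + 1L
  starts <- (seq_len(nf) - 1L) * H + 1L
  frame_times <- (starts - 1 + n / 2) / fs

  cand_f0 <- vector("list", nf)
  cand_v  <- vector("list", nf)
  chunk <- 400L
  for (lo in seq(1L, nf, by = chunk)) {
    hi <- min(lo + chunk - 1L, nf)
    R <- nccf_block(x, starts[lo:hi], n, kmax)
    for (j in lo:hi) {
      r <- R[, j - lo + 1L]
      pk <- local_maxima(r)
      pk <- pk[pk - 1L >= kmin & pk - 1L <= kmax]  # row k+1 = lag k
      pk <- pk[r[pk] >= voicing_threshold]
      if (length(pk)) {
        if (length(pk) > max_candidates)
          pk <- pk[order(r[pk], decreasing = TRUE)[seq_len(max_candidates)]]
        # parabolic lag refinement
        k0 <- pk - 1L
        y1 <- r[pk - 1L]; y2 <- r[pk]; y3 <- r[pk + 1L]
        denom <- (y1 - 2 * y2 + y3)
        d <- ifelse(abs(denom) > 1e-12, 0.5 * (y1 - y3) / denom, 0)
        d <- pmax(pmin(d, 0.5), -0.5)
        lag <- k0 + d
        f0 <- fs / lag
        keep <- f0 >= f_min & f0 <= f_max
        cand_f0[[j]] <- f0[keep]
        cand_v[[j]]  <- pmin(y2[keep] + 0.25 * abs(y1 - y3)[keep] * abs(d[keep]), 1)
      } else {
        cand_f0[[j]] <- numeric(0)
        cand_v[[j]]  <- numeric(0)
      }
    }
  }

  ## Viterbi over candidates + an unvoiced state per frame.
  unvoiced_cost <- 1 - voicing_threshold
  f0_out <- rep(NA_real_, nf)
  v_out <- logical(nf)
  score_out <- numeric(nf)
  ncand <- vapply(cand_f0, length, 1L)
  # states per frame: 1..ncand voiced, ncand+1 unvoiced
  prev_cost <- NULL; back <- vector("list", nf)
  for (j in seq_len(nf)) {
    f <- cand_f0[[j]]; v <- cand_v[[j]]
    local <- c(1 - v + lag_weight * (fs / f) / kmax, unvoiced_cost)
    ns <- length(local)
    if (j == 1L) {
      cost <- local
      back[[j]] <- integer(ns)
    } else {
      fp <- cand_f0[[j - 1L]]
      np <- length(fp) + 1L
      trans <- matrix(voicing_transition_cost, np, ns)
      if (length(fp) && length(f))
        trans[seq_along(fp), seq_along(f)] <-
          octave_cost * abs(log2(outer(fp, f, "/")))
      trans[np, ns] <- 0                            # unvoiced -> unvoiced
      tot <- prev_cost + trans                      # np x ns
      bi <- max.col(-t(tot), ties.method = "first") # best predecessor per state
      cost <- local + tot[cbind(bi, seq_len(ns))]
      back[[j]] <- bi
    }
    prev_cost <- cost
  }
  # backtrace
  st <- which.min(prev_cost)
  for (j in rev(seq_len(nf))) {
    if (st <= ncand[j]) {
      f0_out[j] <- cand_f0[[j]][st]
      v_out[j] <- TRUE
      score_out[j] <- cand_v[[j]][st]
    }
    st <- if (j > 1L) back[[j]][st] else st
  }

  structure(
    list(frame_times = frame_times, f0_hz = f0_out, voiced = v_out,
         nccf = score_out, hop_s = hop_s, f_min = f_min, f_max = f_max),
    class = "pitch_track")
}

#' @export
print.pitch_track <- function(x, ...) {
  cat(sprintf("<pitch_track> %d frames, %.1f%% voiced, median F0 %.1f Hz\n",
              length(x$voiced), 100 * mean(x$voiced),
              stats::median(x$f0_hz, na.rm = TRUE)))
  invisible(x)
}

#' Extract voiced regions from a pitch track
#'
#' Maximal runs of voiced frames become `[start, end]` intervals (seconds);
#' frame extent is taken as `hop_s` centered on the frame time. Runs shorter
#' than `min_duration_s` are discarded.
#'
#' @param track a `pitch_track`.
#' @param min_duration_s minimum region length in seconds.
#' @return data.frame with columns `start`, `end` (sorted, non-overlapping).
#' @export
voiced_regions <- function(track, min_duration_s = 0) {
  stopifnot(inherits(track, "pitch_track"))
  v <- track$voiced
  if (!length(v)) stop("empty pitch track", call. = FALSE)
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  h <- track$hop_s / 2
  out <- data.frame(start = track$frame_times[starts[keep]] - h,
                    end   = track$frame_times[ends[keep]] + h)
  out$start <- pmax(out$start, 0)
  out[out$end - out$start >= min_duration_s - 1e-12, , drop = FALSE]
}

#' Write a per-frame pitch dump as two-column delimited text
#'
#' Columns are `time_s` and `f0_hz`; unvoiced frames are written as `NaN`.
#'
#' @param track a `pitch_track`.
#' @param path output path.
#' @export
write_pitch_dump <- function(track, path) {
  f0 <- ifelse(track$voiced, track$f0_hz, NaN)
  utils::write.table(
    data.frame(time_s = sprintf("%.4f", track$frame_times),
               f0_hz = ifelse(is.nan(f0), "NaN", sprintf("%.3f", f0))),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
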