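# Shared fixtures: tiny deterministic signals built in code.

make_tone <- function(freq, dur = 1, fs = 16000, amp = 0.8) {
  audio_signal(amp * sin(2 * pi * freq * seq(0, dur, by = 1 / fs)[-1]), fs)
}

# Harmonic complex with a linear frequency glide from f0 to f1 over `dur`.
make_glide <- function(f0, f1, dur = 1, fs = 16000, n_harm = 6, amp = 0.6) {
  t <- seq(0, dur, by = 1 / fs)[-1]
  f <- f0 + (f1 - f0) * t / dur
  phase <- 2 * pi * cumsum(f) / fs
  x <- 0
  for (h in seq_len(n_harm)) x <- x + sin(h * phase) / h
  list(signal = audio_signal(amp * x / max(abs(x)), fs),
       times = t, freqs = f)
}

# Hand-built envelope object for boundary/peak unit tests.
make_envelope <- function(values, hop_s = 0.005, t0 = 0) {
  structure(list(frame_times = t0 + (seq_along(values) - 1) * hop_s,
                 values = values, window_s = 2 * hop_s, hop_s = hop_s),
            class = "envelope")
}

# Hand-built pitch track.
make_track <- function(f0, voiced = !is.na(f0), hop_s = 0.005, t0 = 0) {
  structure(list(frame_times = t0 + (seq_along(f0) - 1) * hop_s,
                 f0_hz = f0, voiced = voiced,
                 nccf = as.numeric(voiced), hop_s = hop_s,
                 f_min = 60, f_max = 400),
            class = "pitch_track")
}

# Hand-built nuclei table; f0_means recycled over rows.
make_nuclei <- function(onset, offset, f0_means = NULL, f0_lists = NULL) {
  df <- data.frame(onset = onset, peak_time = (onset + offset) / 2,
                   offset = offset, duration = offset - onset)
  if (!is.null(f0_means)) {
    df$mean_f0_hz <- rep_len(f0_means, nrow(df))
    df$f0 <- if (is.null(f0_lists)) I(as.list(df$mean_f0_hz)) else I(f0_lists)
    df$unvoiced <- vapply(df$f0, length, 1L) == 0L
  }
  structure(df, class = c("syllable_nuclei", "data.frame"))
}

# Independent brute-force two-sample KS oracle: enumerate all C(n+m, n)
# group assignments of the pooled sample; p = share with D* >= D_obs.
ks_brute <- function(x, y) {
  n <- length(x); m <- length(y)
  pooled <- sort(c(x, y))
  d_of <- function(is_x) {
    max(abs(cumsum(is_x) / n - cumsum(!is_x) / m))
  }
  obs <- d_of(order(c(x, y)) <= n)  # positions of x in sorted pooled order
  combos <- utils::combn(n + m, n)
  ds <- apply(combos, 2, function(ix) {
    v <- logical(n + m); v[ix] <- TRUE; d_of(v)
  })
  list(D = obs, p = mean(ds >= obs - 1e-9))
}

# Random two-class feature table for classifier tests.
make_noise_table <- function(n_per_class = 10, k = 4, seed = 1) {
  set.seed(seed)
  data.frame(label = rep(c("MD", "non-MD"), each = n_per_class),
             matrix(rnorm(2 * n_per_class * k), ncol = k,
                    dimnames = list(NULL, paste0("F", seq_len(k)))))
}
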