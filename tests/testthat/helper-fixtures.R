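# Shared fixtures and independent reference implementations used as oracles.

# Rectangular sync pulse channel: height on a baseline, pulse spanning
# 1-based sample indices [start, start + len - 1].
rect_aux <- function(n, start, len, height, baseline = 0, fs = 1000) {
  x <- rep(baseline, n)
  x[start:(start + len - 1L)] <- baseline + height
  ppg_signal(x, fs = fs)
}

# Brute-force two-moving-average reference: per-sample window means with
# reflect indexing, pointwise threshold evaluation, explicit run enumeration.
# Deliberately naive (O(n * w)); use at low sampling rates.
brute_elgendi <- function(x, fs, w1_s = 0.18, w2_s = 0.69, beta = 0.01) {
  n <- length(x)
  sq <- pmax(x, 0)^2
  win_mean <- function(width_s) {
    w <- round(width_s * fs)
    if (w %% 2L == 0L) w <- w + 1L
    h <- (w - 1L) %/% 2L
    vapply(seq_len(n), function(i) {
      idx <- (i - h):(i + h)
      idx <- ifelse(idx < 1L, 2L - idx, idx)
      idx <- ifelse(idx > n, 2L * n - idx, idx)
      mean(sq[idx])
    }, numeric(1))
  }
  interest <- win_mean(w1_s) > win_mean(w2_s) + beta * mean(sq)
  peaks <- integer(0)
  i <- 1L
  while (i <= n) {
    if (!interest[i]) { i <- i + 1L; next }
    j <- i
    while (j < n && interest[j + 1L]) j <- j + 1L
    if (j - i + 1L >= round(w1_s * fs)) {
      seg <- i:j
      peaks <- c(peaks, seg[which.max(x[seg])])
    }
    i <- j + 1L
  }
  peaks
}

# Direct spectral-entropy summation over an explicit bin power vector;
# zero-power bins contribute nothing but still count toward N.
entropy_of_bins <- function(p) {
  n_bins <- length(p)
  p <- p / sum(p)
  p <- p[p > 0]
  -sum(p * log2(p)) / log2(n_bins)
}

# Detector recovery on a clean generated signal at one heart rate.
recovery_at <- function(hr, duration_s, seed) {
  params <- physio_params(mean_hr_bpm = hr, duration_s = duration_s,
                          seed = seed)
  g <- generate_clean(params)
  peaks <- elgendi_peaks(bandpass(g$signal), g$signal$fs)
  match_peaks(truth_peaks(g$truth, g$signal$fs), peaks)
}
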