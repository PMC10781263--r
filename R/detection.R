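#' Bandpass filter specification
#'
#' A 4th-order Butterworth bandpass with critical frequencies 1-8 Hz is the
#' standard PPG preprocessing choice: it removes the DC level and respiratory
#' drift below 1 Hz and the noise above 8 Hz while keeping the systolic
#' upstroke sharp.
#'
#' @param order filter order (of the one-pass design).
#' @param band numeric `c(low, high)` in Hz.
#' @param zero_phase apply forward-backward (default), so peak positions are
#'   not phase-shifted; this doubles the effective order.
#' @return A `filter_spec` list.
#' @export
filter_spec <- function(order = 4, band = c(1, 8), zero_phase = TRUE) {
  if (length(band) != 2L || band[1] <= 0 || band[2] <= band[1]) {
    ppg_stop("value_error", "band must satisfy 0 < low < high")
  }
  structure(list(order = order, band = band, family = "butterworth",
                 zero_phase = zero_phase), class = "filter_spec")
}

## Squared magnitude of the analog Butterworth bandpass prototype at
## frequency f (Hz): |H|^2 = 1 / (1 + ((w^2 - w1 w2) / (w (w2 - w1)))^(2 order)).
butter_bp_mag2 <- function(f, low, high, order) {
  w <- 2 * pi * f
  w0sq <- (2 * pi * low) * (2 * pi * high)
  bw <- 2 * pi * (high - low)
  x <- (w^2 - w0sq) / (w * bw)
  h <- 1 / (1 + x^(2 * order))
  h[f == 0] <- 0
  h
}

#' Butterworth bandpass preprocessing
#'
#' Zero-phase filtering is applied in the frequency domain: the
#' reflect-padded signal's spectrum is multiplied by the squared magnitude
#' of the analog Butterworth prototype, which is exactly the response of a
#' forward-backward application of the filter (zero phase, doubled
#' effective order) without the numerical conditioning problems of an
#' 8-pole recursion at low normalized frequencies. With `zero_phase =
#' FALSE` a conventional single-pass recursive filter is used instead (its
#' group delay then shifts peak positions).
#'
#' @param signal a [ppg_signal()] or numeric vector (then `fs` is required).
#' @param spec a [filter_spec()].
#' @param fs sampling rate in Hz when `signal` is a bare vector.
#' @return Numeric vector of filtered samples, same length as the input.
#' @export
bandpass <- function(signal, spec = filter_spec(), fs = NULL) {
  if (inherits(signal, "ppg_signal")) {
    fs <- signal$fs
    x <- signal$samples
  } else {
    if (is.null(fs)) ppg_stop("value_error", "fs required for a bare vector")
    x <- as.numeric(signal)
  }
  if (spec$band[2] >= fs / 2) {
    ppg_stop("value_error", "band must lie strictly below the Nyquist frequency")
  }
  if (!spec$zero_phase) {
    bf <- signal::butter(spec$order, spec$band / (fs / 2), type = "pass")
    return(as.numeric(signal::filter(bf, x)))
  }
  n <- length(x)
  pad <- min(n - 1L, round(5 * fs))
  xp <- if (pad > 0L) {
    c(rev(x[2L:(pad + 1L)]), x, rev(x[(n - pad):(n - 1L)]))
  } else {
    x
  }
  m <- length(xp)
  fr <- (seq_len(m) - 1L) * fs / m
  fr <- pmin(fr, fs - fr)                 # fold to two-sided frequencies
  h2 <- butter_bp_mag2(fr, spec$band[1], spec$band[2], spec$order)
  y <- Re(stats::fft(stats::fft(xp) * h2, inverse = TRUE)) / m
  y[(pad + 1L):(pad + n)]
}

#' Two-moving-average peak detector parameters
#'
#' The detector smooths the squared signal with two centered moving
#' averages: a short one at the scale of the systolic peak (`w1_s`) and a
#' long one at the scale of a whole beat (`w2_s`). Regions where the peak
#' average rises above the beat average (plus a small offset `beta` times the
#' mean squared signal) are candidate systolic blocks.
#'
#' @param w1_s peak window in seconds (default 0.18).
#' @param w2_s beat window in seconds (default 0.69).
#' @param beta dimensionless offset fraction (default 0.01).
#' @return An `elgendi_params` list.
#' @export
elgendi_params <- function(w1_s = 0.18, w2_s = 0.69, beta = 0.01) {
  if (w1_s <= 0 || w2_s <= w1_s) {
    ppg_stop("value_error", "windows must satisfy 0 < w1_s < w2_s")
  }
  if (beta < 0) ppg_stop("value_error", "beta must be non-negative")
  structure(list(w1_s = w1_s, w2_s = w2_s, beta = beta),
            class = "elgendi_params")
}

#' Systolic peak set
#'
#' @param indices strictly increasing 1-based sample indices.
#' @param fs sampling rate in Hz.
#' @param provenance `"automatic"`, `"manual"` or `"ground_truth"`.
#' @return A `peak_set` list with `indices`, `fs`, `provenance`.
#' @export
peak_set <- function(indices, fs,
                     provenance = c("automatic", "manual", "ground_truth")) {
  provenance <- match.arg(provenance)
  indices <- as.integer(indices)
  if (length(indices) > 1L && any(diff(indices) <= 0L)) {
    ppg_stop("value_error", "peak indices must be strictly increasing")
  }
  if (length(indices) > 0L && any(indices < 1L)) {
    ppg_stop("value_error", "peak indices must be positive")
  }
  structure(list(indices = indices, fs = fs, provenance = provenance),
            class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("<peak_set> %d %s peak(s) @ %g Hz\n", length(x$indices),
              x$provenance, x$fs))
  invisible(x)
}

#' Peak times in seconds
#' @param peaks a [peak_set()].
#' @return Numeric vector of peak times (sample 1 is time 0).
#' @export
peak_times <- function(peaks) (peaks$indices - 1L) / peaks$fs

#' Ground-truth peak set from a generator truth object
#' @param truth a `ground_truth` from [generate_clean()].
#' @param fs sampling rate in Hz.
#' @return A [peak_set()] with provenance `"ground_truth"`.
#' @export
truth_peaks <- function(truth, fs) {
  peak_set(round(truth$peak_times_s * fs) + 1L, fs, "ground_truth")
}

#' Systolic peak detection by two event-related moving averages
#'
#' Implements the two-moving-average scheme on a bandpassed PPG trace:
#' negative samples are clipped to zero and the result squared; a peak-scale
#' moving average (width `round(w1_s * fs)`, forced odd for centering) and a
#' beat-scale moving average (width `round(w2_s * fs)`, forced odd) are
#' computed with reflect padding; samples where the peak average exceeds the
#' dynamic threshold `MA_beat + beta * mean(squared)` form blocks of
#' interest; blocks narrower than `round(w1_s * fs)` samples are discarded;
#' each surviving block contributes one peak at the argmax of the filtered
#' signal within the block.
#'
#' @param filtered numeric vector, output of [bandpass()].
#' @param fs sampling rate in Hz.
#' @param params an [elgendi_params()].
#' @return A [peak_set()] with provenance `"automatic"`.
#' @export
elgendi_peaks <- function(filtered, fs, params = elgendi_params()) {
  x <- as.numeric(filtered)
  if (length(x) == 0L) return(peak_set(integer(0), fs, "automatic"))
  sq <- pmax(x, 0)^2
  w1 <- round(params$w1_s * fs)
  w2 <- round(params$w2_s * fs)
  ma_peak <- moving_average(sq, w1 + (1L - w1 %% 2L))
  ma_beat <- moving_average(sq, w2 + (1L - w2 %% 2L))
  thr1 <- ma_beat + params$beta * mean(sq)
  interest <- ma_peak > thr1
  if (!any(interest)) return(peak_set(integer(0), fs, "automatic"))

  r <- rle(interest)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= w1
  idx <- mapply(function(s, e) s + which.max(x[s:e]) - 1L,
                starts[keep], ends[keep])
  peak_set(as.integer(idx), fs, "automatic")
}

#' Pulse onset (foot) localization
#'
#' The onset of each beat is the minimum of the filtered signal between the
#' previous systolic peak and the current one (search interval
#' `(previous peak, current peak]`); the first beat's onset is searched in a
#' beat-window-length interval before the first peak.
#'
#' @param filtered numeric vector, output of [bandpass()].
#' @param peaks a [peak_set()] over the same trace.
#' @param w2_s beat window used for the first onset's search interval.
#' @return Integer vector of onset indices, one per peak (empty when `peaks`
#'   is empty).
#' @export
find_onsets <- function(filtered, peaks, w2_s = 0.69) {
  x <- as.numeric(filtered)
  idx <- peaks$indices
  if (length(idx) == 0L) return(integer(0))
  onsets <- integer(length(idx))
  first_lo <- max(1L, idx[1L] - round(w2_s * peaks$fs))
  onsets[1L] <- first_lo + which.min(x[first_lo:idx[1L]]) - 1L
  if (length(idx) > 1L) {
    for (i in 2L:length(idx)) {
      lo <- idx[i - 1L] + 1L
      onsets[i] <- lo + which.min(x[lo:idx[i]]) - 1L
    }
  }
  onsets
}
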