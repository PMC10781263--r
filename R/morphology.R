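#' Extract one pulse (onset to onset)
#'
#' Returns the samples of beat `beat_index`, spanning from its onset up to
#' (but excluding) the next beat's onset, so consecutive pulses partition the
#' trace between the first and last onset.
#'
#' @param filtered numeric vector (typically the [bandpass()] output).
#' @param peaks a [peak_set()] over the trace.
#' @param beat_index 1-based beat number; must have an onset on both sides,
#'   i.e. `1 <= beat_index <= length(peaks) - 1`.
#' @param onsets optional precomputed [find_onsets()] output.
#' @return Numeric vector of one pulse.
#' @export
extract_pulse <- function(filtered, peaks, beat_index, onsets = NULL) {
  if (is.null(onsets)) onsets <- find_onsets(filtered, peaks)
  if (length(onsets) < 2L || beat_index < 1L || beat_index > length(onsets) - 1L) {
    ppg_stop("index_error", "beat_index must have onsets on both sides")
  }
  as.numeric(filtered[onsets[beat_index]:(onsets[beat_index + 1L] - 1L)])
}

#' Min-max normalization to \[0, 1\]
#'
#' @param x numeric vector with `max(x) > min(x)`.
#' @return `(x - min) / (max - min)`.
#' @export
minmax_normalize <- function(x) {
  lo <- min(x); hi <- max(x)
  if (hi - lo <= 0) {
    ppg_stop("degenerate_pulse_error", "constant pulse cannot be normalized")
  }
  (x - lo) / (hi - lo)
}

#' Residual lag alignment of a pulse pair
#'
#' Small inter-site propagation delays survive device-level synchronization;
#' this finds the lag within `±max_lag_s` that maximizes the
#' cross-correlation of the mean-removed sequences, then crops both to their
#' common support. Positive lag means `y` lags (is delayed relative to) `x`.
#'
#' @param x,y equal-rate numeric sequences.
#' @param fs sampling rate in Hz.
#' @param max_lag_s lag search half-range in seconds (default 0.25).
#' @return List with `x`, `y` (aligned, equal length) and `lag_s`.
#' @export
align_lag <- function(x, y, fs, max_lag_s = 0.25) {
  xc <- x - mean(x)
  yc <- y - mean(y)
  n <- min(length(xc), length(yc))
  max_lag <- min(round(max_lag_s * fs), n - 1L)
  # normalized cross-correlation over the overlap: exactly 1 when the
  # overlapping segments are proportional, so an identical pair scores its
  # maximum at zero lag and an exact shift at the true lag
  score <- vapply(-max_lag:max_lag, function(k) {
    if (k >= 0) {
      xs <- xc[seq_len(n - k)]; ys <- yc[seq_len(n - k) + k]
    } else {
      xs <- xc[seq_len(n + k) - k]; ys <- yc[seq_len(n + k)]
    }
    den <- sqrt(sum(xs^2) * sum(ys^2))
    if (den == 0) -Inf else sum(xs * ys) / den
  }, numeric(1))
  k <- (-max_lag:max_lag)[which.max(score)]
  if (k >= 0) {
    xa <- x[seq_len(n - k)]
    ya <- y[seq_len(n - k) + k]
  } else {
    xa <- x[seq_len(n + k) - k]
    ya <- y[seq_len(n + k)]
  }
  list(x = xa, y = ya, lag_s = k / fs)
}

#' Pearson correlation coefficient
#'
#' Covariance over the product of standard deviations, with numerator and
#' denominator in the same (population) convention, so the value equals the
#' usual product-moment correlation.
#'
#' @param x,y equal-length numeric vectors, both non-constant.
#' @return Correlation in \[-1, 1\].
#' @export
pcc <- function(x, y) {
  if (length(x) != length(y)) ppg_stop("value_error", "length mismatch")
  xc <- x - mean(x); yc <- y - mean(y)
  sx <- sqrt(mean(xc^2)); sy <- sqrt(mean(yc^2))
  if (sx == 0 || sy == 0) {
    ppg_stop("undefined_error", "correlation undefined for constant input")
  }
  mean(xc * yc) / (sx * sy)
}

#' Cosine similarity
#'
#' Dot product over the product of Euclidean norms.
#'
#' @param x,y equal-length numeric vectors, both nonzero.
#' @return Similarity in \[-1, 1\].
#' @export
cosine_similarity <- function(x, y) {
  if (length(x) != length(y)) ppg_stop("value_error", "length mismatch")
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) {
    ppg_stop("undefined_error", "cosine similarity undefined for a zero vector")
  }
  sum(x * y) / (nx * ny)
}

#' Normalized Euclidean distance
#'
#' Square root of the sum of squared elementwise differences of two min-max
#' normalized pulses. There is no division by length, so the magnitude grows
#' as the square root of the pulse length; compare equal-length pulses only.
#'
#' @param x_norm,y_norm equal-length, min-max normalized vectors.
#' @return Distance `>= 0`; 0 iff the pulses are identical.
#' @export
ned <- function(x_norm, y_norm) {
  if (length(x_norm) != length(y_norm)) {
    ppg_stop("value_error", "length mismatch")
  }
  sqrt(sum((x_norm - y_norm)^2))
}

## Linear resampling to a target length (used to put a pulse pair on a
## common grid before the metrics).
resample_to <- function(x, n_out) {
  if (length(x) == n_out) return(x)
  stats::approx(seq_along(x), x, n = n_out)$y
}

#' Morphological comparison of one pulse pair across two channels
#'
#' Full pulse-pair pipeline: extract the selected beat from each channel
#' (onset to onset), min-max normalize, resample the longer pulse to the
#' shorter one's length, re-align for residual inter-site lag, and compute
#' the three similarity metrics on the aligned normalized pulses.
#'
#' By default the beat is chosen as the one lying in the lowest-entropy
#' quality window of channel `a` among beats available in both channels
#' (i.e. the beat with the cleanest periodicity); pass `beat_index` to
#' override.
#'
#' @param filtered_a,filtered_b bandpassed traces of the two channels.
#' @param peaks_a,peaks_b [peak_set()]s of the two channels.
#' @param fs sampling rate in Hz.
#' @param beat_index optional explicit beat number.
#' @param max_lag_s residual-lag search half-range (default 0.25 s).
#' @param spec [quality_spec()] used for default beat selection.
#' @return A `morphology_result` list: `pcc`, `cs`, `ned`, `lag_s`,
#'   `beat_index`.
#' @export
compare_pulses <- function(filtered_a, peaks_a, filtered_b, peaks_b, fs,
                           beat_index = NULL, max_lag_s = 0.25,
                           spec = quality_spec()) {
  onsets_a <- find_onsets(filtered_a, peaks_a)
  onsets_b <- find_onsets(filtered_b, peaks_b)
  n_beats <- min(length(onsets_a), length(onsets_b)) - 1L
  if (n_beats < 1L) ppg_stop("index_error", "no overlapping beats")

  if (is.null(beat_index)) {
    beat_index <- select_beat(filtered_a, peaks_a, n_beats, fs, spec)
  }
  pa <- extract_pulse(filtered_a, peaks_a, beat_index, onsets_a)
  pb <- extract_pulse(filtered_b, peaks_b, beat_index, onsets_b)
  pa <- minmax_normalize(pa)
  pb <- minmax_normalize(pb)
  n_common <- min(length(pa), length(pb))
  pa <- resample_to(pa, n_common)
  pb <- resample_to(pb, n_common)
  al <- align_lag(pa, pb, fs, max_lag_s)
  structure(list(pcc = pcc(al$x, al$y),
                 cs = cosine_similarity(al$x, al$y),
                 ned = ned(al$x, al$y),
                 lag_s = al$lag_s, beat_index = beat_index),
            class = "morphology_result")
}

#' @export
print.morphology_result <- function(x, ...) {
  cat(sprintf("<morphology_result> beat %d: PCC %.3f, CS %.3f, nED %.3f (lag %+.0f ms)\n",
              x$beat_index, x$pcc, x$cs, x$ned, 1000 * x$lag_s))
  invisible(x)
}

## Beat whose quality window has the lowest spectral entropy; falls back to
## the first beat when the trace is shorter than one window.
select_beat <- function(filtered, peaks, n_beats, fs, spec) {
  wlen <- round(spec$window_s * fs)
  n_win <- length(filtered) %/% wlen
  if (n_win < 1L) return(1L)
  se <- vapply(seq_len(n_win), function(w) {
    win <- filtered[((w - 1L) * wlen + 1L):(w * wlen)]
    tryCatch(spectral_entropy(win, fs, spec$band),
             ppgbench_error = function(e) NA_real_)
  }, numeric(1))
  beat_win <- pmin(n_win, 1L + (peaks$indices[seq_len(n_beats)] - 1L) %/% wlen)
  se_per_beat <- se[beat_win]
  if (all(is.na(se_per_beat))) return(1L)
  which.min(se_per_beat)
}
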