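#' Quality-scoring specification
#'
#' Parameters of the spectral-entropy quality index: consecutive
#' non-overlapping windows of `window_s` seconds, a frequency band (default
#' 1-3 Hz, spanning plausible resting heart rates and their first harmonic),
#' and the threshold above which a signal's mean entropy marks it as poor
#' quality.
#'
#' @param window_s window length in seconds (default 4).
#' @param band numeric length-2 vector `c(f1, f2)` in Hz, `0 < f1 < f2`.
#' @param poor_threshold mean-entropy cut-off; quality is poor when the mean
#'   is strictly above it.
#' @return A `quality_spec` list.
#' @export
quality_spec <- function(window_s = 4, band = c(1, 3), poor_threshold = 0.8) {
  if (window_s <= 0) ppg_stop("value_error", "window_s must be positive")
  if (length(band) != 2L || band[1] <= 0 || band[2] <= band[1]) {
    ppg_stop("value_error", "band must satisfy 0 < f1 < f2")
  }
  structure(list(window_s = window_s, band = band,
                 poor_threshold = poor_threshold, hop = window_s),
            class = "quality_spec")
}

#' Band-limited spectral entropy of one window
#'
#' Shannon entropy of the in-band power distribution, normalized to \[0, 1\]:
#' the power spectral density of the window is estimated by Welch's method
#' (rectangular segments of `segment_s` seconds, 50% overlap, demeaned per
#' segment, periodograms averaged), the bins with `f1 <= f <= f2` (inclusive
#' on both edges) are renormalized to sum to one, and
#' `SE = -sum(p * log2(p)) / log2(N)` is computed over the `N` in-band bins
#' (zero-power bins contribute 0). A pure in-band tone gives values near 0,
#' white noise values near 1; the segment averaging is what makes a noise
#' spectrum flat enough to score high, while a periodic signal keeps its
#' power in the bin(s) at the cardiac fundamental and scores low.
#'
#' Windows shorter than one segment are analyzed as a single segment.
#'
#' @param window numeric vector of at least 8 samples.
#' @param fs sampling rate in Hz.
#' @param band numeric `c(f1, f2)`, within the Nyquist range.
#' @param segment_s Welch segment length in seconds (default 1, giving a
#'   1 Hz bin spacing and 3 bins in the default 1-3 Hz band).
#' @param overlap segment overlap fraction in \[0, 1) (default 0.5).
#' @return Spectral entropy in \[0, 1\].
#' @export
spectral_entropy <- function(window, fs, band = c(1, 3), segment_s = 1,
                             overlap = 0.5) {
  n <- length(window)
  if (n < 8L) ppg_stop("insufficient_data_error", "window must have >= 8 samples")
  if (band[2] > fs / 2) ppg_stop("value_error", "band exceeds the Nyquist frequency")
  L <- min(n, round(segment_s * fs))
  step <- max(1L, round(L * (1 - overlap)))
  starts <- seq(1L, n - L + 1L, by = step)
  spec <- numeric(floor(L / 2) + 1L)
  half <- seq_along(spec)                 # 0 .. Nyquist of one segment
  for (s in starts) {
    seg <- window[s:(s + L - 1L)]
    seg <- seg - mean(seg)
    spec <- spec + Mod(stats::fft(seg))[half]^2
  }
  freqs <- (half - 1L) * fs / L
  tol <- 1e-9 * fs
  inband <- freqs >= band[1] - tol & freqs <= band[2] + tol
  N <- sum(inband)
  if (N == 0L) ppg_stop("value_error", "band contains no frequency bin")
  p <- spec[inband]
  total <- sum(p)
  if (total <= 0) ppg_stop("undefined_se_error", "all in-band power is zero")
  if (N == 1L) return(0)
  p <- p / total
  p <- p[p > 0]
  -sum(p * log2(p)) / log2(N)
}

#' Windowed spectral-entropy quality profile
#'
#' Splits the signal into consecutive non-overlapping windows (any trailing
#' partial window is discarded), scores each with [spectral_entropy()], and
#' averages. When an exclusion mask (from [remove_saturated_windows()]) is
#' given, a second mean over the retained windows only is reported, which is
#' how quality of the "non-saturated signal" is assessed.
#'
#' @param signal a [ppg_signal()] at least one window long.
#' @param spec a [quality_spec()].
#' @param exclusion optional `window_exclusion` or logical vector (one flag
#'   per full window, `TRUE` = excluded).
#' @return A `quality_report` list: `window_se` (NA where entropy was
#'   undefined), `mean_se`, `mean_se_excluding_saturated`, `n_windows`,
#'   `n_excluded`.
#' @export
quality_profile <- function(signal, spec = quality_spec(), exclusion = NULL) {
  stopifnot(inherits(signal, "ppg_signal"))
  wlen <- round(spec$window_s * signal$fs)
  n_win <- length(signal$samples) %/% wlen
  if (n_win < 1L) {
    ppg_stop("insufficient_data_error", "signal shorter than one window")
  }
  if (inherits(exclusion, "window_exclusion")) {
    if (abs(exclusion$window_s - spec$window_s) > 1e-9) {
      ppg_stop("value_error", "exclusion window length does not match spec")
    }
    exclusion <- exclusion$excluded
  }
  if (is.null(exclusion)) exclusion <- rep(FALSE, n_win)
  exclusion <- rep_len(as.logical(exclusion), n_win)

  se <- vapply(seq_len(n_win), function(w) {
    win <- signal$samples[((w - 1L) * wlen + 1L):(w * wlen)]
    tryCatch(spectral_entropy(win, signal$fs, spec$band),
             undefined_se_error = function(e) NA_real_)
  }, numeric(1))

  defined <- !is.na(se)
  if (!any(defined)) {
    ppg_stop("insufficient_data_error", "no window has defined entropy")
  }
  keep <- defined & !exclusion
  if (!any(keep)) {
    ppg_stop("insufficient_data_error", "all windows excluded")
  }
  structure(list(window_se = se,
                 mean_se = mean(se[defined]),
                 mean_se_excluding_saturated = mean(se[keep]),
                 n_windows = n_win, n_excluded = sum(exclusion)),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("<quality_report> mean SE %.3f over %d windows (%d excluded; %.3f excl. saturated)\n",
              x$mean_se, x$n_windows, x$n_excluded,
              x$mean_se_excluding_saturated))
  invisible(x)
}

#' Poor-quality decision
#'
#' A signal is poor quality iff its mean spectral entropy is strictly above
#' the cut-off (default 0.8): high entropy means the in-band power is spread
#' rather than concentrated at the cardiac fundamental.
#'
#' @param report a `quality_report` from [quality_profile()].
#' @param spec a [quality_spec()].
#' @return Logical.
#' @export
is_poor_quality <- function(report, spec = quality_spec()) {
  report$mean_se > spec$poor_threshold
}
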