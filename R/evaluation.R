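#' Match detected peaks against ground truth within a time tolerance
#'
#' One-to-one greedy matching in increasing time order: each ground-truth
#' peak is paired with the nearest still-unmatched detected peak within
#' `±tolerance_s` (boundary inclusive). Unmatched truth peaks are false
#' negatives; unmatched detected peaks are false positives. The one-to-one
#' rule never lets a single detected peak satisfy two truth peaks, so it
#' never inflates the true-positive count.
#'
#' @param truth,detected [peak_set()]s sharing a sampling rate.
#' @param tolerance_s matching tolerance in seconds (default 0.05, i.e.
#'   50 ms).
#' @return A `match_result` list: `tp`, `fp`, `fn`, `sensitivity`
#'   (`tp/(tp+fn)`), `precision` (`tp/(tp+fp)`, `NA` with
#'   `precision_defined = FALSE` when nothing was detected), `pairs` (two
#'   column matrix of matched truth/detected indices into the peak sets),
#'   `tolerance_s`.
#' @export
match_peaks <- function(truth, detected, tolerance_s = 0.05) {
  stopifnot(inherits(truth, "peak_set"), inherits(detected, "peak_set"))
  if (abs(truth$fs - detected$fs) > 1e-9) {
    ppg_stop("value_error", "peak sets must share a sampling rate")
  }
  tt <- peak_times(truth)
  td <- peak_times(detected)
  used <- rep(FALSE, length(td))
  pairs <- matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("truth", "detected")))
  for (i in seq_along(tt)) {
    if (!length(td)) break
    d <- abs(td - tt[i])
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && d[j] <= tolerance_s + 1e-12) {
      used[j] <- TRUE
      pairs <- rbind(pairs, c(i, j))
    }
  }
  tp <- nrow(pairs)
  fn <- length(tt) - tp
  fp <- length(td) - tp
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  prec_defined <- (tp + fp) > 0
  prec <- if (prec_defined) tp / (tp + fp) else NA_real_
  structure(list(tp = tp, fp = fp, fn = fn, sensitivity = sens,
                 precision = prec, precision_defined = prec_defined,
                 pairs = pairs, tolerance_s = tolerance_s),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> tp %d, fp %d, fn %d | sensitivity %.3f, precision %s (tol %g ms)\n",
              x$tp, x$fp, x$fn, x$sensitivity,
              if (x$precision_defined) sprintf("%.3f", x$precision) else "undefined",
              1000 * x$tolerance_s))
  invisible(x)
}

#' Instantaneous heart rate from systolic peaks
#'
#' `HR_i = 60 / (t_{i+1} - t_i)` for each consecutive peak pair, with mean
#' and standard deviation over the series.
#'
#' @param peaks a [peak_set()] with at least 2 peaks.
#' @return An `hr_report` list: `hr_series_bpm`, `mean_hr_bpm`, `sd_hr_bpm`,
#'   `n_beats`.
#' @export
hr_from_peaks <- function(peaks) {
  stopifnot(inherits(peaks, "peak_set"))
  if (length(peaks$indices) < 2L) {
    ppg_stop("insufficient_peaks_error", "need at least 2 peaks for HR")
  }
  rr <- diff(peak_times(peaks))
  hr <- 60 / rr
  structure(list(hr_series_bpm = hr, mean_hr_bpm = mean(hr),
                 sd_hr_bpm = if (length(hr) > 1L) stats::sd(hr) else 0,
                 n_beats = length(hr)),
            class = "hr_report")
}

#' Heart-rate estimation error
#'
#' Absolute difference of the mean heart rates and the relative error of the
#' automatic estimate against the ground truth, in percent:
#' `100 * |HR_auto - HR_truth| / HR_truth`. Errors below 5% are commonly
#' taken as acceptable for clinical heart-rate devices.
#'
#' @param auto,truth `hr_report`s from [hr_from_peaks()].
#' @return List with `mean_hr_diff_bpm` and `percent_error`.
#' @export
hr_error <- function(auto, truth) {
  if (truth$mean_hr_bpm == 0) {
    ppg_stop("undefined_error", "ground-truth mean HR is zero")
  }
  d <- abs(auto$mean_hr_bpm - truth$mean_hr_bpm)
  list(mean_hr_diff_bpm = d,
       percent_error = 100 * d / truth$mean_hr_bpm)
}

#' Poincare descriptors of the peak-to-peak intervals
#'
#' From the scatter of each RR interval against the next, SD1 measures
#' dispersion perpendicular to the identity line (short-term variability)
#' and SD2 along it (long-term variability):
#' `SD1 = SD((RR_{i+1} - RR_i) / sqrt(2))`,
#' `SD2 = SD((RR_{i+1} + RR_i) / sqrt(2))` (population SD), reported in ms.
#'
#' @param peaks a [peak_set()] with at least 3 peaks.
#' @return A `poincare_descriptors` list: `sd1_ms`, `sd2_ms`, `n_points`,
#'   `rr1_ms`, `rr2_ms` (the scatter coordinates).
#' @export
poincare <- function(peaks) {
  stopifnot(inherits(peaks, "peak_set"))
  if (length(peaks$indices) < 3L) {
    ppg_stop("insufficient_peaks_error", "need at least 3 peaks for Poincare")
  }
  rr <- diff(peak_times(peaks)) * 1000   # ms
  rr1 <- rr[-length(rr)]
  rr2 <- rr[-1L]
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  structure(list(sd1_ms = pop_sd((rr2 - rr1) / sqrt(2)),
                 sd2_ms = pop_sd((rr2 + rr1) / sqrt(2)),
                 n_points = length(rr1), rr1_ms = rr1, rr2_ms = rr2),
            class = "poincare_descriptors")
}

#' Poincare scatter plot
#'
#' @param x a `poincare_descriptors` from [poincare()].
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.poincare_descriptors <- function(x, ...) {
  graphics::plot(x$rr1_ms, x$rr2_ms, xlab = "RR_i (ms)",
                 ylab = "RR_i+1 (ms)", asp = 1,
                 main = sprintf("SD1 %.1f ms, SD2 %.1f ms", x$sd1_ms, x$sd2_ms),
                 ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
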