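#' Calibrate a saturation threshold by the mean-minus-one-SD rule
#'
#' From a calibration recording driven into saturation (e.g. by shining an
#' LED directly onto the photodetector for ~10 s), takes all samples strictly
#' above a manually chosen initial threshold and sets the final saturation
#' threshold to their mean minus one standard deviation. Saturation of a real
#' front-end is gradual rather than instantaneous, so the samples above the
#' manual threshold have spread; subtracting one SD yields a conservative
#' threshold that captures more of the saturated regime without admitting
#' outliers.
#'
#' The SD is the population SD (divide by n); see `sd_type` to switch to the
#' sample convention.
#'
#' @param calibration a [ppg_signal()] recorded under forced saturation.
#' @param initial_threshold manual ADC threshold; at least one sample must
#'   lie strictly above it.
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return A `saturation_profile` list: `initial_threshold`, `mean_above`,
#'   `sd_above`, `min_above`, `max_above`, `median_above`, `n_samples_above`,
#'   `final_threshold = mean_above - sd_above`.
#' @export
#' @examples
#' cal <- ppg_signal(c(10, 20, 100, 102, 98), fs = 1000)
#' calibrate_threshold(cal, 50)$final_threshold  # 98.367
calibrate_threshold <- function(calibration, initial_threshold,
                                sd_type = c("population", "sample")) {
  stopifnot(inherits(calibration, "ppg_signal"))
  sd_type <- match.arg(sd_type)
  above <- calibration$samples[calibration$samples > initial_threshold]
  if (length(above) == 0L) {
    ppg_stop("calibration_error",
             "no calibration sample above the initial threshold")
  }
  m <- mean(above)
  s <- if (length(above) == 1L) 0 else stats::sd(above)
  if (sd_type == "population") {
    s <- s * sqrt((length(above) - 1) / length(above))
  }
  if (is.na(s)) s <- 0
  structure(list(initial_threshold = initial_threshold,
                 mean_above = m, sd_above = s,
                 min_above = min(above), max_above = max(above),
                 median_above = stats::median(above),
                 n_samples_above = length(above),
                 final_threshold = m - s),
            class = "saturation_profile")
}

#' @export
print.saturation_profile <- function(x, ...) {
  cat(sprintf(
    "<saturation_profile> final threshold %.3f (mean %.3f - sd %.3f, n = %d above %.3f)\n",
    x$final_threshold, x$mean_above, x$sd_above, x$n_samples_above,
    x$initial_threshold))
  invisible(x)
}

#' Classify saturated samples
#'
#' A sample is saturated iff its value is at or above the profile's final
#' threshold (the threshold itself is a saturation value). Reports the
#' percentage of saturated samples and the maximal contiguous saturated runs.
#'
#' @param signal a [ppg_signal()].
#' @param profile a `saturation_profile` from [calibrate_threshold()], or a
#'   single numeric threshold.
#' @return A `saturation_report` list: `percent_saturated` (0-100), `mask`
#'   (logical per sample), `runs` (data frame of 1-based inclusive
#'   `start`/`end` sample indices), `final_threshold`.
#' @export
classify_saturation <- function(signal, profile) {
  stopifnot(inherits(signal, "ppg_signal"))
  thr <- if (inherits(profile, "saturation_profile")) {
    profile$final_threshold
  } else {
    as.numeric(profile)
  }
  mask <- signal$samples >= thr
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  structure(list(percent_saturated = 100 * sum(mask) / length(mask),
                 mask = mask, runs = runs, final_threshold = thr),
            class = "saturation_report")
}

#' @export
print.saturation_report <- function(x, ...) {
  cat(sprintf("<saturation_report> %.3f%% saturated (%d run(s), threshold %.3f)\n",
              x$percent_saturated, nrow(x$runs), x$final_threshold))
  invisible(x)
}

#' Mark analysis windows containing saturation for exclusion
#'
#' Quality scoring averages spectral entropy over consecutive windows; this
#' marks every window that contains at least one saturated sample so the
#' average can be recomputed over non-saturated signal only. Samples are not
#' modified (window exclusion avoids the splicing discontinuities that
#' deleting samples would create).
#'
#' @param signal a [ppg_signal()].
#' @param report a `saturation_report` from [classify_saturation()].
#' @param window_s window length in seconds (must match the quality spec).
#' @return A `window_exclusion` list: `excluded` (logical per full window),
#'   `window_s`, `n_windows`.
#' @export
remove_saturated_windows <- function(signal, report, window_s = 4) {
  stopifnot(inherits(signal, "ppg_signal"),
            inherits(report, "saturation_report"))
  if (window_s <= 0) ppg_stop("value_error", "window_s must be positive")
  wlen <- round(window_s * signal$fs)
  n_win <- length(signal$samples) %/% wlen
  excluded <- vapply(seq_len(n_win), function(w) {
    any(report$mask[((w - 1L) * wlen + 1L):(w * wlen)])
  }, logical(1))
  structure(list(excluded = excluded, window_s = window_s, n_windows = n_win),
            class = "window_exclusion")
}
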