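#' PPG signal object
#'
#' A uniformly sampled single-channel PPG recording together with its
#' acquisition metadata. Samples are real ADC values (arbitrary PPG units);
#' signals that have not yet passed through an ADC front-end may carry
#' `adc_bits = NULL` and arbitrary real values.
#'
#' @param samples numeric vector of samples, length at least 1.
#' @param fs sampling rate in Hz, strictly positive.
#' @param adc_bits optional integer ADC bit depth. When set, all samples must
#'   lie in `[0, 2^adc_bits - 1]`.
#' @param sensor_label,site,device optional character metadata (sensor
#'   configuration label, anatomical site, acquisition device).
#' @param t0 start-time offset in seconds (default 0).
#' @return An object of class `ppg_signal`.
#' @export
ppg_signal <- function(samples, fs, adc_bits = NULL, sensor_label = NULL,
                       site = NULL, device = NULL, t0 = 0) {
  if (!is.numeric(samples) || length(samples) < 1L) {
    ppg_stop("value_error", "samples must be a non-empty numeric vector")
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    ppg_stop("value_error", "fs must be a single positive number")
  }
  if (!is.null(adc_bits)) {
    ceiling_code <- adc_ceiling(adc_bits)
    bad <- which(samples < 0 | samples > ceiling_code)
    if (length(bad) > 0L) {
      ppg_stop("range_error", sprintf(
        "sample %d (value %g) outside ADC range [0, %g]",
        bad[1L], samples[bad[1L]], ceiling_code))
    }
  }
  structure(
    list(samples = as.numeric(samples), fs = fs, adc_bits = adc_bits,
         sensor_label = sensor_label, site = site, device = device, t0 = t0),
    class = "ppg_signal")
}

#' @export
print.ppg_signal <- function(x, ...) {
  dur <- length(x$samples) / x$fs
  cat(sprintf("<ppg_signal> %d samples @ %g Hz (%.3f s)\n",
              length(x$samples), x$fs, dur))
  if (!is.null(x$adc_bits)) cat(sprintf("  adc_bits: %d\n", x$adc_bits))
  for (f in c("sensor_label", "site", "device")) {
    if (!is.null(x[[f]])) cat(sprintf("  %s: %s\n", f, x[[f]]))
  }
  invisible(x)
}

#' @export
length.ppg_signal <- function(x) length(x$samples)

#' Signal duration in seconds
#' @param signal a [ppg_signal()].
#' @return Duration in seconds (`length / fs`).
#' @export
signal_duration <- function(signal) length(signal$samples) / signal$fs

#' Multi-channel recording
#'
#' A set of [ppg_signal()] channels acquired together, optionally with an
#' auxiliary optical synchronization channel (the LED/LUX pulse shared by
#' both devices) and at-rest / movement segment labels.
#'
#' @param signals named list of `ppg_signal` objects sharing one sampling
#'   rate.
#' @param aux_sync optional `ppg_signal` holding the sync channel.
#' @param labels data frame with columns `start_s`, `end_s`, `label`
#'   (half-open intervals, labels `"at_rest"` or `"movement"`).
#' @return An object of class `ppg_recording`.
#' @export
ppg_recording <- function(signals, aux_sync = NULL, labels = NULL) {
  if (length(signals) > 0L) {
    stopifnot(all(vapply(signals, inherits, logical(1), "ppg_signal")))
    fss <- vapply(signals, function(s) s$fs, numeric(1))
    if (length(unique(fss)) != 1L) {
      ppg_stop("value_error", "all channels must share one sampling rate")
    }
  }
  if (!is.null(labels)) {
    stopifnot(all(c("start_s", "end_s", "label") %in% names(labels)))
    if (nrow(labels) > 1L) {
      o <- order(labels$start_s)
      labels <- labels[o, , drop = FALSE]
      if (any(labels$end_s[-nrow(labels)] > labels$start_s[-1L] + 1e-12)) {
        ppg_stop("value_error", "label intervals must not overlap")
      }
    }
  }
  structure(list(signals = signals, aux_sync = aux_sync, labels = labels),
            class = "ppg_recording")
}

#' @export
print.ppg_recording <- function(x, ...) {
  cat(sprintf("<ppg_recording> %d channel(s): %s\n", length(x$signals),
              paste(names(x$signals), collapse = ", ")))
  if (!is.null(x$aux_sync)) cat("  aux_sync channel present\n")
  if (!is.null(x$labels) && nrow(x$labels)) {
    cat(sprintf("  labels: %s\n", paste(
      sprintf("[%g,%g) %s", x$labels$start_s, x$labels$end_s, x$labels$label),
      collapse = "; ")))
  }
  invisible(x)
}

sidecar_path <- function(path) sub("\\.[Cc][Ss][Vv]$", ".json", path)

#' Write a signal to CSV with a JSON metadata sidecar
#'
#' The CSV has a `time_s,value` header; the sidecar records `fs`, `adc_bits`,
#' `sensor_label`, `site`, `device` and `labels` (explicit nulls when unset).
#' Integer-valued samples round-trip bit-exactly through [read_signal()].
#'
#' @param signal a [ppg_signal()].
#' @param path CSV output path; the sidecar is written next to it with a
#'   `.json` extension unless `sidecar` overrides it.
#' @param sidecar optional sidecar path.
#' @return Invisibly, the sidecar path.
#' @export
write_signal <- function(signal, path, sidecar = sidecar_path(path)) {
  stopifnot(inherits(signal, "ppg_signal"))
  n <- length(signal$samples)
  time_s <- signal$t0 + (seq_len(n) - 1L) / signal$fs
  ok <- tryCatch({
    con <- file(path, "w"); on.exit(close(con))
    writeLines("time_s,value", con)
    writeLines(paste(format(time_s, digits = 15, trim = TRUE, scientific = FALSE),
                     format(signal$samples, digits = 15, trim = TRUE,
                            scientific = FALSE), sep = ","), con)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) ppg_stop("io_error", paste("cannot write", path))
  meta <- list(fs = signal$fs, adc_bits = signal$adc_bits,
               sensor_label = signal$sensor_label, site = signal$site,
               device = signal$device, labels = NULL)
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, null = "null",
                       digits = NA)
  invisible(sidecar)
}

#' Read a signal from CSV plus its JSON sidecar
#'
#' @param path CSV path with a `time_s,value` header.
#' @param sidecar path of the JSON metadata sidecar (defaults to `path` with
#'   the extension swapped for `.json`).
#' @return A [ppg_signal()] with metadata populated from the sidecar.
#' @export
read_signal <- function(path, sidecar = sidecar_path(path)) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!all(c("time_s", "value") %in% names(df))) {
    ppg_stop("format_error", "CSV must have 'time_s' and 'value' columns")
  }
  if (nrow(df) > 1L && any(diff(df$time_s) <= 0)) {
    ppg_stop("format_error", "time column must be strictly increasing")
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  fs <- meta$fs
  if (is.null(fs)) {
    fs <- if (nrow(df) > 1L) 1 / stats::median(diff(df$time_s)) else 1
  }
  ppg_signal(df$value, fs = fs, adc_bits = meta$adc_bits,
             sensor_label = meta$sensor_label, site = meta$site,
             device = meta$device, t0 = df$time_s[1L])
}

#' Label at-rest and movement segments
#'
#' Marks the first `rest_duration_s` seconds of the recording as `at_rest`
#' and the remainder as `movement`; a recording shorter than the rest
#' duration is labeled entirely at rest. Intervals are half-open.
#'
#' @param recording a [ppg_recording()].
#' @param rest_duration_s non-negative rest duration in seconds.
#' @return The recording with its `labels` field replaced.
#' @export
label_segments <- function(recording, rest_duration_s) {
  stopifnot(inherits(recording, "ppg_recording"))
  if (!is.numeric(rest_duration_s) || rest_duration_s < 0) {
    ppg_stop("value_error", "rest_duration_s must be non-negative")
  }
  dur <- max(vapply(recording$signals, signal_duration, numeric(1)))
  cut <- min(rest_duration_s, dur)
  labels <- data.frame(start_s = numeric(0), end_s = numeric(0),
                       label = character(0))
  if (cut > 0) {
    labels <- rbind(labels, data.frame(start_s = 0, end_s = cut,
                                       label = "at_rest"))
  }
  if (cut < dur) {
    labels <- rbind(labels, data.frame(start_s = cut, end_s = dur,
                                       label = "movement"))
  }
  recording$labels <- labels
  recording
}

#' Locate the optical synchronization pulse
#'
#' Returns the time of the first rising crossing of
#' `min + threshold_fraction * (max - min)` in the auxiliary channel; the
#' crossing time is the time of the first sample at or above the threshold.
#'
#' @param aux the sync-channel [ppg_signal()].
#' @param threshold_fraction crossing level as a fraction of the pulse
#'   amplitude, in (0, 1); default 0.5 (midpoint, robust to pulse shape).
#' @return Pulse time in seconds from the start of the channel.
#' @export
detect_sync_pulse <- function(aux, threshold_fraction = 0.5) {
  stopifnot(inherits(aux, "ppg_signal"))
  if (threshold_fraction <= 0 || threshold_fraction >= 1) {
    ppg_stop("value_error", "threshold_fraction must be in (0, 1)")
  }
  x <- aux$samples
  lo <- min(x); hi <- max(x)
  if (hi - lo <= 0) ppg_stop("no_pulse_error", "sync channel is flat")
  thr <- lo + threshold_fraction * (hi - lo)
  idx <- which(x >= thr)[1L]
  if (is.na(idx)) ppg_stop("no_pulse_error", "no crossing found")
  (idx - 1L) / aux$fs
}

#' Align two recordings by their optical sync pulses
#'
#' Computes the signed shift, in samples, that device B must be advanced by
#' so that the two sync-pulse edges coincide:
#' `offset_samples = round((edge_b - edge_a) * fs)`. Sub-sample residuals are
#' rounded; at typical PPG rates one sample is far below the 50 ms peak
#' matching tolerance.
#'
#' @param a,b [ppg_recording()] objects, each with an `aux_sync` channel.
#' @param threshold_fraction passed to [detect_sync_pulse()].
#' @return A `sync_result` list with `offset_samples`, `edge_a_s`, `edge_b_s`.
#' @export
align_recordings <- function(a, b, threshold_fraction = 0.5) {
  for (r in list(a, b)) {
    if (!inherits(r, "ppg_recording") || is.null(r$aux_sync)) {
      ppg_stop("sync_error", "both recordings need an aux_sync channel")
    }
  }
  edge_a <- detect_sync_pulse(a$aux_sync, threshold_fraction)
  edge_b <- detect_sync_pulse(b$aux_sync, threshold_fraction)
  fs <- b$aux_sync$fs
  offset <- as.integer(round((edge_b - edge_a) * fs))
  shorter <- min(length(a$aux_sync$samples), length(b$aux_sync$samples))
  if (abs(offset) >= shorter) {
    ppg_stop("sync_error", "sync offset exceeds recording length")
  }
  structure(list(offset_samples = offset, edge_a_s = edge_a,
                 edge_b_s = edge_b), class = "sync_result")
}

#' @export
print.sync_result <- function(x, ...) {
  cat(sprintf("<sync_result> offset %+d samples (edges %.3f s / %.3f s)\n",
              x$offset_samples, x$edge_a_s, x$edge_b_s))
  invisible(x)
}

#' Apply a sync offset to a recording
#'
#' Advances every channel (including the aux channel) of the recording by
#' `offset_samples`: positive offsets drop leading samples and pad the tail
#' by holding the last value, so length is preserved.
#'
#' @param recording a [ppg_recording()].
#' @param offset_samples signed integer shift, as produced by
#'   [align_recordings()] for device B.
#' @return The shifted recording.
#' @export
shift_recording <- function(recording, offset_samples) {
  stopifnot(inherits(recording, "ppg_recording"))
  k <- as.integer(offset_samples)
  shift1 <- function(sig) {
    x <- sig$samples; n <- length(x)
    if (k > 0) {
      x <- c(x[(k + 1L):n], rep(x[n], k))
    } else if (k < 0) {
      x <- c(rep(x[1L], -k), x[1L:(n + k)])
    }
    sig$samples <- x
    sig
  }
  recording$signals <- lapply(recording$signals, shift1)
  if (!is.null(recording$aux_sync)) recording$aux_sync <- shift1(recording$aux_sync)
  recording
}
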