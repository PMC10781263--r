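#' Transimpedance amplifier closed-loop gain
#'
#' Gain of a non-inverting amplification stage with feedback resistor `r6`
#' and ground-leg resistor `r5`: `Av = 1 + r6/r5`. With the stock sensor
#' values (3.3 MOhm, 10 kOhm) this evaluates to 331; lowering `r6` lowers the
#' gain and with it the tendency of the output to saturate the ADC.
#'
#' @param r6_ohm feedback resistance in Ohm, non-negative.
#' @param r5_ohm ground-leg resistance in Ohm, strictly positive.
#' @return Dimensionless voltage gain.
#' @export
#' @examples
#' amplifier_gain(3.3e6, 1e4)  # 331
amplifier_gain <- function(r6_ohm, r5_ohm) {
  if (!is.numeric(r5_ohm) || any(r5_ohm <= 0)) {
    ppg_stop("value_error", "r5_ohm must be strictly positive")
  }
  if (!is.numeric(r6_ohm) || any(r6_ohm < 0)) {
    ppg_stop("value_error", "r6_ohm must be non-negative")
  }
  1 + r6_ohm / r5_ohm
}

#' Sensor front-end configuration
#'
#' Describes the analog/digital acquisition chain of one sensor: the
#' amplification resistor pair, the ADC bit depth, a dimensionless
#' site-dependent amplitude factor (perfusion differs strongly between
#' fingertip, wrist, arm and ankle), and the fraction of full scale at which
#' soft saturation begins.
#'
#' @param r6_ohm,r5_ohm amplifier resistors in Ohm (defaults: the stock
#'   3.3 MOhm / 10 kOhm pair, gain 331).
#' @param adc_bits ADC bit depth; 10 and 23 are the depths of the two
#'   acquisition devices modeled, but any positive integer is accepted.
#' @param site_gain relative optical amplitude at the measurement site.
#' @param ceiling_knee_fraction fraction of full scale where the soft
#'   compression knee sits, in (0, 1].
#' @param label,site,device optional metadata copied onto generated signals.
#' @return A `sensor_config` list.
#' @export
sensor_config <- function(r6_ohm = 3.3e6, r5_ohm = 1e4, adc_bits = 10,
                          site_gain = 1.0, ceiling_knee_fraction = 0.95,
                          label = NULL, site = NULL, device = NULL) {
  if (site_gain < 0) ppg_stop("value_error", "site_gain must be non-negative")
  if (ceiling_knee_fraction <= 0 || ceiling_knee_fraction > 1) {
    ppg_stop("value_error", "ceiling_knee_fraction must be in (0, 1]")
  }
  amplifier_gain(r6_ohm, r5_ohm)  # validates resistors
  adc_ceiling(adc_bits)           # validates bit depth
  structure(list(r6_ohm = r6_ohm, r5_ohm = r5_ohm, adc_bits = adc_bits,
                 site_gain = site_gain,
                 ceiling_knee_fraction = ceiling_knee_fraction,
                 label = label, site = site, device = device),
            class = "sensor_config")
}

#' Relative PPG amplitude by anatomical site
#'
#' Qualitative ordering used by the generator: fingertip strongest, then toe,
#' wrist, arm, ankle weakest. The literature gives no quantitative per-site
#' pulse amplitudes, so these are fixed package defaults.
#'
#' @param site one of `"finger"`, `"toe"`, `"wrist"`, `"arm"`, `"ankle"`.
#' @return Dimensionless site gain.
#' @export
site_gain_default <- function(site = c("finger", "toe", "wrist", "arm", "ankle")) {
  site <- match.arg(site)
  c(finger = 1.5, toe = 1.3, wrist = 0.8, arm = 0.7, ankle = 0.5)[[site]]
}

#' Physiological simulation parameters
#'
#' Parameters of the quasi-periodic PPG model: mean heart rate with i.i.d.
#' Gaussian beat-to-beat jitter, a two-Gaussian pulse template (systolic lobe
#' plus delayed diastolic lobe), sinusoidal respiratory baseline wander,
#' additive white measurement noise, and optional Poisson-arriving motion
#' artifact bursts.
#'
#' @param mean_hr_bpm mean heart rate, in (20, 250) BPM.
#' @param sdnn_s standard deviation of beat-to-beat interval jitter, seconds.
#' @param systolic_amp systolic lobe amplitude (normalized physiological
#'   units; the front-end applies all gain).
#' @param diastolic_amp_fraction diastolic lobe amplitude relative to the
#'   systolic lobe, in \[0, 1).
#' @param diastolic_delay_fraction delay of the diastolic lobe center after
#'   the systolic center, as a fraction of the beat.
#' @param pulse_width_fraction Gaussian lobe width (SD) as a fraction of the
#'   beat.
#' @param resp_rate_hz,resp_amp respiratory baseline wander frequency and
#'   amplitude.
#' @param noise_sd additive white Gaussian noise SD.
#' @param artifact_rate_per_min,artifact_amp rate and amplitude of
#'   band-limited (0.5-10 Hz) motion-artifact bursts of 0.5-3 s; the default
#'   rate 0 reproduces at-rest acquisition.
#' @param duration_s recording duration in seconds.
#' @param seed integer RNG seed; identical seeds give bit-identical signals.
#' @return A `physio_params` list.
#' @export
physio_params <- function(mean_hr_bpm = 70, sdnn_s = 0.03, systolic_amp = 1,
                          diastolic_amp_fraction = 0.35,
                          diastolic_delay_fraction = 0.25,
                          pulse_width_fraction = 0.10,
                          resp_rate_hz = 0.25, resp_amp = 0.05,
                          noise_sd = 0.01, artifact_rate_per_min = 0,
                          artifact_amp = 0.5, duration_s = 120, seed = 1L) {
  if (mean_hr_bpm <= 20 || mean_hr_bpm >= 250) {
    ppg_stop("value_error", "mean_hr_bpm must lie in (20, 250)")
  }
  if (duration_s <= 0) ppg_stop("value_error", "duration_s must be positive")
  amps <- c(systolic_amp, diastolic_amp_fraction, resp_amp, noise_sd,
            artifact_amp, sdnn_s)
  if (any(amps < 0)) ppg_stop("value_error", "amplitudes must be non-negative")
  structure(list(mean_hr_bpm = mean_hr_bpm, sdnn_s = sdnn_s,
                 systolic_amp = systolic_amp,
                 diastolic_amp_fraction = diastolic_amp_fraction,
                 diastolic_delay_fraction = diastolic_delay_fraction,
                 pulse_width_fraction = pulse_width_fraction,
                 resp_rate_hz = resp_rate_hz, resp_amp = resp_amp,
                 noise_sd = noise_sd,
                 artifact_rate_per_min = artifact_rate_per_min,
                 artifact_amp = artifact_amp, duration_s = duration_s,
                 seed = as.integer(seed)),
            class = "physio_params")
}

#' Two-Gaussian pulse template
#'
#' Amplitude of one PPG beat at phase `t_frac` in \[0, 1): a systolic
#' Gaussian lobe centered at 0.25 of the beat plus a smaller diastolic lobe
#' delayed by `diastolic_delay_fraction`. The systolic lobe is the global
#' maximum whenever `diastolic_amp_fraction < 1`.
#'
#' @param t_frac beat phase, vectorized.
#' @param params a [physio_params()] list.
#' @return Template amplitude(s).
#' @export
pulse_template <- function(t_frac, params = physio_params()) {
  w <- params$pulse_width_fraction
  sys_c <- 0.25
  dia_c <- sys_c + params$diastolic_delay_fraction
  params$systolic_amp * (
    exp(-(t_frac - sys_c)^2 / (2 * w^2)) +
      params$diastolic_amp_fraction * exp(-(t_frac - dia_c)^2 / (2 * w^2)))
}

#' Generate beat-to-beat intervals
#'
#' Draws i.i.d. intervals `60/mean_hr_bpm + N(0, sdnn_s)`, truncated below at
#' 0.3 s (a physiological floor), until their sum covers `duration_s`.
#'
#' @param params a [physio_params()] list (its `seed` drives the RNG).
#' @return Numeric vector of RR intervals in seconds.
#' @export
generate_rr <- function(params = physio_params()) {
  set.seed(params$seed)
  draw_rr(params)
}

## RR draw without touching the RNG seed (callers manage the stream).
draw_rr <- function(params) {
  mean_rr <- 60 / params$mean_hr_bpm
  n_guess <- ceiling(params$duration_s / mean_rr) + 10L
  rr <- numeric(0)
  while (sum(rr) < params$duration_s) {
    rr <- c(rr, pmax(0.3, mean_rr + stats::rnorm(n_guess, 0, params$sdnn_s)))
  }
  keep <- which(cumsum(rr) >= params$duration_s)[1L]
  rr[seq_len(keep)]
}

#' Generate a clean synthetic PPG signal with ground truth
#'
#' Renders the two-Gaussian template on the beat grid of [generate_rr()],
#' adds sinusoidal respiratory wander, white noise and (if configured)
#' motion-artifact bursts. Only complete beats are rendered: the signal ends
#' at the last beat boundary at or before `duration_s` (so within one beat
#' of the requested duration), which keeps the ground truth exhaustive --
#' every rendered systolic upstroke has a corresponding truth peak. The
#' returned ground truth carries the true systolic peak times (each beat's
#' systolic lobe center) and the RR series.
#'
#' @param params a [physio_params()] list.
#' @param fs sampling rate in Hz (the acquisition model runs at 1000 Hz).
#' @return List with elements `signal` (a [ppg_signal()] in normalized
#'   physiological units, no ADC metadata) and `truth` (a `ground_truth`
#'   list: `peak_times_s`, `rr_s`, `saturated_mask`, `clip_level`).
#' @export
generate_clean <- function(params = physio_params(), fs = 1000) {
  set.seed(params$seed)
  rr <- draw_rr(params)
  ends <- cumsum(rr)
  complete <- which(ends <= params$duration_s + 1e-9)
  if (length(complete) == 0L) {
    ppg_stop("value_error", "duration_s shorter than one beat")
  }
  rr <- rr[seq_len(max(complete))]
  starts <- cumsum(c(0, rr[-length(rr)]))
  peak_times <- starts + 0.25 * rr

  n <- round(sum(rr) * fs)
  t <- (seq_len(n) - 1L) / fs
  beat <- findInterval(t, starts)
  t_frac <- (t - starts[beat]) / rr[beat]
  x <- pulse_template(t_frac, params)
  x <- x + params$resp_amp * sin(2 * pi * params$resp_rate_hz * t)
  if (params$noise_sd > 0) x <- x + stats::rnorm(n, 0, params$noise_sd)
  if (params$artifact_rate_per_min > 0 && params$artifact_amp > 0) {
    x <- x + artifact_track(n, fs, params)
  }

  keep <- peak_times < n / fs
  truth <- structure(list(peak_times_s = peak_times[keep], rr_s = rr,
                          saturated_mask = rep(FALSE, n), clip_level = NA_real_),
                     class = "ground_truth")
  list(signal = ppg_signal(x, fs = fs), truth = truth)
}

## Poisson-arriving bursts of 0.5-10 Hz band-limited noise, 0.5-3 s long.
artifact_track <- function(n, fs, params) {
  track <- numeric(n)
  n_bursts <- stats::rpois(1, params$artifact_rate_per_min * params$duration_s / 60)
  if (n_bursts == 0L) return(track)
  bf <- signal::butter(2, c(0.5, 10) / (fs / 2), type = "pass")
  for (i in seq_len(n_bursts)) {
    len <- round(stats::runif(1, 0.5, 3) * fs)
    start <- 1L + floor(stats::runif(1, 0, max(1, n - len)))
    burst <- signal::filtfilt(bf, stats::rnorm(len))
    burst <- burst / max(1e-12, stats::sd(burst)) * params$artifact_amp
    idx <- start:min(n, start + len - 1L)
    track[idx] <- track[idx] + burst[seq_along(idx)]
  }
  track
}

#' Pass a physiological signal through a sensor front-end
#'
#' Applies the amplification chain and ADC of a [sensor_config()]: the input
#' is scaled by `amplifier_gain * site_gain`, biased to mid-range
#' (`0.5 * full scale`, emulating the sensor's biased analog output), softly
#' compressed above the knee (a quadratic blend that reaches the ceiling with
#' zero slope, so saturated samples retain spread rather than collapsing to a
#' single code), hard-clipped at full scale and rounded to integer codes.
#'
#' @param signal a [ppg_signal()] in normalized physiological units.
#' @param sensor a [sensor_config()].
#' @param truth optional `ground_truth` to annotate; its `saturated_mask` is
#'   set to the samples whose pre-clip value exceeded the knee and
#'   `clip_level` to the ADC ceiling.
#' @return List with `signal` (digital [ppg_signal()], `adc_bits` set) and
#'   `truth`.
#' @export
apply_front_end <- function(signal, sensor, truth = NULL) {
  stopifnot(inherits(signal, "ppg_signal"), inherits(sensor, "sensor_config"))
  full <- adc_ceiling(sensor$adc_bits)
  gain <- amplifier_gain(sensor$r6_ohm, sensor$r5_ohm) * sensor$site_gain
  v <- gain * signal$samples + 0.5 * full

  knee <- sensor$ceiling_knee_fraction * full
  mask <- v > knee
  span <- 2 * (full - knee)
  if (span > 0) {
    over <- v > knee & v < knee + span
    v[over] <- v[over] - (v[over] - knee)^2 / (2 * span)
    v[v >= knee + span] <- full
  }
  v <- pmin(pmax(round(v), 0), full)

  out <- ppg_signal(v, fs = signal$fs, adc_bits = sensor$adc_bits,
                    sensor_label = sensor$label, site = sensor$site,
                    device = sensor$device, t0 = signal$t0)
  if (!is.null(truth)) {
    truth$saturated_mask <- mask
    truth$clip_level <- full
  }
  list(signal = out, truth = truth)
}

## Rectangular optical sync pulse as seen by a device's ADC.
sync_channel <- function(n, fs, adc_bits, t_pulse_s = 1.0, width_s = 0.1) {
  full <- adc_ceiling(adc_bits)
  x <- rep(0, n)
  i0 <- 1L + round(t_pulse_s * fs)
  i1 <- min(n, i0 + round(width_s * fs) - 1L)
  if (i0 <= n) x[i0:i1] <- 0.5 * full
  ppg_signal(x, fs = fs, adc_bits = adc_bits, sensor_label = "sync")
}

#' Simulate a two-device acquisition with a shared sync pulse
#'
#' One physiological signal is rendered through two sensor front-ends; the
#' second device's stream (PPG and aux channel alike) is delayed by
#' `offset_samples`, emulating unsynchronized acquisition clocks. Both
#' devices record a 100 ms rectangular optical pulse emitted at a shared
#' physiological instant, so [align_recordings()] can recover the injected
#' offset exactly.
#'
#' @param params a [physio_params()] list.
#' @param sensor_a,sensor_b [sensor_config()] objects for the two devices.
#' @param offset_samples signed integer clock offset applied to device B.
#' @param fs sampling rate in Hz.
#' @param seed optional seed overriding `params$seed`.
#' @param t_sync_s time of the shared optical pulse, seconds.
#' @return List with `a`, `b` ([ppg_recording()]s, one `ppg` channel plus
#'   `aux_sync` each), per-device ground truths `truth_a`, `truth_b`, and the
#'   injected `offset_samples`.
#' @export
generate_dual_device <- function(params = physio_params(), sensor_a, sensor_b,
                                 offset_samples = 0L, fs = 1000, seed = NULL,
                                 t_sync_s = 1.0) {
  if (!is.null(seed)) params$seed <- as.integer(seed)
  clean <- generate_clean(params, fs)
  n <- length(clean$signal$samples)

  fe_a <- apply_front_end(clean$signal, sensor_a, clean$truth)
  fe_b <- apply_front_end(clean$signal, sensor_b, clean$truth)
  rec_a <- ppg_recording(signals = list(ppg = fe_a$signal),
                         aux_sync = sync_channel(n, fs, sensor_a$adc_bits, t_sync_s))
  rec_b <- ppg_recording(signals = list(ppg = fe_b$signal),
                         aux_sync = sync_channel(n, fs, sensor_b$adc_bits, t_sync_s))
  truth_a <- fe_a$truth
  truth_b <- fe_b$truth

  k <- as.integer(offset_samples)
  if (k != 0L) {
    # delay device B by k samples (negative k advances it)
    rec_b <- shift_recording(rec_b, -k)
    truth_b$peak_times_s <- truth_b$peak_times_s + k / fs
    truth_b$peak_times_s <-
      truth_b$peak_times_s[truth_b$peak_times_s >= 0 &
                             truth_b$peak_times_s < n / fs]
    m <- truth_b$saturated_mask
    truth_b$saturated_mask <- if (k > 0) {
      c(rep(m[1L], k), m)[seq_len(n)]
    } else {
      c(m[(-k + 1L):n], rep(m[n], -k))
    }
  }
  list(a = rec_a, b = rec_b, truth_a = truth_a, truth_b = truth_b,
       offset_samples = k)
}
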