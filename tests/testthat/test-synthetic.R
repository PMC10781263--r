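test_that("amplifier gain follows the non-inverting closed-loop formula", {
  expect_equal(amplifier_gain(3.3e6, 1e4), 331)
  expect_equal(amplifier_gain(0, 1e4), 1)
  expect_equal(amplifier_gain(1e6, 1e4), 101)
  expect_equal(amplifier_gain(1e7, 1e4), 1001)
  expect_error(amplifier_gain(1e6, 0), class = "value_error")
  expect_error(amplifier_gain(1e6, -5), class = "value_error")
})

test_that("ADC ceiling codes match the bit depths of the two devices", {
  expect_equal(adc_ceiling(10), 1023)
  expect_equal(adc_ceiling(23), 8388607)
  expect_error(adc_ceiling(0), class = "value_error")
})

test_that("pulse template peaks at the systolic center", {
  p0 <- physio_params(diastolic_amp_fraction = 0)
  expect_equal(pulse_template(0.25, p0), p0$systolic_amp)

  # Gaussian tail: negligible far from both lobes
  p <- physio_params()
  far <- 0.25 + p$diastolic_delay_fraction + 6 * p$pulse_width_fraction
  expect_lt(pulse_template(far, p), 1e-5 * p$systolic_amp)

  # brute-force grid search: global max at the systolic center
  grid <- seq(0, 0.999, by = 0.005)
  amax <- grid[which.max(pulse_template(grid, p))]
  expect_lt(abs(amax - 0.25), 0.005 + 1e-12)
})

test_that("beat intervals have the configured mean and spread", {
  expect_equal(unique(generate_rr(physio_params(mean_hr_bpm = 60, sdnn_s = 0))),
               1.0)
  expect_equal(unique(generate_rr(physio_params(mean_hr_bpm = 75, sdnn_s = 0))),
               0.8)

  # law of large numbers: sample SD of ~10000 intervals near sdnn_s
  rr <- generate_rr(physio_params(mean_hr_bpm = 60, sdnn_s = 0.05,
                                  duration_s = 10000, seed = 21))
  expect_gte(length(rr), 9900)
  expect_gt(sd(rr), 0.045)
  expect_lt(sd(rr), 0.055)
  expect_true(all(rr >= 0.3))
})

test_that("clean generation yields a regular beat grid with exhaustive truth", {
  p <- physio_params(mean_hr_bpm = 60, sdnn_s = 0, resp_amp = 0, noise_sd = 0,
                     duration_s = 120, seed = 6)
  g <- generate_clean(p)
  expect_equal(length(g$truth$peak_times_s), 120)
  expect_equal(unique(round(diff(g$truth$peak_times_s), 9)), 1.0)

  # identical peak heights at the truth instants
  idx <- round(g$truth$peak_times_s * 1000) + 1
  expect_lt(diff(range(g$signal$samples[idx])), 1e-9)

  # brute-force local maxima of a noise-free rendering lie within 10 ms of truth
  p2 <- physio_params(noise_sd = 0, duration_s = 20, seed = 7)
  g2 <- generate_clean(p2)
  x <- g2$signal$samples
  for (tp in g2$truth$peak_times_s) {
    i <- round(tp * 1000) + 1
    lo <- max(1, i - 100); hi <- min(length(x), i + 100)
    j <- lo + which.max(x[lo:hi]) - 1
    expect_lte(abs(j - i), 10)
  }
})

test_that("front end applies gain, offset, soft knee and hard clip", {
  fs <- 1000
  # input that never reaches the knee: exact affine + rounding, no saturation
  s <- sensor_config(r6_ohm = 1e6, adc_bits = 10, site_gain = 1)
  x <- ppg_signal(seq(0, 0.5, length.out = 100), fs)
  fe <- apply_front_end(x, s, structure(list(saturated_mask = NULL),
                                        class = "ground_truth"))
  expect_equal(fe$signal$samples, round(101 * x$samples + 511.5))
  expect_false(any(fe$truth$saturated_mask))

  # constant drive far above the ceiling: hard clip, fully saturated
  big <- ppg_signal(rep(100, 50), fs)
  fe2 <- apply_front_end(big, s, structure(list(), class = "ground_truth"))
  expect_true(all(fe2$signal$samples == 1023))
  expect_true(all(fe2$truth$saturated_mask))
  expect_equal(fe2$truth$clip_level, 1023)

  # sinusoid driven into the knee: saturated-sample values keep spread,
  # with the minimum well below the mean (saturation is gradual)
  t <- (0:9999) / fs
  drive <- ppg_signal(3 + 3 * sin(2 * pi * 1.2 * t), fs)
  s2 <- sensor_config(r6_ohm = 3.3e6, adc_bits = 10, site_gain = 1)
  fe3 <- apply_front_end(drive, s2, structure(list(), class = "ground_truth"))
  sat_vals <- fe3$signal$samples[fe3$truth$saturated_mask]
  expect_gt(length(sat_vals), 100)
  expect_lt(min(sat_vals), mean(sat_vals))
  expect_gt(sd(sat_vals), 0)
})

test_that("quantized outputs always respect the ADC range", {
  for (bits in c(10, 23)) {
    s <- sensor_config(r6_ohm = 3.3e6, adc_bits = bits,
                       site_gain = site_gain_default("finger"))
    g <- generate_clean(physio_params(duration_s = 10, seed = 8))
    out <- apply_front_end(g$signal, s)$signal
    expect_true(all(out$samples >= 0))
    expect_true(all(out$samples <= adc_ceiling(bits)))
    expect_equal(out$samples, round(out$samples))
  }
})

test_that("raising the feedback resistor never decreases the saturated fraction", {
  clean <- generate_clean(physio_params(duration_s = 20, seed = 9))
  fracs <- vapply(c(5e5, 1e6, 2e6, 3.3e6, 5e6, 1e7), function(r6) {
    s <- sensor_config(r6_ohm = r6, adc_bits = 10,
                       site_gain = site_gain_default("finger"))
    mean(apply_front_end(clean$signal, s, clean$truth)$truth$saturated_mask)
  }, numeric(1))
  expect_true(all(diff(fracs) >= 0))
  expect_gt(fracs[length(fracs)], 0)
})

test_that("dual-device generation is deterministic and shares its physiology", {
  p <- physio_params(duration_s = 8, seed = 10)
  sa <- sensor_config(r6_ohm = 1e6)
  sb <- sensor_config(r6_ohm = 3.3e6)

  sim1 <- generate_dual_device(p, sa, sb, offset_samples = 0L)
  sim2 <- generate_dual_device(p, sa, sb, offset_samples = 0L)
  expect_identical(sim1$a$signals$ppg$samples, sim2$a$signals$ppg$samples)
  expect_identical(sim1$b$signals$ppg$samples, sim2$b$signals$ppg$samples)

  # zero offset: sync edges coincide
  expect_equal(detect_sync_pulse(sim1$a$aux_sync),
               detect_sync_pulse(sim1$b$aux_sync))
  # both devices see the same beat grid
  expect_equal(sim1$truth_a$peak_times_s, sim1$truth_b$peak_times_s)
})

test_that("site gains order fingertip strongest, ankle weakest", {
  g <- vapply(c("finger", "toe", "wrist", "arm", "ankle"), site_gain_default,
              numeric(1))
  expect_true(all(diff(g) < 0))
})
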