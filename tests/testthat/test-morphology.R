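test_that("min-max normalization maps onto [0, 1] and is affine-invariant", {
  expect_equal(minmax_normalize(c(2, 4, 6)), c(0, 0.5, 1))
  x <- c(0.3, 1.7, 0.9, 2.4)
  expect_equal(minmax_normalize(3.2 * x + 11), minmax_normalize(x))
  expect_error(minmax_normalize(rep(4, 10)), class = "degenerate_pulse_error")
})

test_that("Pearson correlation matches its closed forms and stats::cor", {
  x <- c(1, 2, 3, 4)
  expect_equal(pcc(x, 2 * x + 3), 1.0)
  expect_equal(pcc(x, -x), -1.0)
  expect_equal(pcc(x, c(1, 2, 4, 3)), 0.8)
  # independent route: base R product-moment correlation
  set.seed(61)
  a <- rnorm(50); b <- rnorm(50)
  expect_equal(pcc(a, b), stats::cor(a, b))
  expect_error(pcc(x, rep(2, 4)), class = "undefined_error")
  expect_error(pcc(x, c(1, 2)), class = "value_error")
})

test_that("cosine similarity matches its closed forms", {
  x <- c(0.4, 1.1, 2.2)
  expect_equal(cosine_similarity(x, x), 1.0)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0.0)
  expect_equal(cosine_similarity(c(1, 0), c(1, 1)), 1 / sqrt(2))
  expect_equal(cosine_similarity(c(1, 0), c(1, 1)), 0.70711, tolerance = 1e-5)
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), class = "undefined_error")
})

test_that("normalized Euclidean distance is a plain root sum of squares", {
  expect_equal(ned(c(0, 0.5, 1), c(0, 0.5, 1)), 0)
  expect_equal(ned(c(0, 1), c(1, 0)), sqrt(2))
  expect_equal(ned(c(0, 1), c(1, 0)), 1.41421, tolerance = 1e-5)
  expect_equal(ned(c(0, 0.5, 1), c(0, 0, 1)), 0.5)
  expect_error(ned(c(0, 1), c(0, 0.5, 1)), class = "value_error")
  # grows as sqrt(n) under repetition upsampling
  a <- c(0, 0.2, 0.7, 1); b <- c(0, 0.3, 0.5, 1)
  expect_equal(ned(rep(a, 4), rep(b, 4)), 2 * ned(a, b))
})

test_that("lag alignment recovers injected shifts", {
  fs <- 1000
  t <- (0:1999) / fs
  x <- exp(-(t - 1)^2 / (2 * 0.1^2))
  y <- exp(-(t - 1.03)^2 / (2 * 0.1^2))  # 30 ms later
  al <- align_lag(x, y, fs)
  expect_equal(abs(al$lag_s), 0.030, tolerance = 1e-3)
  expect_equal(length(al$x), length(al$y))

  al0 <- align_lag(x, x, fs)
  expect_equal(al0$lag_s, 0)
  expect_equal(al0$x, al0$y)
})

test_that("pulse extraction partitions the trace between onsets", {
  fs <- 1000
  p <- physio_params(mean_hr_bpm = 60, duration_s = 20, seed = 62)
  g <- generate_clean(p)
  f <- bandpass(g$signal)
  pk <- elgendi_peaks(f, fs)
  on <- find_onsets(f, pk)

  # beat length tracks the generated RR interval (onset jitter excepted)
  pulse <- extract_pulse(f, pk, 5, on)
  expect_equal(length(pulse), round(1000 * g$truth$rr_s[5]), tolerance = 0.1)

  # identical noise-free beats: pulse length is the beat period exactly
  g0 <- generate_clean(physio_params(mean_hr_bpm = 60, sdnn_s = 0,
                                     resp_amp = 0, noise_sd = 0,
                                     duration_s = 8, seed = 62))
  f0 <- bandpass(g0$signal)
  pk0 <- elgendi_peaks(f0, fs)
  on0 <- find_onsets(f0, pk0)
  expect_equal(length(extract_pulse(f0, pk0, 3, on0)), 1000)

  # concatenating all pulses reproduces the span between first and last onset
  pulses <- lapply(seq_len(length(on) - 1), function(b)
    extract_pulse(f, pk, b, on))
  expect_equal(unlist(pulses), f[on[1]:(on[length(on)] - 1)])

  expect_error(extract_pulse(f, pk, 0, on), class = "index_error")
  expect_error(extract_pulse(f, pk, length(on), on), class = "index_error")
})

test_that("the pulse-pair pipeline scores identity and gain pairs correctly", {
  fs <- 1000
  g <- generate_clean(physio_params(duration_s = 30, seed = 18))
  fA <- bandpass(apply_front_end(g$signal, sensor_config(r6_ohm = 1e6))$signal)
  fB <- bandpass(apply_front_end(g$signal, sensor_config(r6_ohm = 2e6))$signal)
  pkA <- elgendi_peaks(fA, fs)
  pkB <- elgendi_peaks(fB, fs)

  self <- compare_pulses(fA, pkA, fA, pkA, fs)
  expect_equal(self$pcc, 1.0)
  expect_equal(self$cs, 1.0)
  expect_equal(self$ned, 0.0)

  pair <- compare_pulses(fA, pkA, fB, pkB, fs)
  expect_gt(pair$pcc, 0.99)
  expect_gt(pair$cs, 0.99)

  # clipping one channel's systolic lobes degrades the correlation
  xc <- pmin(g$signal$samples,
             min(g$signal$samples) + 0.6 * diff(range(g$signal$samples)))
  fC <- bandpass(apply_front_end(ppg_signal(xc, fs),
                                 sensor_config(r6_ohm = 2e6))$signal)
  pkC <- elgendi_peaks(fC, fs)
  clipped <- compare_pulses(fA, pkA, fC, pkC, fs,
                            beat_index = pair$beat_index)
  expect_lt(clipped$pcc, pair$pcc)
})

test_that("similarity metrics are symmetric in their arguments", {
  set.seed(63)
  a <- runif(80); b <- runif(80)
  expect_equal(pcc(a, b), pcc(b, a))
  expect_equal(cosine_similarity(a, b), cosine_similarity(b, a))
  expect_equal(ned(a, b), ned(b, a))
})
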