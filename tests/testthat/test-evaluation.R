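mk_peaks <- function(times_s, fs = 1000, provenance = "ground_truth") {
  peak_set(round(times_s * fs) + 1L, fs, provenance)
}

test_that("peak matching follows the one-to-one 50 ms rule", {
  truth <- mk_peaks(c(1.0, 2.0, 3.0))
  det <- mk_peaks(c(1.02, 2.06, 2.99), provenance = "automatic")
  m <- match_peaks(truth, det)
  expect_equal(m$tp, 2)
  expect_equal(m$fn, 1)
  expect_equal(m$fp, 1)
  expect_equal(m$sensitivity, 2 / 3, tolerance = 1e-12)
  expect_equal(m$precision, 2 / 3, tolerance = 1e-12)

  ident <- match_peaks(truth, truth)
  expect_equal(ident$sensitivity, 1)
  expect_equal(ident$precision, 1)

  # boundary inclusive: exactly 50 ms counts
  m50 <- match_peaks(mk_peaks(1.0), mk_peaks(1.05))
  expect_equal(m50$tp, 1)

  # nothing detected: sensitivity 0, precision flagged undefined
  none <- match_peaks(truth, mk_peaks(numeric(0)))
  expect_equal(none$sensitivity, 0)
  expect_false(none$precision_defined)
  expect_true(is.na(none$precision))
  expect_equal(none$fp, 0)
})

test_that("matching conserves counts and is monotone in tolerance", {
  set.seed(71)
  for (i in 1:25) {
    tt <- sort(runif(sample(0:20, 1), 0, 30))
    td <- sort(runif(sample(0:20, 1), 0, 30))
    tt <- tt[c(TRUE, diff(tt) > 1e-3)]
    td <- td[c(TRUE, diff(td) > 1e-3)]
    m <- match_peaks(mk_peaks(tt), mk_peaks(td))
    expect_equal(m$tp + m$fn, length(tt))
    expect_equal(m$tp + m$fp, length(td))

    # swapping truth and detected swaps fn and fp
    sw <- match_peaks(mk_peaks(td), mk_peaks(tt))
    expect_equal(sw$tp, m$tp)
    expect_equal(sw$fn, m$fp)
    expect_equal(sw$fp, m$fn)

    # sensitivity never decreases as the tolerance grows
    tols <- c(0.01, 0.05, 0.2, 1)
    if (length(tt) && length(td)) {
      sens <- vapply(tols, function(tol)
        match_peaks(mk_peaks(tt), mk_peaks(td), tol)$sensitivity, numeric(1))
      expect_true(all(diff(sens) >= -1e-12))
    }
  }
})

test_that("instantaneous heart rate follows the interval arithmetic", {
  r1 <- hr_from_peaks(mk_peaks(seq(0, 10, by = 1)))
  expect_true(all(r1$hr_series_bpm == 60))
  expect_equal(r1$mean_hr_bpm, 60)
  expect_equal(r1$sd_hr_bpm, 0)

  expect_equal(hr_from_peaks(mk_peaks(seq(0, 8, by = 0.8)))$mean_hr_bpm, 75)

  r3 <- hr_from_peaks(mk_peaks(c(0, 1.0, 1.5)))
  expect_equal(r3$hr_series_bpm, c(60, 120))
  expect_equal(r3$mean_hr_bpm, 90)

  expect_error(hr_from_peaks(mk_peaks(1)), class = "insufficient_peaks_error")
})

test_that("heart-rate error is the absolute difference and relative percent", {
  mk_hr <- function(m) structure(list(mean_hr_bpm = m), class = "hr_report")
  e <- hr_error(mk_hr(63), mk_hr(60))
  expect_equal(e$mean_hr_diff_bpm, 3)
  expect_equal(e$percent_error, 5.0)

  expect_equal(hr_error(mk_hr(60), mk_hr(60))$percent_error, 0)
  expect_equal(hr_error(mk_hr(66), mk_hr(60))$percent_error, 10.0)
  expect_equal(hr_error(mk_hr(57), mk_hr(60))$mean_hr_diff_bpm, 3)
  expect_error(hr_error(mk_hr(60), mk_hr(0)), class = "undefined_error")
})

test_that("Poincare descriptors match their closed forms", {
  const <- poincare(mk_peaks(seq(0, 10, by = 1)))
  expect_equal(const$sd1_ms, 0)
  expect_equal(const$sd2_ms, 0)

  # alternating intervals a, b: sd1 = |a - b| / sqrt(2) (population SD;
  # one extra leading interval balances the successive-difference signs)
  a <- 0.8; b <- 1.0
  times <- cumsum(c(0, rep(c(a, b), 10), a))
  alt <- poincare(mk_peaks(times))
  expect_equal(alt$sd1_ms, 1000 * abs(a - b) / sqrt(2), tolerance = 1e-6)

  # i.i.d. jitter: sd1 approaches the generated sdnn
  rr <- generate_rr(physio_params(mean_hr_bpm = 60, sdnn_s = 0.05,
                                  duration_s = 5000, seed = 72))
  iid <- poincare(mk_peaks(cumsum(c(0, rr))))
  expect_gt(iid$sd1_ms, 45)
  expect_lt(iid$sd1_ms, 55)

  expect_error(poincare(mk_peaks(c(0, 1))), class = "insufficient_peaks_error")
})

test_that("the benchmark table reflects channel quality differences", {
  expect_equal(nrow(benchmark_report(list(), list())), 0)

  fs <- 1000
  g <- generate_clean(physio_params(duration_s = 30, seed = 73))
  clean_ch <- apply_front_end(g$signal, sensor_config(r6_ohm = 1e6,
                                                      site_gain = 1.5))$signal
  tr <- truth_peaks(g$truth, fs)

  # a clean channel benchmarked against itself
  rep1 <- benchmark_report(list(ch = clean_ch), list(ch = tr),
                           profiles = list(ch = max(clean_ch$samples) + 1))
  expect_equal(nrow(rep1), 1)
  expect_equal(rep1$pct_saturated, 0)
  expect_equal(rep1$sensitivity, 1)
  expect_equal(rep1$precision, 1)
  expect_equal(rep1$pcc, 1)
  expect_lt(rep1$hr_diff_bpm, 0.05)

  # clipped twin: lower sensitivity, higher HR error
  xc <- pmin(g$signal$samples,
             min(g$signal$samples) + 0.5 * diff(range(g$signal$samples)))
  clip_ch <- apply_front_end(ppg_signal(xc, fs),
                             sensor_config(r6_ohm = 1e6, site_gain = 1.5))$signal
  rep2 <- benchmark_report(list(clean = clean_ch, clipped = clip_ch),
                           list(clean = tr, clipped = tr),
                           reference = "clean")
  expect_equal(nrow(rep2), 2)
  expect_lt(rep2$sensitivity[2], rep2$sensitivity[1])
  expect_gt(rep2$pct_error[2], rep2$pct_error[1])
})
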