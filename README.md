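# ppgbench

Benchmarking photoplethysmography (PPG) acquisition front-ends against
known ground truth.

PPG sensors measure blood-volume pulses optically. How well a given sensor
records them depends on its analog chain: the transimpedance amplifier's
gain (`Av = 1 + R6/R5`) determines whether the pulse saturates the ADC, the
measurement site (fingertip, wrist, arm, ankle) scales the optical
amplitude, and the ADC's bit depth fixes the representable range
`[0, 2^bits − 1]`. `ppgbench` implements the full evaluation chain used to
compare such front-ends, together with a synthetic signal generator that
provides the ground truth real recordings lack:

- **Saturation calibration** — from a forced-saturation recording, the
  threshold is set to `μ − 1σ` of the samples above a manual cut
  (saturation is gradual, so the statistics matter); signals are then
  scored as percent of samples at or above the threshold.
- **Signal quality** — spectral entropy
  `SE = −Σ p(f) log₂ p(f) / log₂ N` of the normalized 1–3 Hz power
  distribution in consecutive 4 s windows. Periodic (good) signals score
  low; a mean above 0.8 flags poor quality.
- **Systolic peak detection** — a zero-phase 4th-order Butterworth
  band-pass (1–8 Hz) followed by the two-event-related-moving-average
  detector (peak window 0.18 s, beat window 0.69 s, offset 0.01).
- **Pulse morphology** — onset-to-onset pulse pairs are min–max
  normalized, lag-aligned, and compared by Pearson correlation, cosine
  similarity and the (unscaled) Euclidean distance of the normalized
  pulses.
- **Evaluation** — detected peaks are matched one-to-one to annotated
  peaks within ±50 ms to give sensitivity and precision; heart rate is
  `60 / IBI` with absolute and percent error against ground truth, plus
  Poincaré SD1/SD2 variability descriptors.
- **Synthetic acquisition** — a two-Gaussian pulse model on a jittered
  beat grid, rendered through a configurable front-end (gain, site factor,
  mid-range bias, soft-knee-then-hard ADC saturation, quantization), with
  a two-device setup synchronized by a shared optical pulse.

## Worked example

Two fingertip sensors on separate devices share one simulated physiology:
channel A with a lowered feedback resistor (1 MΩ, gain 101) and channel B
with the stock 3.3 MΩ (gain 331), both on 10-bit ADCs, with a 137-sample
clock offset between devices:

```r
library(ppgbench)
res <- run_scenario(default_scenario(seed = 1, duration_s = 60))
print(res$report, digits = 3)
#>   sensor segment pct_saturated mean_se pcc cs   ned sensitivity precision
#> 1      A at_rest           0.0   0.471   1  1 0.000           1         1
#> 2      B at_rest          11.9   0.466   1  1 0.136           1         1
#>   hr_diff_bpm pct_error
#> 1      0.0133    0.0190
#> 2      0.0131    0.0188
res$sync
#> <sync_result> offset +137 samples (edges 1.000 s / 1.137 s)
res$profiles$B
#> <saturation_profile> final threshold 943.836 (mean 996.903 - sd 53.067, n = 7999 above 818.400)
```

The optical sync pulse recovers the injected 137-sample offset exactly. The
stock-gain channel B saturates on 11.9% of its samples (its μ−1σ threshold,
943.8 ADC counts, was calibrated from a simulated LED-drive sweep), while
the lowered gain eliminates saturation — the effect the gain modification
is designed to achieve. Both channels still detect every systolic peak here;
`mean_se` well below 0.8 marks both signals as good quality.

Detection and heart rate against generator ground truth:

```r
g  <- generate_clean(physio_params(duration_s = 30, seed = 2))
pk <- elgendi_peaks(bandpass(g$signal), 1000)
match_peaks(truth_peaks(g$truth, 1000), pk)
#> <match_result> tp 34, fp 0, fn 0 | sensitivity 1.000, precision 1.000 (tol 50 ms)
p <- poincare(pk)
sprintf("mean HR %.1f BPM | SD1 %.1f ms SD2 %.1f ms",
        hr_from_peaks(pk)$mean_hr_bpm, p$sd1_ms, p$sd2_ms)
#> "mean HR 69.4 BPM | SD1 23.6 ms SD2 23.0 ms"
```

SD1 ≈ the generated beat-to-beat jitter (30 ms i.i.d.), as expected for
uncorrelated interval noise.

See `vignettes/ppg-benchmarking.Rmd` for the model details, parameter
choices, and known limitations (including the heart-rate range over which
the fixed-window detector is reliable).

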