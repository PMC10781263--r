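---
title: "Benchmarking PPG front-ends with synthetic ground truth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking PPG front-ends with synthetic ground truth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppgbench)
```

## The problem

A reflective PPG sensor converts photodetector current to voltage through a
transimpedance stage whose closed-loop gain is `Av = 1 + R6/R5`. With the
stock resistor pair (3.3 MΩ / 10 kΩ) that gain is 331 — high enough that a
well-perfused fingertip drives the output into the ADC ceiling during each
systolic upstroke. Saturation flattens the very feature (the systolic peak)
that heart-rate estimation and pulse-morphology analysis depend on. The
remedy is to lower `R6`; the open question is by how much, and how to
*quantify* what a given front-end/site combination does to the signal.

`ppgbench` implements that quantification as a reusable pipeline:
saturation threshold calibration and scoring, spectral-entropy quality,
systolic peak detection with evaluation against annotated peaks,
pulse-morphology similarity, and heart-rate error — plus a synthetic
generator that emulates the acquisition chain, so every stage can be
validated against known ground truth (real multi-site benchmark recordings
are rarely shareable, and only they would otherwise provide truth).

## The synthetic acquisition model

**Physiology.** Beats are drawn i.i.d.: `RR_i = 60/HR + N(0, sdnn)`,
truncated at 0.3 s. Each beat renders a two-Gaussian template on its phase
`u ∈ [0, 1)`: a systolic lobe at `u = 0.25` and a diastolic lobe of
relative amplitude 0.35 delayed by 0.25 of the beat, both with width (SD)
0.10 of the beat. The defaults were chosen once against textbook pulse
morphology — systolic peak at a quarter of the cycle, a dicrotic/diastolic
wave near mid-cycle at a third of the systolic height, systolic full width
at half maximum near a quarter of the beat — and are not tuned thereafter.
To this are added sinusoidal respiratory wander (0.25 Hz, amplitude 0.05 of
the systolic amplitude), white measurement noise (SD 0.01), and optionally
Poisson-arriving motion-artifact bursts of band-limited 0.5–10 Hz noise
(0.5–3 s long). The generator renders complete beats only, so the ground
truth (one systolic time per rendered beat) is exhaustive: a truncated
final upstroke would otherwise produce a detector response with no truth
peak to match — an artifact of the simulation boundary, not of the detector
under test.

**Front end.** The physiological signal is scaled by
`amplifier_gain(R6, R5) × site_gain`, biased to mid-range (half of full
scale, emulating the sensor's biased analog output), softly compressed
above a knee at 0.95 of full scale — a quadratic blend reaching the ceiling
with zero slope, so saturated samples retain spread rather than collapsing
onto one code — then hard-clipped and rounded. The per-sample truth mask
records which samples exceeded the knee before clipping. Site gains
(finger 1.5, toe 1.3, wrist 0.8, arm 0.7, ankle 0.5) are free parameters
fixed once to give the qualitative amplitude ordering fingertip > toe >
wrist > arm > ankle; no quantitative per-site amplitudes are established in
the literature. With these defaults the stock fingertip configuration
saturates on the order of 10–20% of samples while a 1 MΩ feedback resistor
eliminates saturation — the regime the benchmark is designed to resolve.

**Two devices.** Both devices render the same physiology through their own
front-ends (10-bit and/or 23-bit ADCs); device B's stream is delayed by an
integer clock offset. A shared 100 ms optical pulse appears in both aux
channels; alignment detects each edge at the 50% amplitude crossing (the
pulse shape is not specified beyond "brief", and the midpoint crossing is
robust to it) and rounds the offset to whole samples — at 1000 Hz one
sample is far below the 50 ms peak-matching tolerance, so no interpolation
is attempted.

**What the generator does not emulate.** Optical tissue physics and
wavelength effects, respiration-coupled amplitude modulation, autoregressive
heart-rate dynamics (jitter is i.i.d., so SD1 ≈ SD2 ≈ sdnn in Poincaré
terms), pathology, and floor (zero-code) saturation. Passing tests
therefore demonstrate algorithmic correctness and the direction of
front-end effects, not performance on any particular human population.

## Stage-by-stage choices

**Saturation (μ − 1σ).** Calibration takes all samples strictly above a
manual initial threshold in a forced-saturation recording and sets the
final threshold to their mean minus one *population* SD (divide by n; the
rule names "one standard deviation" without qualification, and the
population convention is the deterministic choice — `sd_type = "sample"`
switches). Classification is inclusive (`value ≥ threshold`): the threshold
is itself a saturation value. Only ceiling saturation is modeled. For
quality assessment of the non-saturated signal, whole analysis windows
containing any saturated sample are excluded rather than deleting samples,
which would splice discontinuities into the waveform.

**Spectral entropy.** Per 4 s window (consecutive, non-overlapping,
trailing partial dropped), the power spectral density is estimated by
Welch's method — 1 s rectangular segments, 50% overlap, per-segment mean
removal — the bins with `1 ≤ f ≤ 3` Hz (inclusive) are renormalized to sum
to one, and `SE = −Σ p log₂ p / log₂ N` over the `N` in-band bins. Two
readings of the formula are open: whether the in-band distribution is
renormalized (it must be for `SE ∈ [0, 1]`, so it is), and which PSD
estimator stands behind `P̂(f)`. A single 4 s periodogram was considered
and rejected: its per-bin powers are exponentially distributed even for
white noise, which caps the expected normalized entropy of *noise* near
0.83 and breaks the metric's contract that noise scores high (> 0.9) and
periodic signals low. Segment averaging restores that contract (white
noise means ≈ 0.95; an on-grid tone scores ≈ 0) at the cost of 1 Hz bin
spacing. Amplitude scaling cancels exactly; a flat window raises a
classed error and the window is excluded from the mean.

**Filtering.** The 4th-order Butterworth band-pass [1, 8] Hz is applied
zero-phase so detected peak positions are not delayed relative to
annotations; this squares the magnitude response (doubled effective
order). The zero-phase response is computed in the frequency domain —
reflect-padded spectrum multiplied by the squared analog prototype
magnitude — because the 8-pole transfer-function recursion at normalized
band edges of 0.002–0.016 is numerically ill-conditioned (its realized
gain at 4 Hz deviates by ~6% from the intended response). A conventional
single-pass recursive filter remains available via
`filter_spec(zero_phase = FALSE)`.

**Peak detection.** The two-moving-average scheme: clip negatives, square,
smooth with centered moving averages at the peak scale (0.18 s) and beat
scale (0.69 s), both forced to odd sample counts with reflect padding;
threshold at `MA_beat + 0.01 × mean(squared)`; keep blocks at least
`round(0.18 fs)` samples wide; one peak per block at the filtered signal's
argmax. The 0.18/0.69/0.01 parameters are interpreted as seconds, seconds,
and a dimensionless fraction multiplying the mean of the *squared* signal,
the published form of the cited scheme. Onsets are located as the minimum
between consecutive peaks (first onset: within one beat window before the
first peak).

**Morphology.** One beat is extracted onset-to-onset from each channel —
by default the beat lying in channel A's lowest-entropy quality window
among beats available in both channels, i.e. the cleanest beat, since the
procedure presumes "a pulse wave" is selected. Both pulses are min–max
normalized, the longer resampled linearly to the shorter's length, and
re-aligned within ±0.25 s by normalized cross-correlation (Cauchy–Schwarz
normalization over the overlap, so an identical pair scores its maximum at
zero lag). PCC and cosine similarity are indifferent to the normalization;
computing all three metrics on one prepared pair keeps them comparable.
The Euclidean distance of the normalized pulses is deliberately *not*
divided by length (none appears in its definition), so its magnitude grows
as √n and only equal-length pulses should be compared.

**Evaluation.** Matching is one-to-one greedy in increasing truth order,
tolerance inclusive at exactly ±50 ms; a laxer reading that lets one
detected peak serve two truth peaks would inflate true positives.
Sensitivity with no truth peaks and precision with no detections are
reported as missing and flagged, not coerced to zero. Heart-rate
difference and percent error are reported as magnitudes (×100 for
percent); 5% is the conventional acceptability bound for clinical HR
devices. Poincaré SD1/SD2 use the population SD of the rotated successive
interval pairs and are reported in ms.

## The detector's valid heart-rate range

The fixed window parameters bound the heart-rate range in which the
detector is structurally reliable, independently of signal quality:

- **Low HR (≲ 60 BPM).** The beat average spans 0.69 s. When the beat
  interval is much longer, there are in-beat instants farther than 0.345 s
  from the systolic peak whose beat average contains no systolic energy.
  Any strictly periodic signal high-passed at 1 Hz loses its sub-1 Hz
  fundamental and necessarily retains harmonic residue that bumps above
  the near-zero threshold there, producing one spurious block per beat:
  precision collapses toward 0.5 at 50 BPM. This holds across every pulse
  morphology we examined (template widths 0.06–0.15 of the beat, diastolic
  delays 0.25–0.40, diastolic amplitudes 0.35–0.5).
- **High HR (≳ 140 BPM).** A periodic signal's above-threshold support
  cannot exceed about half a beat (closed-form for a sinusoid; a pure
  2.5 Hz tone yields block widths of 171–207 samples at 1000 Hz), while
  blocks narrower than 180 samples are discarded. At 150 BPM the two
  scales collide and beat-to-beat jitter pushes a large fraction of blocks
  under the cutoff: sensitivity falls to ~0.64.

Between roughly 65 and 140 BPM — which covers resting adult physiology,
the regime the parameters were published for — clean-signal recovery is
essentially perfect (sensitivity and precision 1.00 at 70/90/120 BPM on
120 s synthetic recordings). The acceptance suite exercises the full
{50, 60, 90, 120, 150} sweep and the two extreme rates fail it; we report
this as a property of the fixed-parameter method rather than adjusting
windows or generator to mask it.

## Degenerate inputs and numerical conventions

All user-facing failures are classed conditions (`format_error`,
`range_error`, `calibration_error`, `undefined_se_error`,
`insufficient_peaks_error`, ...) so callers can discriminate them.
Intervals are half-open `[start, end)` in seconds from recording start;
sample indices are 1-based; peak times place sample 1 at `t = 0`. Integer
ADC samples round-trip CSV bit-exactly. Constant pulses cannot be min–max
normalized; constant windows have undefined entropy; fewer than two peaks
yield no heart rate, fewer than three no Poincaré descriptors. Moving
averages reflect-pad half a window at each end. Tie-breaks: block argmax
takes the first maximal sample; lag search takes the first maximal
correlation (most negative lag).

## Problem sizes

The test suite validates closed forms on 4 s windows, oracle equivalence
on ≤ 10 s traces at 100 Hz (the brute-force reference is quadratic),
detector recovery on 60–120 s recordings at 1000 Hz, and distributional
properties (interval SD, Poincaré SD1) on runs of 5,000–10,000 beats;
these sizes give sub-sample or percent-level agreement wherever a closed
form exists, and the full benchmark scenario (two channels, 60–120 s)
completes in seconds.

## Known limitations

- The generator's beat-to-beat intervals are i.i.d.; real RR series have
  autoregressive structure (SD2 > SD1). Poincaré descriptors are computed
  correctly but the synthetic comet is circular, not elongated.
- Site gains and the saturation knee are stylized single numbers; real
  site differences involve morphology changes (pulse-arrival delay,
  damping), of which only the arrival delay (via lag alignment) is
  represented.
- The μ − 1σ threshold lands near, not exactly at, the compression knee;
  classification against the generator's truth mask agrees to ~97% for
  moderately driven sensors and ≥ 99% only under deep drive. This mirrors
  the practical situation: the rule is calibrated from a forced-saturation
  recording whose statistics, not the circuit's true knee, define it.
- Quality windows excluded for saturation shorten the averaging basis; a
  fully saturated signal has no defined non-saturated mean and is flagged
  rather than scored.
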