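Package: ppgbench
Title: Benchmarking Photoplethysmography Sensors with Synthetic Ground Truth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for benchmarking photoplethysmography (PPG) acquisition
    front-ends: calibration of amplifier/ADC saturation thresholds by the
    mean-minus-one-standard-deviation rule, spectral-entropy signal quality
    scoring over short windows, Butterworth preprocessing and systolic peak
    detection by the two-event-related-moving-average scheme, pulse-wave
    morphology comparison (Pearson correlation, cosine similarity, normalized
    Euclidean distance), heart-rate estimation with error metrics and Poincare
    descriptors, and evaluation of detectors against annotated peaks within a
    fixed time tolerance. Includes a synthetic PPG generator with a two-device
    acquisition model (transimpedance gain, soft-then-hard ADC saturation,
    quantization, optical sync pulse) that provides ground truth for every
    stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
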