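Package: gaitdfa
Title: Cycle-Wise Detrended Fluctuation Analysis of Gait Signals
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying long-range temporal correlations in
    multichannel gait recordings. Reads WFDB or CSV records carrying
    bilateral surface EMG (tibialis anterior, lateral gastrocnemius) and
    foot force-sensitive-resistor (FSR) channels, segments strides by
    dynamic-threshold heel-strike detection on the FSR signal, conditions
    EMG with a zero-phase Butterworth bandpass plus full-wave
    rectification and maximum normalization, and computes a detrended
    fluctuation analysis (DFA) scaling exponent per gait cycle per
    channel. Group differences in the per-cycle exponents are tested with
    one-way ANOVA and Tukey HSD post hoc comparisons. A synthetic-data
    module generates fractional Gaussian noise and fractional Brownian
    motion with known Hurst exponents, and synthetic gait records with
    known heel strikes, so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
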