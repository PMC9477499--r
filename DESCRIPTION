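Package: nremtools
Title: Sleep EEG Oscillation Analysis: Spindles, Slow Waves and Their
    Coupling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An analysis pipeline for overnight sleep EEG recordings:
    epoch-level artifact rejection (flanking band-power, clipped-sample and
    iterative RMS/Hjorth criteria), Welch and multitaper spectral
    estimation, IRASA decomposition of spectra into aperiodic (1/f) and
    oscillatory components with power-law slope/intercept fits,
    individualized-frequency sleep spindle detection by complex
    frequency B-spline wavelet transform, slow-wave negative half-wave
    detection with median-relative thresholds, spindle to slow-wave phase
    coupling (overlap, mean resultant length, mean angle) with
    shuffle-based null z-scores, circular statistics (Rayleigh,
    Watson-Williams) and cluster-based permutation correction. Includes a
    synthetic polysomnography generator with known ground truth for
    validating every stage, EDF and hypnogram readers, and
    sleep-architecture summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
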