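Package: sozpac
Title: Seizure-Onset-Zone Mapping from Interictal Phase-Amplitude Coupling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Localizes candidate seizure-onset-zone (SOZ) electrodes from
    interictal intracranial recordings using narrow-band phase-amplitude
    coupling. Implements the mean-vector-length modulation index with
    circular time-shift surrogate z-scoring over a 16 x 16 grid of
    low-frequency phase bands (0.5-24 Hz) and high-frequency-oscillation
    amplitude bands (80-560 Hz), per-electrode band-pair statistics with
    Mann-Whitney U tests, imbalance-aware classifiers (class-weighted
    support vector machines, balanced gradient-boosted trees, and a small
    2-D convolutional network trained with focal or class-balanced focal
    loss), and a chronological nested cross-validation that scores
    electrodes by their mean predicted SOZ probability. A synthetic
    multichannel generator with injected, depth-controlled coupling makes
    the whole pipeline testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
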