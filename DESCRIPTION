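Package: thetasync
Title: Theta Synchronization Analysis for Hippocampal-Entorhinal Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for analysing theta-band (5-12 Hz)
    synchronization in simultaneous hippocampal (HPC) and medial entorhinal
    cortex (MEC) laminar recordings. Provides multitaper theta power and
    channel-pair coherence matrices, spike-theta phase locking with
    self-contained circular statistics (Rayleigh, two-sample Kuiper,
    Fisher's concentration test), extracellular unit classification, MEC
    layer-3 subpopulation clustering, a coherence-matched subsampling
    dissociation analysis, and novel-object-location scoring. A synthetic
    cohort generator with closed-form oracles (von Mises-modulated Poisson
    spike trains, shared-oscillator laminar LFP) makes every stage
    verifiable without real recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    rlang,
    readr,
    jsonlite,
    signal,
    ggplot2,
    generics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
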