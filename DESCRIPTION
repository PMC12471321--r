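Package: emghht
Title: Hilbert-Huang Time-Frequency Analysis of Gait Surface EMG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ensemble empirical mode decomposition (EEMD) and Hilbert spectral
    analysis of lower-limb surface electromyography recorded during the stance
    phase of running. Provides EMG preprocessing (zero-phase band-pass
    filtering, moving-RMS enveloping, ground-reaction-force based stance
    detection, amplitude and time normalization), EMD/EEMD signal
    decomposition with a compiled sifting core, Hilbert spectra with marginal
    spectra and maximum-energy timing/frequency features, frequency-band
    powers, the tibialis anterior / medial gastrocnemius co-activation index,
    one-way repeated-measures ANOVA with LSD post hoc comparisons, and a
    seeded synthetic gait EMG + GRF generator emulating forefoot, midfoot and
    rearfoot strike patterns for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    signal,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    emmeans,
    withr,
    optparse
Config/testthat/edition: 3
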