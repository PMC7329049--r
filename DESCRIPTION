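Package: vocaffect
Title: Simulation and Analysis of Affect Perception from Animal Vocalizations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for studying how human listeners infer
    behavioural context and core affect (arousal, valence) from animal call
    bouts. Provides a seeded synthetic stimulus generator (harmonic-plus-noise
    call bouts with per-context acoustic presets), simulators for a 10-way
    forced-choice categorization experiment and a yes/no match-to-context
    experiment, extraction of bioacoustic features (call segmentation,
    autocorrelation pitch tracking, harmonics-to-noise ratio, jitter, shimmer,
    spectral centre of gravity), varimax-rotated principal component analysis
    with variance-inflation-factor screening, perceptual accuracy statistics
    (unbiased hit rates with Wagner chance levels, signed-rank tests against
    chance, signal-detection d-prime with extreme-rate adjustment, a priori
    power analysis via the noncentral t distribution), and acoustic prediction
    models (multinomial/binomial logits and binomial mixed models with crossed
    participant and caller random intercepts, selected by AICc).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    nnet,
    lme4,
    jsonlite,
    rlang,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
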