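Package: myodecode
Title: Simultaneous and Proportional Myoelectric Decoding with Noise-Robustness Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the robustness of myoelectric (surface EMG)
    decoding to signal non-stationarities. Generates synthetic 8-channel EMG
    from two-degree-of-freedom wrist intent under cue-based calibration and
    target-holding protocols, implements the standard real-time processing
    chain (causal Butterworth band-pass, 50 Hz comb filter, windowed RMS
    features on a 40 ms update schedule), and provides two simultaneous and
    proportional decoders: multivariate ordinary least-squares regression and
    multiclass linear discriminant analysis with majority voting and
    class-specific proportional scaling. Artificial disturbances (linearly
    ramping and sudden additive white Gaussian noise on single channels,
    scaled to the calibration-phase maximal amplitude) can be injected into
    raw recordings, and open-loop robustness metrics (baseline error,
    time-below-threshold, residual step error) and target-reaching metrics
    are computed with paired non-parametric statistical comparisons. A
    pluggable closed-loop user-policy hook supports simulated adaptation
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
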