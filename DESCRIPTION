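Package: vmdenoise
Title: ECG Denoising via Sparrow-Search-Optimised Variational Mode
    Decomposition and Hankel SVD
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Removes baseline wander and broadband noise from single-channel
    electrocardiogram (ECG) recordings. The signal is decomposed into
    band-limited intrinsic mode functions by variational mode decomposition
    (VMD), whose mode count K and bandwidth penalty alpha are selected
    automatically by a sparrow search metaheuristic minimising the envelope
    entropy of the sparsest mode. Baseline-drift modes are rejected by a
    mean-value criterion, effective modes are kept by a correlation
    threshold, and each retained mode is further denoised by Hankel-matrix
    singular value decomposition with difference-spectrum order selection.
    Includes synthetic ECG / test-signal generators, WFDB and CSV readers,
    SNR and MSE evaluation, broom-style tidiers and ggplot2 plotting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
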