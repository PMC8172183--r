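Package: eegstress
Title: Multi-Level Mental Stress Classification from EEG Biomarkers and
    Autoencoder Latent Representations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for four-condition mental-stress classification
    from midline EEG (Fz, Cz, Pz). Generates seeded synthetic recordings with
    condition-dependent spectral structure over a 1/f background, applies IIR
    band-limiting, resampling, baseline correction and one-second windowing,
    extracts three spectral biomarkers per window (alpha/beta/theta band powers
    via Welch's method, relative gamma, and the theta(Fz)/alpha(Pz) brain load
    index), learns latent representations with a from-scratch fully connected
    autoencoder trained by stochastic gradient descent on an RMSE loss, and
    benchmarks classifiers on raw versus latent features under stratified,
    fold-safe 5-fold cross-validation with t-SNE diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    signal,
    MASS,
    e1071,
    randomForest,
    rpart,
    class,
    Rtsne,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    cluster,
    jsonlite,
    withr
Config/testthat/edition: 3
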