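Package: respmotion
Title: Respiratory Motion Simulation, Wavelet Denoising and
    Latency-Compensated Tumor Motion Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for respiratory motion management in image-guided
    radiotherapy. Simulates labelled multi-axis respiratory surrogate
    signals with clinically motivated amplitude structure, denoises them
    with an orthogonal discrete wavelet transform, and trains a hybrid
    dilated-convolution / bidirectional-LSTM / autoencoder network that
    jointly classifies motion range into four amplitude bins, predicts
    future tumor position across 50-500 ms latency horizons, reconstructs
    physiologically coherent breathing curves, and flags excessive
    (>= 9 mm) motion. Includes the full evaluation protocol: confusion
    matrices, per-class precision/recall/F1 and one-vs-rest AUC, per-axis
    and per-latency RMSE, reconstruction MAE, reference predictors, and a
    PSNR utility.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
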