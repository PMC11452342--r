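Package: dpad
Title: Dissociative Prioritized Analysis of Neural Population Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Models the dynamical transformation from neural population
    activity to behavior with a two-section recurrent state-space model in
    predictor form, trained by a four-step prioritized optimization that
    learns behaviorally relevant latent dynamics first and the remaining
    neural dynamics afterwards. Each model parameter (recursion, neural
    input, neural readout, behavior readout) can independently be linear,
    a feed-forward network, or (recursion) an LSTM; an inner
    cross-validated architecture search selects the nonlinearity, and a
    joint decoding/self-prediction performance frontier localizes its
    origin. Includes causal filtering and multistep forecasting,
    categorical and intermittently observed behaviors, contiguous
    cross-validation and dimension-selection rules, simulation ground
    truths with a steady-state Kalman predictor ceiling, and spike/LFP
    feature extraction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    pROC
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
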