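Package: revlearn
Title: Learning-Rate Dynamics in Probabilistic Reversal Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and model-based analysis of probabilistic reversal
    learning with counterfactual feedback. Provides a generative task
    simulator (three stimuli, blocked reward contingencies with unsignalled
    reversals), the nested Pearce-Hall hybrid reinforcement-learning model
    family (constant learning rate; associability-gated learning rate;
    feedback-confirmation and feedback-modality modulation), maximum
    a posteriori fitting with multi-start bounded optimisation, BIC-based
    random-effects Bayesian model selection with protected exceedance
    probabilities, learning-rate-dynamics analyses (reversal-aligned
    learning curves, structural-break segmentation, learning-rate
    variability, reversal-versus-noise signal-to-noise contrast,
    misleading-feedback accuracy, eta sweeps), a joint
    volatility/stochasticity learner (Kalman filter within a
    Rao-Blackwellized particle filter) with a stochasticity-lesioned
    variant, and labelled synthetic cohorts with ground truth for
    parameter- and model-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    readr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
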