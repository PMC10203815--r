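Package: mmrlearn
Title: Model-Based Single-Trial Analysis of Multimodal Mismatch Responses
Version: 0.1.0
Authors@R:
    person("Analysis", "Pipeline", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and model-based analysis pipeline for tri-modal
    (auditory, somatosensory, visual) roving oddball experiments. Generates
    probabilistic stimulus sequences from an 8-state Markov model with
    cross-modal conditional dependencies, computes ideal-observer surprise
    regressors (predictive, Bayesian and confidence-corrected surprise) from
    Dirichlet-Categorical learners with exponential forgetting plus a
    train-length change-detection baseline, fits them to single-trial
    channel-by-time amplitude data with variational Bayesian linear
    regression, and adjudicates between model families using random-effects
    Bayesian model selection with exceedance probabilities. Includes the
    ERP-style condition GLM stage (train-length and predictability designs,
    linear contrasts, conjunction, repeated-measures ANOVA, cluster-based
    permutation correction) and a synthetic EEG generator with known ground
    truth for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
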