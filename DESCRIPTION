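Package: momentumRPE
Title: Momentum-Biased Reward Prediction Errors: Generative Models,
    Model-Based fMRI Simulation, and Group Inference
Version: 0.1.0
Authors@R:
    person("Analysis", "Pipeline", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Generative models of reward prediction errors (RPEs) in which
    the exponentially integrated history of recent outcomes ("momentum",
    a computational stand-in for momentary mood) recursively biases the
    perception of subsequent outcomes. Provides a balanced probabilistic
    Roulette-task schedule generator, synthetic region-of-interest BOLD
    simulation with known ground truth (canonical double-gamma HRF, AR(1)
    noise, drift, motion nuisance, momentum-modulated insular-striatal
    coupling), a parametric-modulator first-level GLM, generalized
    psychophysiological interaction (gPPI) analysis, and a group-level
    statistics layer (one-sample/pooled/Welch t, chi-squared, Cohen's d,
    standardized symptom regressions, Bonferroni correction), orchestrated
    by a reproducible end-to-end pipeline over a simulated two-group cohort.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
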