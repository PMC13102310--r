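Package: vmradapt
Title: Error Models of Visuomotor Rotation Adaptation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Trial-by-trial state-space models of visuomotor rotation (VMR)
    adaptation in which implicit learning is driven by one of three competing
    error signals: performance error (PE), sensory prediction error (SPE), or
    a perceptual prediction error (PPE) computed from Bayesian reliability-
    weighted integration of visual, proprioceptive, and motor-prediction cues
    with eccentricity-dependent visual uncertainty. Includes a synthetic-data
    generator for six classical VMR experiment designs (blocked perturbation
    sizes, stepwise versus one-step perturbations, pseudo-random single-trial
    perturbations, instructed re-aiming, late re-aiming, and perceptual probe
    trials), constrained multi-start least-squares fitting of condition-mean
    learning curves, goodness-of-fit and information-criterion model
    comparison, participant bootstrap, parameter recovery with Lin's
    concordance correlation coefficient, and model-confusion analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    lhs,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
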