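Package: lrpipe
Title: Simulation and Analysis of Lateralized Readiness Potentials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: An end-to-end toolkit for lateralized readiness potential (LRP)
    experiments: generation of block/trial schedules with condition-ordering
    constraints, synthesis of spectrally matched noise stimuli and
    intensity-change response cues, simulation of continuous multichannel EEG
    with ground-truth motor potentials, ocular artifacts and ex-Gaussian
    reaction times, standard ERP preprocessing (mastoid re-referencing,
    zero-phase Butterworth filtering, bad-channel interpolation, EOG
    regression), epoching with rule-based trial rejection, Coles-method LRP
    derivation, jackknife 50%-of-peak onset scoring with adjusted test
    statistics, and a frequentist plus Bayesian inference layer
    (Greenhouse-Geisser repeated-measures ANOVA, JZS Bayes factors for paired
    t-tests and one-way repeated-measures designs, and exact Bayes factors for
    Pearson correlations under a stretched beta prior).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
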