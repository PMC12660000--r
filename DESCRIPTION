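Package: msmlog
Title: Multi-State Survival Modelling of Timestamped Action-Sequence Log Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing timestamped action-sequence (process) log data
    from computer-based assessments with a multi-state survival model. Actions
    are treated as states of a time-homogeneous Markov process; transition
    hazards combine group-specific baseline rates, an individual speed factor,
    covariate effects, and effects of discriminative "key actions" selected by
    TF-ISF-weighted chi-square feature scores. Estimation is fully Bayesian via
    adaptive Metropolis-within-Gibbs MCMC with Gelman-Rubin diagnostics and
    highest-posterior-density intervals. Includes posterior comparison of
    embedded-chain transition probabilities between correct and incorrect
    responder groups, machine-readable heatmap and network exports, and a
    simulator for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
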