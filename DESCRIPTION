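Package: mindchange
Title: Neural Circuit Simulation of Decision Uncertainty and Change-of-Mind
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates a distributed attractor-network model of two-choice
    perceptual decision making in which a cortical-column-like microcircuit
    continuously monitors decision uncertainty and feeds it back to the
    sensorimotor populations, occasionally producing changes-of-mind.
    Provides the reduced two-variable sensorimotor model with NMDA-mediated
    synaptic gating, a threshold-linear uncertainty-monitoring module, motor
    integrators mapped to screen position, Euler-Maruyama trial simulation
    with the full within-trial event schedule, behavioural analyses (Weibull
    psychometric fits, chronometric summaries, peak/area uncertainty
    read-outs, change-of-mind statistics, coupled-trial sequential effects),
    and numerical phase-plane and bifurcation analysis of the sensorimotor
    subsystem.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    pracma,
    data.table,
    stats,
    utils,
    graphics,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
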