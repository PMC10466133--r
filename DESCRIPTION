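Package: isctsim
Title: In Silico Clinical Trials for Closed-Loop Drug Infusion Devices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulator for in-silico clinical trials of physiological
    closed-loop drug-infusion devices, instantiated for intravenous
    anesthetic (propofol) delivery. Provides a three-compartment
    pharmacokinetic model with a virtual effect-site compartment, virtual
    patient cohort generation under log-normal inter-individual variability,
    a combined additive/proportional residual-error sensor model with
    configurable measurement period, delay and failure injection, an
    open-loop target-controlled-infusion (TCI) algorithm, a Bayesian
    (MAP-personalized) model-predictive closed-loop controller, actuator
    constraint enforcement with alarms, and a trial engine that compares
    open- and closed-loop arms on cohort concentration-time statistics
    (median profiles, 95% prediction intervals, accuracy-band metrics).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
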