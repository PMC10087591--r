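Package: conformity
Title: Frequency-Dependent Social Learning Rules, Conformity Tests, and
    Gene-Culture Metapopulation Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying conformist transmission (positive
    frequency-dependent social learning). Implements the classical
    three-demonstrator conformist-bias rule and a logistic (discrete-choice)
    family of learning rules covering hyper-, weak- and anti-conformity with
    an optional behavioural error rate; a log-odds regression estimator of
    conformity strength with a one-sided test of conformist bias, a
    multi-trait pairwise extension, and a maximum-likelihood fit of the
    error-mixture model; and a forward-time two-locus metapopulation
    simulator in which conformist mate choice can evolve through independent
    Fisher runaway processes in subpopulations coupled by dispersal.
    Includes a synthetic choice-data generator, a power/calibration harness
    for the conformity test, parameter sweeps over conformity strength and
    dispersal, YAML run configuration, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
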