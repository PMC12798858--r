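Package: aispike
Title: Axon Initial Segment Excitability Modelling for Fast-Spiking Interneurons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Conductance-based multi-compartment modelling of cortical
    fast-spiking (parvalbumin) interneurons with a parameterizable axon
    initial segment (AIS). Implements tanh-formalism Hodgkin-Huxley channel
    kinetics, a discretized soma/axon/dendrite cable integrated with a
    semi-implicit Hines solver, square-pulse and synaptic-conductance (EPSC)
    stimulation protocols, phase-plot based action-potential feature
    extraction (10 mV/ms threshold criterion, half-width, AHP, rheobase,
    latency), passive-property measurement (input resistance, apparent tau),
    baseline calibration, and AIS parameter-sweep experiments (AIS length,
    Kv1/Nav1.6 conductance density, AIS position, axon diameter and axial
    resistance). A synthetic-data module generates ground-truth-annotated
    voltage traces and quantile-matched feature cohorts for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
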