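Package: knaephys
Title: Sodium-Activated Potassium Current Analysis for DRG Neuron Electrophysiology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification of sodium-activated potassium (KNa) background
    current in small-diameter dorsal root ganglion neurons and of its role in
    setting action-potential threshold and rheobase. Provides a conductance-based
    single-compartment neuron model with submembrane Na+ handling and
    Hill-activated KNa conductance, voltage- and current-clamp protocol
    simulators with pipette-dialysis and rundown dynamics, single-channel
    record generation, hyperpolarizing-step leak quantification, voltage-dependent
    Cs+ block fitting, phase-plane (dV/dt) spike threshold and rheobase
    extraction, f-I analysis, chord-conductance resting-potential calculations,
    Nernst potentials, Boltzmann activation fits, single-channel conductance
    estimation, and cohort-level Kolmogorov-Smirnov / t-test comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
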