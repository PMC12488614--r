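Package: calres
Title: Calcium and Voltage Resonance in Conductance-Based Hippocampal Neuron Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Conductance-based modelling of subthreshold calcium and voltage
    resonance in hippocampal CA1 pyramidal neurons. Implements a
    single-compartment model and a gradient-endowed multi-compartment
    somato-apical trunk model (non-uniform Rm/Ra, A-type K+, h and T-type
    Ca2+ conductance gradients, d-lambda discretization), a semi-implicit
    cable integrator with Hodgkin-Huxley gating, Goldman-Hodgkin-Katz T-type
    calcium current and single-pool calcium dynamics, chirp (ZAP) stimulus
    generation, impedance-profile analysis (resonance frequency f_R and
    strength Q), and the parameter-sweep experiments that characterize how
    T-type calcium, h and A-type K+ channels shape intrinsic calcium
    resonance and its dissociation from voltage resonance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
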