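Package: hippsim
Title: Shift-Register Simulation of the CA3-CA1 Hippocampal Microcircuit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a small CA3-CA1 hippocampal microcircuit (14 cells:
    pyramidal, basket and O-LM cells) built from 16-compartment shift-register
    neurons with AMPA, NMDA and GABA-A synapses, theta-modulated entorhinal
    and medial-septum inputs, and an NMDA-gated long-term potentiation rule
    with a forgetting coefficient. Supports a progressive synaptic-deletion
    lesion protocol emulating Alzheimer's-type degradation of CA3 afferents,
    and provides spike-train statistics (counts, interspike intervals,
    frequencies, group tests, correlations with deletion load) and nonlinear
    time-series analysis (autocorrelation delay selection, false nearest
    neighbors, Grassberger-Procaccia correlation dimension, Shannon entropy,
    recurrence distance matrices).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
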