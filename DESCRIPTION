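Package: avnet
Title: Firing-Rate Network Simulation of Audiovisual Spatiotemporal Integration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a biologically inspired four-layer firing-rate neural
    network for audiovisual perception: topographic auditory and visual input
    areas coupled by fast excitatory cross-modal synapses, a competitive
    interneuron layer implementing winner-takes-all cross-sensory inhibition,
    a multisensory integration area, and a premotor readout that generates
    simulated reaction times. Includes the full experiment battery of the
    model family: modality-switch reaction-time tasks, spatial ventriloquism
    localization, race-model (redundant signals) analysis, connection-strength
    sensitivity sweeps, and spatiotemporal prediction grids over interstimulus
    interval and audiovisual disparity.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    tools,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    withr,
    deSolve,
    testthat (>= 3.0.0),
    optparse,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
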