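Package: ingsim
Title: Interneuronal Network Gamma: Conductance-Based Simulation and Phase-Response Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of theta-nested fast oscillations in networks of
    fast-spiking, parvalbumin-positive inhibitory interneurons of the medial entorhinal
    cortex. Provides a single-compartment Hodgkin-Huxley-type model of type-2
    fast-spiking cells (Nav, Kv1, Kv3), calibrated synthetic populations with
    physiological heterogeneity, depressing GABA-A synapses, gap-junction coupling with
    leak compensation, a fixed-step network integrator with conduction delays and a
    simulated channelrhodopsin theta drive, first- and second-order phase response
    curves with pulse-coupled predictions of network frequency and synchrony stability,
    and detection of theta-nested fast oscillations via Morlet wavelet scalograms and
    circular statistics of onset/offset phases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
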