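Package: adexnet
Title: Adaptive Exponential Integrate-and-Fire Network Simulation and
    Synchronization Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates random directed networks of adaptive exponential
    integrate-and-fire (AdEx) neurons with conductance-based excitatory and
    inhibitory synapses, and analyses their collective dynamics.  Provides a
    fast compiled explicit-Euler integrator with event-driven synaptic
    updates, spike-phase Kuramoto order parameter, inter-spike-interval
    coefficient of variation, instantaneous and mean firing rates, and
    regime classification (desynchronized/synchronized spikes/bursts).
    Experiment protocols cover parameter-space sweeps over the
    excitation-inhibition balance, hysteresis continuation sweeps that
    detect bistability between desynchronized spiking and synchronized
    bursting, inhibitory-neuron removal, square-current-pulse stimulation
    that triggers or suppresses abnormal synchronization, synchronization
    probability, noise sensitivity, and membrane-potential nullcline
    (phase-plane) analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
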