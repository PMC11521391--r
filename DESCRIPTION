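Package: pingnet
Title: Cholinergic Modulation and Synchrony in Excitatory-Inhibitory
    Spiking Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Conductance-based simulation and analysis of
    excitatory-inhibitory (E-I) spiking networks under cholinergic
    neuromodulation. Single neurons follow a Hodgkin-Huxley style
    cortical pyramidal cell model with a slow M-type potassium current
    whose conductance (gKs) switches the cell between Type I (M-current
    blocked, as under acetylcholine) and Type II excitability.  The
    package provides the single-cell model with I-F and phase-response
    characterization, a Bernoulli-wired E-I network builder with
    calibrated heterogeneous drive currents, a fixed-step Runge-Kutta
    network integrator with double-exponential synapses, spike-train
    measures (a variance-ratio synchrony index, Gaussian-convolution
    burst detection, burst frequency and width, active-cell counts),
    synthetic raster generators with known ground truth, and a sweep
    pipeline over inter- versus intra-population synaptic conductances
    including an I-to-E ablation experiment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    yaml,
    deSolve
Config/testthat/edition: 3
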