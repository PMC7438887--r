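Package: spikefuse
Title: Neuromorphic Sensor Fusion for EMG and Event-Camera Gesture Recognition
Version: 0.1.0
Authors@R:
    person("spikefuse", "developers", email = "spikefuse@example.org",
           role = c("aut", "cre"))
Description: Tools for fully event-driven hand-gesture classification from
    surface electromyography (sEMG) and dynamic vision sensor (DVS) event
    streams. Provides delta-modulator spike encoding of biosignals, event
    cropping/subsampling, a discrete-time simulator for quantized
    current-based leaky integrate-and-fire (CUBA-LIF) spiking networks with
    axonal delays, surrogate-gradient training and quantization-aware
    ANN-to-SNN mapping, late sensor fusion of penultimate layers, an
    analytic hardware cost model (synaptic operations, dynamic power,
    energy, energy-delay product, chip utilization) for crossbar
    neuromorphic processors, seeded synthetic dataset generation, and
    session-wise cross-validated evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    rlang,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
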