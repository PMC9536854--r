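Package: scsdh
Title: Dorsal Column Stimulation, Dorsal Horn Network Modeling, and Spike-Train
    Analysis for Surround Inhibition Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how low-amplitude epidural spinal cord stimulation
    (SCS) engages surround inhibition in the spinal dorsal horn. Provides an
    analytic volume-conductor model of a bipolar epidural electrode, MRG-style
    double-cable models of myelinated dorsal column axons with activation
    threshold search and response libraries, a somatotopic dorsal column map
    sampler, a conductance-based three-node center/surround dorsal horn circuit
    (excitatory and inhibitory interneurons plus a wide-dynamic-range projection
    neuron per node), generators for neuropathic pain afferent input and
    synthetic extracellular recordings, and an analysis pipeline for recorded
    units (optimal bin width, z-score responder statistics, response
    normalization, fuzzy c-means clustering, and waveform-based cell-class
    classification).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    yaml,
    stats,
    utils,
    jsonlite,
    lhs,
    minpack.lm,
    MASS,
    cluster
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
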