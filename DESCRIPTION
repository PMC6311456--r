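Package: fibermix
Title: Modeling and Demixing Fluorescence Recorded Through Splayed Optical Microfiber Bundles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis framework for high-channel-count fiber
    photometry through bundles of splayed optical microfibers. Computes
    single-fiber fluorescence sensitivity profiles by Monte Carlo photon
    transport in voxelized tissue, samples fiber-bundle and neuron geometries,
    builds the excitation/collection mixing matrix of the interface, simulates
    calcium-indicator (GCaMP6f) fluorescence recordings mixed through the
    bundle, demixes them with inverse-filtered non-negative independent
    component analysis, and evaluates separation quality with correlation
    matching and threshold-crossing spike-detection ROC analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    stats,
    utils,
    yaml,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
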