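Package: hcstraffic
Title: Quantification of Plasma-Membrane Protein Traffic from High-Content Screening Images
Version: 0.1.0
Authors@R: person("HCS", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: End-to-end quantification of plasma-membrane protein traffic from
    multichannel fluorescence microscopy plates: illumination-correction
    estimation and subtraction, nucleus and cell segmentation with per-cell
    fluorescence integration, three-level quality control (cell, image,
    plate), ratiometric surface/total traffic-efficiency readouts,
    SEM-scaled deviation scores with enhancer/inhibitor calling and
    Student's t-tests against negative controls, plus a seeded synthetic
    plate simulator that provides pixel-level ground truth for validation.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
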