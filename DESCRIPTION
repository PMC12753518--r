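Package: cochstim
Title: Simulation of Cochlear-Implant Stimulation of Auditory Nerve Fibers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for simulating extracellular stimulation of the auditory
    nerve by cochlear-implant electrode arrays. Generates a parametric
    synthetic human cochlea with 25 auditory-nerve-fiber trajectories, fits
    peri-modiolar and lateral-wall electrode-array centerlines in scala
    tympani or scala vestibuli under a constant fiber-distance constraint,
    computes monopolar extracellular potentials with a voxelized
    finite-difference volume-conductor solver, integrates a temperature
    adjusted Hodgkin-Huxley multi-compartment model of the human type I
    spiral ganglion cell, and runs threshold, spike-initiation-site,
    specificity, conductivity-sensitivity and ossification analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
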