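Package: gridplace
Title: Grid-to-Place Cell Transformation with Oscillatory-Interference
    Grid Cells and a Hodgkin-Huxley Place Cell
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for the entorhinal-to-hippocampal
    grid-to-place transformation. Implements velocity-controlled-oscillator
    (oscillatory interference) grid cell models with Gaussian firing-field
    thinning, a pool of spatiotemporally diverse grid cells, a reduced
    multicompartment Hodgkin-Huxley CA1 pyramidal place cell driven through
    distal excitatory synapses, dwell-normalized firing-rate maps with grid
    spacing/score metrics, excitatory-ramp-input (ERI) classification, and
    theta phase-precession analysis via circular-linear regression.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
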