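Package: smfretr
Title: Single-Molecule FRET Trace Analysis, Gaussian Mixture Decomposition
    and Dye Accessible-Volume Distance Modelling
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for single-molecule FRET (smFRET)
    intensity traces of membrane-protein conformational states: synthetic
    trace generation with known ground truth, photobleaching change-point
    detection and trace selection (single acceptor bleach before single
    donor bleach), per-molecule gamma-factor estimation from the intensity
    jump at acceptor photobleaching, gamma-corrected FRET efficiency
    computation, summed trace-normalized efficiency histograms, Gaussian
    mixture decomposition with fractional areas, Forster-relation
    efficiency/distance conversion and R0 calibration, accessible-volume
    simulation of dye positions on protein structures, and auxiliary
    quantification of TIRF puncta time courses and crosslinking
    efficiencies from band densitometry.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    jsonlite,
    yaml,
    bio3d,
    tiff
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
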