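Package: scaffopt
Title: Multiscale Design Optimisation of TPMS Bone-Growth Scaffolds
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to design bone tissue-engineering scaffolds built from
    triply periodic minimal surface (TPMS) lattices. Generates sheet-TPMS
    geometries on voxel grids (Primitive, Gyroid, Split P, Diamond, Lidinoid,
    Neovius), measures minimum and maximum pore diameters by medial-axis
    skeletonisation and Euclidean distance transforms, maps volume fraction to
    axial scaffold stiffness through Gibson-Ashby scaling laws (optionally
    re-derived with a voxel finite-element homogeniser), simulates
    curvature-driven pre-osteoblast growth with a finite-difference level-set
    model, and selects the scaffold type and volume fraction that maximise the
    average cell growth rate subject to pore-size and stiffness constraints.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    minpack.lm,
    yaml,
    jsonlite,
    ggplot2,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
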