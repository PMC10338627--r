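Package: paccmotion
Title: Single-Cell Motility, Chemotaxis, and Cytoskeletal Biomechanics
    Metrics
Version: 0.9.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of single-cell migration assays and
    cell-mechanics measurements of the kind used to phenotype polyaneuploid
    (PACC-state) cancer cells.  Provides per-cell trajectory metrics
    (accumulated and Euclidean distance, directness, spider-plot
    coordinates), circular statistics for chemotaxis (Rayleigh test,
    Moore's rank-based vector variant, parallel and perpendicular forward
    migration indices, and a three-criterion chemotaxis decision rule),
    mean-squared-displacement analysis of cytoskeleton-anchored beads,
    magnetic twisting cytometry stiffness, Hertz-model fitting of AFM
    force-indentation curves, and the small expression-quantification
    calculations (delta-delta-Ct, NanoString positive-control
    normalization, integrated density, positivity percentages).  A
    synthetic-data module generates trajectories, bead tracks, force
    curves, and Ct tables with known ground truth so every estimator is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
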