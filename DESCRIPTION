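Package: GlycSite
Title: Structure-Based Prediction of Lysine Glycation Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts glycated versus non-glycated lysine residues in
    protein sequences from predicted per-residue structural properties
    (accessible surface area, backbone angles phi/psi/theta/tau and
    three-state secondary-structure probabilities). Sites are encoded as
    fixed-length windows centred on each lysine with mirror padding at
    sequence termini, the imbalanced non-glycated class is reduced by
    k-nearest-neighbour cleaning, and a polynomial-kernel support vector
    machine is trained and evaluated with repeated stratified k-fold
    cross-validation, jackknife, ROC/AUC, window-size scans and paired
    method comparison. A seeded synthetic benchmark generator emulates
    the shape of curated glycation datasets so the whole pipeline is
    testable without external structure-prediction tools.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    e1071
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
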