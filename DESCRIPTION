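Package: hawkshead
Title: Lightweight CNN Pipeline for Stain-Normalised H&E Tile Classification
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end workflow for binary classification of haematoxylin-eosin
    (H&E) histology tiles, built around HawksheadNet, a lightweight convolutional
    neural network for differentiating neoplastic (cDLBCL-like) from reactive
    (RLH-like) lymphoid tissue. Provides a seeded synthetic H&E cohort generator
    (Beer-Lambert stain composition with per-patient stain variation),
    non-overlapping 512x512 tile tessellation of slide regions of interest, four
    statistics-based stain normalisers (Reinhard, Macenko, Ruifrok, Vahadane),
    leakage-free patient-level data preparation (median tile capping, stratified
    60:30:10 splitting, class balancing), CNN training and prediction with a
    compiled single-threaded backend, evaluation statistics (confusion metrics,
    AUROC, DeLong's and McNemar's paired tests), and whole-slide prediction
    overlays with GeoJSON export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    EBImage,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
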