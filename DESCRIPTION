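Package: dmqa
Title: Protein Model Quality Assessment from Inter-Residue Distance
    Difference Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Single-model estimation of protein model accuracy (EMA/QA).
    Converts a structural model in PDB format and a sequence-predicted
    inter-residue distance map into a mutually filtered, upper-triangular
    difference map, and regresses the model's GDT-TS score with a 2D
    convolutional neural network carrying squeeze-and-excitation channel
    attention. Includes length-homogeneous batched training with the smooth
    L1 loss and Adam, a full evaluation suite (per-target ranking loss and
    Pearson correlation, two-sample Kolmogorov-Smirnov tests, sample
    skewness), a synthetic decoy generator so the whole pipeline runs at
    desk scale, and a command-line interface covering the
    simulate/featurize/train/predict/evaluate workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
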