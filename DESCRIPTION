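Package: omicspanel
Title: Multi-Omics Biomarker Panel Discovery by Late Integration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scriptable analysis engine for multimodal omics studies: metadata
    association statistics with regression-assumption validation, per-dataset
    principal component analysis with metadata association heatmaps,
    differential expression by ordinary least squares, empirical-Bayes
    moderated t-statistics or precision-weighted log-CPM for counts,
    over-representation analysis against GMT gene-set collections with a
    tested-feature universe, drug-reversal scoring against chemical
    perturbation signatures, and late-integration biomarker discovery via
    per-dataset elastic-net classifiers tuned by repeated stratified
    cross-validation and ensembled by averaging predicted probabilities.
    Includes a synthetic multimodal study generator with known ground truth,
    markdown report assembly, and a config-driven pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    Rcpp,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    limma,
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
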