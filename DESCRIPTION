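Package: ervImpact
Title: Predicting Transcriptional Disruption by Intronic ERV Insertions
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts the likelihood that an intronic endogenous retrovirus
    (ERV) insertion of the mouse IAP or ETn/MusD families disrupts
    transcription of its enclosing gene. Implements factor derivation from
    gene annotation (relative orientation, intron size, ERV-to-exon
    distance), log10 feature normalization with 100 kb / 50 kb caps, a
    4-3-1 multilayer perceptron trained by full-batch back-propagation, an
    ensemble built by stratified 3-fold cross-validation with repeated data
    permutation and random reinitialization (3000 members at the default
    scale), consolidated (averaged) prediction, ROC/threshold evaluation,
    in-silico insertion-grid prediction plots, and a synthetic data
    generator emulating the class-conditional structure of curated
    training sets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    grDevices,
    utils,
    jsonlite,
    pROC,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    ggplot2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
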