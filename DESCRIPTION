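Package: tcreact
Title: T-Cell Reactivity Prediction for MHC Class I Peptides with
    Weighted Degree String Kernels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts T-cell reactivity (immunogenicity) of MHC class
    I-presented 9-mer peptides with a support vector machine on a weighted
    degree string kernel, and characterises the sequence basis of T-cell
    recognition. Provides the kernel and a dual SMO solver for precomputed
    Gram matrices, nested 10-fold cross-validation with grid search and
    repeated runs, learning curves, a mean physicochemical-property RBF-SVM
    baseline, position-deletion importance analysis, two-sample logo
    enrichment statistics with Bonferroni correction, S/M/L
    property-recoded logos, an AAindex flat-file reader, an
    information-gain decision tree with feature-usage ranking, and a
    synthetic peptide dataset generator with planted position-specific
    residue preferences for ground-truth validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    tools,
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    jsonlite,
    ggplot2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    pROC
Config/testthat/edition: 3
biocViews: Classification, Software, ImmunoOncology, SupportVectorMachine,
    SequenceMatching
RoxygenNote: 7.3.3
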