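Package: hotspotEL
Title: Ensemble SVM Classification of Recombination Hotspots from DNA
    Sequence Composition
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Identifies meiotic recombination hotspots and coldspots from
    DNA sequence alone by fusing three support vector machines trained on
    complementary sequence encodings: k-mer occurrence frequencies,
    dinucleotide-based auto-cross covariance over physicochemical
    properties, and pseudo dinucleotide composition. Class probabilities
    of the three base predictors are averaged to form the ensemble
    decision. Includes the dinucleotide physicochemical property table,
    leave-one-out (jackknife) and stratified k-fold evaluation with
    sensitivity, specificity, accuracy, Matthews correlation coefficient,
    ROC curves and AUC, sparse SVM-light feature export, and a
    Markov-chain synthetic sequence generator for offline testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    e1071
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
biocViews: Classification, Sequencing, SupportVectorMachine
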