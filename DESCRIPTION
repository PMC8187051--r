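Package: stack4mC
Title: Stacked-Ensemble Prediction of DNA N4-Methylcytosine Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts DNA N4-methylcytosine (4mC) sites from fixed-length,
    cytosine-centred sequence windows. Windows are encoded with overlapping
    k-mer composition frequencies (k = 1..5) and per-position electron-ion
    interaction pseudopotential (EIIP) values, then classified with a
    two-stage stacked ensemble: a discrete Bayes network, multinomial naive
    Bayes, an RBF-kernel support vector machine and a voted perceptron
    produce out-of-fold probability features on which a logistic
    metaclassifier is trained. Includes FASTA window I/O, stratified
    cross-validation and independent-test evaluation with ACC, MCC,
    sensitivity, specificity and ROC/AUC, and a synthetic benchmark
    generator with plantable positional-motif and k-mer-composition signal.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    e1071,
    igraph,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
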