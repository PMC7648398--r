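Package: lncprior
Title: Prioritization of Disease-Associated lncRNAs from Developmental Brain
    Expression and Transcript Sequence Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A machine-learning pipeline that transfers knowledge from known
    protein-coding autism-spectrum-disorder (ASD) risk genes to long non-coding
    RNAs (lncRNAs). Developmental brain expression profiles are compressed with
    a single-layer autoencoder, transcript sequences are summarised as
    length-normalized k-mer frequencies with random-forest importance
    selection, and class-weighted logistic-regression, support-vector-machine
    and random-forest classifiers are trained and evaluated by repeated
    stratified cross-validation. Models are validated by leave-one-out
    percentile ranking of known risk genes within hypothetical genomic loci,
    and applied to call, rank and annotate candidate lncRNAs (three-model
    consensus, co-expression partners, genomic overlap with risk genes). A
    synthetic-data generator with planted expression and sequence signal makes
    every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    e1071,
    ranger,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    rtracklayer,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
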