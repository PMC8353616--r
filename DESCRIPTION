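Package: pasflow
Title: Calling, Filtering and Quantifying Polyadenylation Sites from 3' Tag Single-Cell RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A stepwise pipeline for alternative-polyadenylation analysis of
    3' tag-based single-cell RNA-seq. Calls fixed-width coverage peaks at
    transcript level from barcoded alignments, assesses peak modality with a
    dip-statistic test, filters candidate cleavage sites with a
    position-insensitive convolutional + bidirectional-LSTM sequence
    classifier trained on shifted windows around annotated poly(A) sites,
    removes intronic internal-priming artifacts, quantifies PAS-based
    transcripts per cell barcode by UMI counting, and computes proximal
    PAS-usage statistics across cells and groups. Includes a synthetic-data
    generator (genome, annotation, tagged alignments) so every stage is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    Matrix,
    Rcpp,
    jsonlite,
    nortest,
    stats,
    utils,
    methods,
    tools,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
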