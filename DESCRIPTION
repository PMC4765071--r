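Package: gliscan
Title: Prediction of Hedgehog-Responsive Enhancers from GLI Binding Motif
    Libraries and k-mer Spectrum SVMs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds libraries of GLI binding motifs (12-mers) from multiple
    ChIP peak sets by iterative enriched-word discovery, trains canonical
    8-mer spectrum support vector machine classifiers on GBM-containing peaks
    versus GC-matched genomic background, scores 600 bp windows centered on
    every genomic GBM, and evaluates predictions by interval overlap
    enrichment, inter-classifier correlation and per-base k-mer weight
    profiles. Includes seeded synthetic-data generators (genomes, peak sets
    with controlled motif grammars and dataset sharing, epigenomic feature
    tracks) so the whole pipeline is testable at desk scale, and an in silico
    GLI-site knockout operation mirroring site-directed mutagenesis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    kernlab,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    BiocGenerics,
    tibble,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
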