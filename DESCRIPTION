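Package: lacteome
Title: Whole-Milk Transcriptome Discovery, Classification, and
    Differential Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for characterizing whole-milk RNA-seq transcriptomes:
    comparison of assembled transcripts against a reference annotation
    using gffcompare-style class codes, discovery and classification of
    novel coding and long non-coding transcripts through a staged
    filtering cascade, transcript-level negative-binomial differential
    expression under a milk-type by parity interaction model, gene-level
    aggregation of transcript P-values by the weighted Lancaster method,
    marker-based cell-type composition profiles, hypergeometric
    over-representation testing, and an a-priori power calculation for
    two-group RNA-seq designs.  A synthetic-data generator with planted
    ground truth supports end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    MASS,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
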