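Package: crispacer
Title: Cas12a CRISPRi Library Design and Pooled Fitness Screen Scoring
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Designs CRISPR interference (CRISPRi) guide libraries for
    Cas12a in AT-rich bacterial genomes and scores pooled fitness screens
    built from them. Covers IUPAC PAM censuses across gene sets, rule-based
    spacer enumeration and ranking (strand rules, GC window, extended TTTV
    PAM preference), genome-wide off-target filtering by Hamming distance,
    CRISPR array assembly with direct-repeat folding validation through an
    RNA secondary-structure engine, emission of cloning-ready Gibson
    fragments and Golden-Gate style repeat-spacer oligo sets, amplicon-based
    library quantification, and per-gene fitness calling from log2 fold
    changes with Benjamini-Hochberg FDR control. Ships a deterministic
    synthetic-data generator for AT-rich genomes, off-target decoys and
    negative-binomial screen counts so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    BiocGenerics,
    rtracklayer,
    Rcpp,
    yaml,
    withr,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    jsonlite
SystemRequirements: ViennaRNA (RNAsubopt and RNAfold on the PATH) for
    CRISPR array folding validation
Config/testthat/edition: 3
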