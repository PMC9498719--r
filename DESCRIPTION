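Package: allseq
Title: Large Insertion and Deletion Detection from Mate-Pair Span Outliers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.org>
Description: Detects large (>= 1 kb) insertions and deletions from
    combined mate-pair / shotgun ("All-seq") sequencing libraries.
    Junction-bearing reads are split at the Tn5 adapter into mate-pair
    fragments; same-chromosome mate-pair spans are summarised by
    quartiles, and pairs whose span falls outside Q1 - 1.5*IQR or
    Q3 + 1.5*IQR are clustered into deletion and insertion calls.
    Includes multi-sample comparison by reciprocal overlap, gene
    loss/gain annotation from expression tables, TAD-fusion flagging,
    in-silico PCR validation of candidate breakpoints, and a
    deterministic read simulator with truth-set evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    graphics,
    jsonlite,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    rtracklayer,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
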