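Package: tnfitness
Title: Conditional Gene Fitness Analysis for Transposon Insertion Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for transposon-directed
    insertion-site sequencing (TraDIS/Tn-seq) conditional-fitness screens.
    Generates annotated genomes and saturated mini-Tn5 insertion libraries
    under known selection, emits and processes barcoded transposon-junction
    reads into per-sample insertion profiles, computes per-gene insertion
    indices and calls essential genes with a two-component gamma mixture,
    scores per-gene fitness as negative-binomial exact-test log2 fold
    changes with Bonferroni correction and a magnitude/significance gate,
    and provides hypergeometric term enrichment and competition-assay
    selection-rate statistics for downstream validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    data.table,
    jsonlite,
    yaml,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    optparse
Config/testthat/edition: 3
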