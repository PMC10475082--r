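Package: methfidelity
Title: Fidelity of CpG Methylation Inheritance Through Clonal Expansion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies how faithfully per-CpG DNA methylation states are
    inherited from a parental cell population through single-cell-derived
    clonal lines. Reads Bismark coverage files, assembles a filtered
    cross-sample CpG matrix, computes per-CpG fidelity and neighbour
    similarity scores, classifies CpGs into methylation groups by k-means
    clustering, conditions clonal outcomes on the parental methylation
    state (including UpSet-style state-combination counts), relates
    fidelity to genomic context (genic tiling by expression quintile,
    transposable elements, histone-mark peaks), and tests de novo
    methyltransferase dependence with per-CpG Fisher exact tests and a
    two-factor analysis of variance. Includes a ground-truthed allele-level
    clonal-expansion simulator so that every pipeline stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
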