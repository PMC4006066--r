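Package: sxrna
Title: Discovery of Trans-Acting Three-Way Junctions Between Small RNAs and
    mRNA Stem-Loop Motifs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scans mRNA sequences for stem-loop RNA-binding-protein motifs
    (histone stem-loop, iron-response element, or user-defined descriptors),
    cofolds each motif region against a query set of small non-coding RNAs,
    and detects trans three-way junctions in which the small RNA splints the
    two flanking segments at the base of the motif stem. Candidates are
    annotated with junction and helix segment geometry, scored against
    configurable thresholds, and classified as motif-stabilizing (inducer)
    or motif-ablating (repressor) interactions. Includes a deterministic
    weighted base-pair-maximization folding backend, an RNAcofold external
    backend, and a seeded synthetic-fixture generator with ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
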