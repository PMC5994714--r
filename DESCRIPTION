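Package: famexscan
Title: Detection and Provenance Analysis of Gene-Family Expansions in
    Bacterial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to census a protein family in an annotated bacterial
    genome and dissect how the family grew. Family members are found by exact
    Smith-Waterman local alignment against characterised query proteins with
    Karlin-Altschul E-values; the genomic landscape is profiled with sliding
    window GC content and GC skew (replication origin and terminus from the
    cumulative-skew reversal), low-GC genomic islands are called by GC
    deviation, and family gene density is contrasted inside versus outside
    islands. Tandem arrays of family genes are censused, and each member is
    classified by its best database hit as a within-genome duplicate
    (lineage-specific expansion), a close-lineage ortholog, or a
    distant-lineage hit (horizontal transfer candidate). A seeded synthetic
    genome generator with full ground-truth labels makes every stage testable
    without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Rcpp,
    jsonlite,
    methods,
    yaml,
    tibble,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
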