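Package: nlrpan
Title: Intra-Species NLR Divergence, Copy-Number Variation and
    Pseudogenization Analysis for Multi-Accession Plant Genome Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classifies plant NLR (nucleotide-binding, leucine-rich-repeat)
    immune receptor genes from annotated genomes by NB-ARC motif content
    (P-loop, Kinase-2, GLPL, MHDV), assigns phylogenetic subgroups via
    alignment, neighbor-joining trees and bootstrap-supported clades,
    projects genes from multiple accessions onto one reference coordinate
    system through unique exact-match anchor chains to build an NLR map,
    catalogues ortholog groups as core, dispensable or accession-specific,
    detects copy-number-variant physical gene clusters with a standard
    deviation filter, chi-square goodness-of-fit tests and
    Benjamini-Hochberg FDR correction, and dissects the mechanism behind
    copy-number changes with a frameshift-aware protein-to-DNA alignment
    that locates premature stop codons, frameshift InDels and large
    insertions.  Ships a multi-accession genome simulator with planted
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    igraph,
    IRanges,
    jsonlite,
    Rcpp,
    rtracklayer,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
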