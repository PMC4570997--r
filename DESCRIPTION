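Package: cladedelim
Title: Mitochondrial Clade Delimitation and Diversity Analysis for DNA
    Barcodes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for delimiting mitochondrial clades in
    DNA-barcode data (COI-5', cytb) and summarising their diversity.
    Computes Kimura 2-parameter distances with pairwise deletion, delimits
    operational taxonomic units by refined single linkage (single linkage +
    Markov clustering + silhouette selection) and by automatic barcode-gap
    discovery with initial and recursive partitioning, builds
    neighbor-joining trees with bootstrap supports, computes haplotype and
    nucleotide diversity, Tajima's D and Fu & Li's D, hierarchical AMOVA
    with permutation tests, minimum spanning haplotype networks, and
    host-parasite divergence-rate comparisons. Includes a coalescent + K80
    simulator generating clade-structured datasets for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    jsonlite,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    cluster
Config/testthat/edition: 3
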