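Package: nemabar
Title: COI Barcoding-Gap Analysis for Free-Living Marine Nematodes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to evaluate the mitochondrial cytochrome c oxidase
    subunit 1 (COI) gene as a DNA barcode for free-living marine
    nematodes: in-silico PCR with degenerate primers (I3-M11 and Folmer
    partitions), translation under the invertebrate mitochondrial
    genetic code with numt screening (stop codons, frameshifts,
    indels), Kimura-2-parameter distances with pairwise deletion and
    codon-position partitioning, neighbor-joining trees with
    long-branch and taxonomic-outlier flags, barcoding-gap threshold
    analysis, and a seeded simulator that generates labelled datasets
    with the statistical structure of a nematode COI barcode survey.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils
Suggests:
    Biostrings,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
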