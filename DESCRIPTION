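Package: hoxwgd
Title: Homeobox Gene Duplication Typing After Whole-Genome Duplication
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers how duplicated homeobox genes arose in lineages carrying
    a single ancestral whole-genome duplication (WGD): ohnologues versus
    ancient or recent tandem duplicates. Combines gene-tree/species-tree
    reconciliation (LCA mapping) with chromosomal linkage classification,
    maps ohnologue losses onto the species tree by Dollo parsimony, detects
    homeobox gene clusters and scores their integrity and ohnologous-pair
    asymmetry, maps chromosome-level orthology and collinear blocks between
    genomes, and computes pairwise dN/dS by the Nei-Gojobori (1986) counting
    method with Jukes-Cantor correction. Ships a forward simulator of genome
    evolution along a WGD-bearing species tree (tandem and dispersed
    duplication, loss, inversion, translocation, fusion/fission, codon-level
    sequence evolution) with a full event log, so every inference stage can
    be validated by event recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
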