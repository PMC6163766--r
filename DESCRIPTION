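Package: PrimerPanels
Title: Greedy Agglomerative Design of Degenerate PCR Primer Panels
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Designs minimal panels of degenerate PCR primer pairs that
    jointly amplify an entire collection of homologous protein-coding
    genes, in silico, by construction. Implements an abundance-seeded,
    similarity-guided agglomerative clustering loop: clusters of similar
    genes are grown codon-aware under an IUPAC consensus, constrained
    degenerate primer pairs are enumerated on each consensus (nearest
    neighbor melting temperatures, degeneracy caps, target window), and
    amplified sequences are removed greedily until the collection is
    exhausted. Includes degenerate in silico PCR with mismatch tolerance,
    specificity screening against decoy collections, coverage and
    genotype-census reporting, and a codon-aware synthetic gene-family
    simulator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
biocViews: Sequencing, Alignment, SequenceMatching, Metagenomics, qPCR
RoxygenNote: 7.3.3
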