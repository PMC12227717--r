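Package: genloss
Title: Comparative Gene Integrity Screening and Loss Mapping on Phylogenies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reference-guided reconstruction of multi-exon genes in genomic
    loci and detection of inactivating mutations (splice-site lesions,
    frameshifting indels, premature stop codons, missing exons), including
    in-frame exon fusions that preserve the reading frame. Shared lesion
    signatures and pseudogene states are mapped onto a species tree under
    Dollo parsimony to count minimum independent gene-loss events, and a
    counting-based selection screen (Nei-Gojobori 1986 pairwise dN/dS with
    Jukes-Cantor correction and a SLAC-style per-site test over Fitch
    ancestors) summarises selective regimes. A sequence-evolution simulator
    plants truth-logged lesions along a phylogeny so every stage can be
    validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
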