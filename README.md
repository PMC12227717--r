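# genloss

Comparative gene-integrity screening and gene-loss mapping on phylogenies.

`genloss` is for molecular evolutionists who want to ask, across a set of
species, "is this gene still alive here — and if not, when did it die?"
It reconstructs a multi-exon gene in pre-extracted genomic loci against an
intact reference template (the role an alpaca orthologue plays for a
cetartiodactyl screen), classifies every inactivating lesion, recognises
reading-frame-preserving structural changes, maps shared lesions onto a
species tree under Dollo parsimony, and runs a counting-based selection
screen. A built-in sequence-evolution simulator plants every lesion class
with a complete truth log, so the whole pipeline is validated against
known ground truth.

## What it computes

For each species × gene, the verdict of the classic presence matrix —
**I**ntact, intact with exon **F**usion, **P**seudogene, or **U**nresolved
(incomplete assembly) — from:

* **Exon mapping** — Smith–Waterman local alignment (affine gaps, match
  +2 / mismatch −3 / gap −5,−2) of each reference exon, colinear by
  construction, with splice donor/acceptor dinucleotides read from fixed
  flanking offsets (GT/AG canonical, GC/AC tolerated non-canonical).
* **Lesion calling** — frameshifting vs in-frame indels, premature STOP
  codons with the frame tracked through indels, splice-site mutations,
  missing exons.
* **Exon fusion** — a mutated donor whose downstream intron has length
  ≡ 0 (mod 3) and a STOP-free read-through fuses two exons into a "super
  exon", adding intron_length/3 residues; this preserves the gene.
* **Dollo loss mapping** — a shared lesion signature (same exon, kind,
  observed sequence, offset bucket) is placed at its carriers' MRCA; the
  minimum number of independent losses is the number of maximal
  carrier-only clades (loss is never reverted).
* **Selection screen** — Nei–Gojobori (1986) pairwise dN/dS with the
  Jukes–Cantor correction d = −(3/4)·ln(1 − 4p/3), a
  foreground/background partition over Fitch ancestral states, and a
  SLAC-style per-site binomial counting test. Outputs are tagged
  `NG86-counting`; this is deliberately not a likelihood method.

## Worked example

Simulate an eight-species scenario with a splice-donor loss on the stem
of a whale-like clade, an extra frameshift in one dolphin, and an
Antilopinae-style exon 11/12 fusion in the sheep/goat clade — then screen
it blind:

```r
library(genloss)

model <- build_reference_model(n_exons = 12, seed = 42)  # 12 exons (2-13), CDS 1977 nt
tree <- "(((Dolphin:1,Porpoise:1)Odo:1,Whale:1)Cet:1,((Sheep:1,Goat:1)Capri:1,(Hippo:1,Cow:1)Anc:1)Terr:1)Root;"
planted <- list(
  splice_event("Cet", 5, "donor", "AT"),
  indel_event("Dolphin", 9, offset = 40, "del", length = 2),
  fusion_event(model, "Capri", 11, intron_length = 99, seed = 7))
sim <- evolve_along_tree(model, tree, sub_rate = 0.005, indel_rate = 2e-4,
                         planted = planted, seed = 42)

verdicts <- lapply(sim$loci, function(l) evaluate_locus(model, l))
render_status_matrix(verdicts, tree)
#>    species simgene
#> 1  Dolphin       P
#> 2 Porpoise       P
#> 3    Whale       P
#> 4    Sheep       F
#> 5     Goat       F
#> 6    Hippo       I
#> 7      Cow       I
```

The three whale-like species are pseudogenes, the sheep/goat pair carries
the non-disrupting fusion (F), and the terrestrial outgroup stays intact.
Mapping the evidence onto the tree:

```r
min_loss_events(vapply(verdicts, `[[`, "", "status"), tree)
#> $n_events
#> [1] 1          # one loss, on the whale-clade stem "Cet"

map_events_on_tree(lapply(verdicts, verdict_signatures), tree)
#>                                    signature               carriers placement_node n_events
#> 1 simgene|exon5|SPLICE_DONOR_MUT|boundary|AT Dolphin,Porpoise,Whale            Cet        1
#> 2         simgene|exon9|FRAMESHIFT_INDEL|13|                Dolphin        Dolphin        1

verdicts$Sheep$fusions[[1]]$incorporated_residues
#> [1] 33         # the 99-nt retained intron adds 33 residues
```

The shared donor mutation is explained by a single event at the whale
stem; the dolphin-private frameshift accumulated later in that lineage —
exactly the planted history.

`run_pipeline(run_config(...))` wraps these stages and writes
`verdicts.tsv`, `lesions.tsv`, `events.tsv`, `loss_events.tsv`,
`dnds.tsv` and a JSON run summary; `inst/cli/genloss.R` is a thin
command-line wrapper around it.

## Limitations

No transcript-evidence channel (exon boundaries are not confirmed by
RNA-seq reads); the splice-rescue scan is a dinucleotide heuristic, not a
splice-strength model; the selection screen is counting-based and its
numbers are not comparable to codeml/HyPhy estimates. See the methods
vignette (`vignettes/gene-integrity-methods.Rmd`) for the full model
description and design rationale.
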