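---
title: "Comparative gene-integrity screening: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative gene-integrity screening: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genloss)
```

## The problem

Gene loss is a recurrent mode of adaptive and neutral evolution: when a
gene's function becomes dispensable in a lineage — as happened to the
δ-subunit gene of the epithelial sodium channel (ENaC) in several marine
mammal lineages — its open reading frame erodes through frameshifting
indels, premature STOP codons, and splice-site mutations. Establishing
*where* on a phylogeny a gene died, and whether related lineages lost it
once or repeatedly, requires (i) reconstructing the gene exon by exon in
each species against an intact reference, (ii) classifying every
inactivating lesion, (iii) recognising structural changes that *look*
drastic but preserve the reading frame (in-frame indels; fusion of two
exons into a "super exon" by loss of a splice donor), and (iv) mapping
shared lesions onto the species tree under an irreversibility assumption.

`genloss` implements this pipeline for pre-extracted genomic loci, plus a
sequence-evolution simulator that plants each class of lesion with a
complete truth log, so every stage is validated against known ground
truth rather than anecdote.

## Reference model and coordinates

A `gene_model` holds ordered exons with phases (cumulative CDS length
upstream, mod 3), expected splice dinucleotides, and optionally intron
sequences and flanks. Exon numbering follows the convention for
multi-exon ENaC-family genes in which the conserved core is exons 2–13,
with the start codon on the first core exon and the STOP on the last;
any strictly increasing numbering is accepted. Internally all
coordinates are 0-based half-open; every human-facing table is 1-based
inclusive. Only the standard nuclear genetic code is supported, and any
codon containing N translates to `X`, which never counts as a STOP.

The configured start exon is authoritative: some terrestrial orthologues
of such genes initiate on an upstream alternative first exon, but
upstream exons are variable and possibly alternatively spliced, so the
screen restricts itself to the conserved core and does not search
upstream.

## Exon mapping

Each exon is located in the target locus by local alignment
(Smith–Waterman with affine gaps via `Biostrings::pairwiseAlignment`),
with BLAST-like scores (match +2, mismatch −3, gap open −5, gap extend
−2) suited to within-order mammalian divergence. Colinearity is enforced
by construction: exon *k* is searched downstream of exon *k − 1*'s hit,
with a 50-nt look-back for micro-overlaps, and the search window is
bounded using the model's own intron sizes (with an unbounded retry on
failure), which keeps the screen fast without assuming anything not in
the model. A hit requires identity ≥ 0.6 over ≥ 60% of the exon; an exon
that fails is reported `found = FALSE` — absence is data.

Because a local aligner clips terminal mismatches, hit boundaries are
snapped outward over unaligned exon ends so that the donor (2 nt 3′ of
the exon) and acceptor (2 nt 5′) are always read from fixed offsets.
Strand is resolved by a vote of exon-derived 12-mers on both strands;
ambiguous cases (high divergence, or no gene at all) fall back to summed
best-exon alignment scores, and a locus in which neither strand yields
an acceptable exon is a "no gene found" error.

## Lesion classification

Splice dinucleotides are classified as canonical (GT donor / AG
acceptor), tolerated non-canonical (GC donor / AC acceptor — the rare GC
donor occurs natively in these genes, e.g. flanking exon 6), or mutated;
N makes the call low-confidence. Alignment gap runs become indel
lesions; runs separated by ≤ 10 matched bases are merged first, because
local aligners can split one event or render clustered mismatches as an
offsetting insertion/deletion pair (a merged net of exactly zero is
treated as substitutions, not a lesion). A net length that is a multiple
of 3 is recorded as a non-disrupting in-frame structural note — a 3-nt
microdeletion preserves the reading frame and the gene. In-frame STOP
codons are detected while tracking the observed frame through indels;
STOPs that only exist because of an upstream frameshift are tagged
`frameshift_consequence` and attributed to that frameshift rather than
treated as independent evidence. A STOP within the final 30 nt
(configurable) of the terminal exon is taken as the true terminator
shifted, reflecting natural terminal-exon length variation.

## Fusion and rescue reconciliation

A mutated donor is not always a death sentence. If the intron it
precedes has a length divisible by 3 and reading through it in the
running frame meets no STOP, the intron is retained in the mRNA and the
two exons fuse into a "super exon": a 99-nt retained intron adds exactly
33 residues. Such a fusion call downgrades the donor lesion to
non-disrupting (it stays in the report), and a gene whose only anomaly
is a fusion is `INTACT_FUSION`, never a pseudogene.

Separately, a mutated splice flank may be rescued by a nearby
alternative site. Full splice-site models are out of scope; the scan
implemented here accepts the nearest canonical dinucleotide within ±30
nt whose use preserves frame (offset ≡ 0 mod 3) and introduces no new
in-frame STOP. This is deliberately permissive — a +7-nt alternative
donor, for example, is correctly rejected because it breaks frame — and
a rescued lesion is likewise kept in the report as non-disrupting.

## Verdicts

Per species and gene: `INCOMPLETE` when an exon is unresolved *and* the
locus carries an assembly-gap N-run ≥ 50 nt; otherwise `PSEUDOGENE` when
any disrupting lesion survives reconciliation or the assembled CDS fails
to yield a single terminal STOP; otherwise `INTACT_FUSION` or `INTACT`.
A pseudogene call resting solely on splice-site evidence carries the
flag `splice_only`, mirroring the appropriate hedging when no transcript
evidence backs a splice-level inference. Status codes I/F/P/U match the
blue/turquoise/magenta/grey semantics of the usual presence matrices.

## Dollo loss mapping

Two species share a lesion *signature* when gene, exon, kind, observed
sequence and offset bucket all agree (0-nt tolerance for splice lesions,
which sit on a fixed boundary; 3 nt for indels, absorbing
assembly-specific gap wobble). Loss is modelled as a gains-only Dollo
character: a pseudogene never reverts. The minimum number of independent
events for a signature (or for the pseudogene state itself) is the
number of maximal subtrees whose informative tips are all carriers;
`INCOMPLETE` tips are compatible with either state and never force an
extra event. Polytomies are hard, which is conservative. On trees of ≤ 8
tips this count is verified exhaustively against all gain-edge subsets
in the test suite. STOPs tagged as frameshift consequences are excluded
from signature sharing, since they are derived, not primary, evidence.

## Counting-based selection screen

The screen is an explicitly simplified counting analogue of
likelihood-based selection tests, and every output carries
`method = "NG86-counting"` so its numbers are never mistaken for ML
estimates. Pairwise dN/dS follows Nei–Gojobori (1986): fractional
synonymous site counts per codon over non-STOP single-nucleotide
mutants, pathway-averaged difference counts (orderings through STOP
codons excluded; codon pairs with no STOP-free pathway are skipped and
counted), and the Jukes–Cantor correction `d = −(3/4) ln(1 − 4p/3)`,
undefined at `p ≥ 3/4` (saturation is flagged). `omega` is `Inf` when
`dS = 0` with `dN > 0` and undefined when both are 0.

For branch partitions, nucleotide ancestral states are reconstructed by
Fitch parsimony (ties prefer the parental state, then alphabetical
order, so results are deterministic given the rooted tree), per-edge
changes are counted codon-wise with the same pathway averaging, and
edges inside the foreground clade (stem included) are pooled against the
rest. The SLAC-style per-site test sums changes per codon site over all
edges and applies a two-sided exact binomial test against the site's
neutral expectation `n/(n + s)`; pathway-averaged counts are rounded to
integers for the test only. No multiple-testing correction is applied by
default (per-site reporting convention); Benjamini–Hochberg is available
by flag.

## The simulator and what passing tests mean

`evolve_along_tree` evolves the reference locus along a phylogeny:
Jukes–Cantor substitutions and background indels per branch (Poisson in
rate × length × sites), then planted events, inherited by all
descendants — Dollo-consistent by construction. Per-branch random
streams are derived from the master seed and the branch label, so
adding an event on one branch never changes the background elsewhere,
and identical configuration plus seed reproduces every output byte for
byte.

The simulator's purpose is unambiguous ground truth, and several
guard-rails serve that purpose rather than realism:

* splice dinucleotides, exon junction bases (terminal 2 nt of each
  exon), the start codon and the terminal STOP are masked from
  background substitution;
* exonic substitutions are rejection-sampled so they never create a
  STOP codon in any reading frame;
* background indels fall only in intron interiors (1–10 nt, geometric);
* around a planted splice mutation, frame-preserving canonical
  dinucleotides in the rescue-scan window are scrubbed and the window is
  then frozen against later substitutions (no chance rescue site can
  appear); a retained fusion intron is protected from substitution; and
  the intron behind a planted (non-fusion) donor mutation receives a
  block containing a STOP in all three frames so read-through can never
  masquerade as a clean fusion.

Consequently, passing recovery tests demonstrate that the detector
recovers exactly the planted signal under calibrated background noise.
They do not demonstrate robustness to features real data have and the
simulator deliberately lacks: stop codons arising from background
drift, exonic background indels, splice-region drift, sequencing error,
or paralogous loci. Default generator conditions are an ENaC-like
12-exon gene (exons numbered 2–13), exons 80–250 nt, introns 100–400 nt
(δ-subunit-like genes are condensed, with small introns), GT donors
with an optional GC fraction, and AG acceptors.

## Problem sizes and numerical choices

The validation suite runs, per invocation: 200 simulated loci for
recovery at zero divergence and 200 at 1% divergence with background
indels (eight-tip random trees, events covering all seven kinds, every
fourth locus reverse-complemented); the full 61 × 61 sense-codon oracle
comparison; 500 random Dollo scenarios on trees of 3–8 tips against
exhaustive search; 50 neutral replicates for per-site type-I
calibration at α = 0.1 and 20 replicates for directional recovery of a
relaxed foreground (nonsynonymous acceptance 0.1 on background edges).
These sizes give stable pass/fail behaviour across seeds while keeping
a full run in the order of minutes on one core.

Tie-breaks and degenerate inputs are fixed deterministically: equal
local-alignment placements resolve leftmost; rescue-scan ties resolve
to the smallest shift, upstream first; Fitch ties prefer the parental
state then alphabetical; an empty CDS, a STOP codon given to the site
counter, and a foreground that is not a clade are errors, while a
codon pair with no STOP-free pathway is skipped and logged.

## Known limitations

* No transcript-evidence channel: exon boundaries cannot be confirmed
  by intron-spanning reads, and out-of-frame pseudo-exon inclusions are
  not called.
* The rescue scan is a dinucleotide heuristic, not a splice-strength
  model; at realistic divergence it occasionally downgrades a genuine
  splice lesion on the strength of a chance in-frame GT (verdicts at
  zero divergence are unaffected; the lesion stays in the report).
* The selection module is counting-based: no rate variation, no
  branch-site machinery, no hypothesis tests on omega itself.
* Ordering of multiple lesions within one dead lineage is not modelled,
  only counted; loss dating is out of scope.
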