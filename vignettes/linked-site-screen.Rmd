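---
title: "The linked-site screen: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The linked-site screen: model, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motiflink)
```

## The screen

`motiflink` looks for a specific cis-regulatory architecture: a SOX9
binding site and a GLI binding site, each perfectly conserved between a
reference and a partner genome, separated by at most a fixed spacing inside
non-coding sequence, and attributable to a gene. The biological setting is
the growth plate: GLI2/3 repressors and SOX9 cooperating on enhancers of
hypertrophic-chondrocyte genes keep those genes off in earlier
differentiation stages, so genes carrying the linked-site architecture in
conserved non-coding regions are candidates for this mode of regulation.

The screen is a deterministic filter chain:

* **Consensus scan.** Motifs are IUPAC consensus strings, matched exactly:
  an ambiguity code in the motif admits any of its bases, while an `N` in
  the scanned sequence never matches (so masked genome never produces
  hits). Both strands are scanned by default; a minus-strand hit is stored
  with forward-axis coordinates and the forward-strand substring, so all
  downstream interval arithmetic lives on one axis. There is deliberately
  no position-weight-matrix scoring: the site classes screened here are
  defined by consensus, and a consensus scan has no tunable score
  threshold to calibrate.

* **Perfect conservation.** A hit passes only if, at every alignment column
  holding one of its reference bases, the partner species' row is present,
  ungapped, and identical. A single gap breaks the call because an indel
  destroys a binding site even when flanking identity is high. Conservation
  is decided against exactly one partner (default `human`); the
  six-species conservation percentage reported alongside each pair is
  descriptive output, never a filter — the panel species beyond the partner
  document how deeply the window is conserved but do not gate it.

* **Non-coding restriction.** "Non-coding" means outside annotated exons,
  UTR exons included — the conservative reading when the elements of
  interest lie wholly outside transcripts' exonic sequence. A config switch
  (`exclude = "cds"`) narrows the exclusion to coding exons where the
  annotation provides them. Where genes overlap, exonic always wins: a base
  inside any exon is not non-coding for any gene.

* **Pairing.** Any SOX9 hit and GLI hit on one chromosome with inner gap
  (end of the leftmost site to start of the rightmost) between 0 and
  `max_spacing` form a pair, in either axis order and any strand
  combination — orientation is reported, not filtered. The 100 nt default
  bound is inclusive; a `strict` flag flips it, since "within 100 nt" is
  read inclusively here but an exclusive reading is defensible.
  Overlapping hits are never pairs: spacing presupposes separated sites.

* **Gene assignment.** A pair inside one or more gene spans belongs to all
  of them; an intergenic pair goes to the nearest gene by edge distance up
  to `max_flank` (default 50,000 nt), with ties assigned to every tied
  gene. The attribution rule for intergenic sites is a package choice — no
  single convention is standard — so the nearest-gene rule and its flank
  are surfaced as prominent parameters rather than buried defaults.
  Positivity is boolean per gene: one pair or ten make the same call,
  because the enrichment statistics count genes, not pairs.

* **Exact statistics.** Over-representation of positive genes in a set of
  `n` genes is the hypergeometric upper tail against a genome of `N` genes
  containing `K` positives; the contrast between two sets is the one-tailed
  Fisher exact test, which is the same tail on the pooled 2×2 margins. `K`
  has no default on purpose: it is a measured property of the reference
  annotation and alignment in use, and silently assuming one would make
  the genome test meaningless. No multiple-testing correction is applied
  (the report says so); with two sets and one contrast there is nothing
  principled to correct.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| SOX9 consensus | `WWCAAWG` | IUPAC | the heptamer site class (COL2C1-type) first defined in the *Col2a1* intron-1 enhancer |
| GLI consensus | `GACCACCCA` | IUPAC | the canonical GLI1/2/3 9-mer |
| TCF consensus | `CTTTGWW` | IUPAC | TCF/LEF core; used only to annotate sites between a pair |
| `max_spacing` | 100 | nt | the linked-site definition; inclusive bound |
| `partner_species` | `human` | — | the conservation filter partner for a mouse reference |
| `max_flank` | 50,000 | nt | intergenic gene-assignment radius |
| `exclude` | `exons` | — | what counts as coding space |

The motif strings are editable config defaults (`motif_set()`,
`read_motifs()`), not constants: the exact consensus used by any published
screen of this architecture is a choice, and this package's defaults follow
the literature conventions for each factor. A dimeric SOX9 arrangement
(two heptamers head-to-head with a short spacer) can be expressed as an
additional motif entry; the default scan uses the single consensus.

## What the synthetic data emulates — and what it does not

`simulate_dataset()` generates one locus per gene on its own chromosome:
i.i.d. reference sequence at 42% GC (mouse-like), a two-exon gene body in
the middle of the locus, and, with per-gene probability `f`, one planted
pair — SOX9 and GLI instances drawn uniformly from the sequences satisfying
each consensus, uniform strands and axis order, spacing uniform on 0–100 nt,
placed uniformly in non-exonic space. Non-reference species derive from the
reference by per-base substitution (default 10%) and single-base deletion
(default 1%) on a star phylogeny; planted windows are exempt when
`protect_planted` is on, making planted sites perfectly conserved. The
default study shape is two gene sets of 11 and 14 genes planted at 6/11 and
2/14 — the positive fractions observed in the chondrocyte gene sets this
screen was designed around — so the enrichment stage has a realistic
ground-truth contrast.

Deliberately not emulated: phylogenetic structure (substitutions are
independent per species; no HKY-style rate matrix), indel length
distributions (all indels are single-base deletions, so the alignment never
contains reference-gap columns), local GC heterogeneity, repeats, and
alignment error. Tests passing on this generator therefore demonstrate the
*logic* of the pipeline — coordinate bookkeeping, filter correctness, exact
recovery, calibrated statistics — not robustness to real alignment
artifacts. On real multiz alignments, block fragmentation and alignment
error will cost sensitivity that the synthetic data cannot measure.

Insertions relative to the reference are the one alignment feature the
conservation checker would interact with that the generator omits: an
insertion column carries a reference gap and is skipped when a motif window
is mapped to columns, so a partner insertion strictly inside a site does
not break the perfect-conservation call. This is a known, documented
leniency; deletions and substitutions — the events the generator does
produce — are handled strictly.

## Numerical choices

* All coordinates are 0-based half-open on the forward reference axis (BED
  convention); converters at the boundary handle 1-based biological
  positions, and `tss_relative_interval()` maps promoter-relative boundary
  coordinates (e.g. −4286 to −3646) to half-open intervals — that example
  spans 640 bp.
* Binomial coefficients are computed as a sum of logs over the shorter
  factor sequence, which keeps the hypergeometric pmf normalized to 1
  within 10⁻¹² even at genome scale; plain log-gamma differences lose
  about 10⁻¹² of absolute accuracy at N in the tens of thousands, which is
  why they are used only as a fallback for very large arguments. Tail sums
  use log-sum-exp and are clipped to [0, 1].
* The hypergeometric tail returns 1 directly whenever `k` is at or below
  the support's lower bound `max(0, n − (N − K))`, avoiding log terms for
  impossible outcomes.
* Hits spanning two alignment blocks are dropped and counted in a message
  rather than stitched: multiz block boundaries rarely split a ≤ 9 nt
  motif, and stitching would require re-deriving coordinates across blocks
  with no way to validate the result.
* A window with no aligned panel species reports 100% conservation with
  `species_present` reduced to the reference — keeping the metric total
  while letting downstream reporting flag vacuous conservation.
* Ties and ordering: hits sort by start then strand (`+` first), pairs by
  window start; gene assignment sorts tied gene ids lexicographically — all
  outputs are deterministic for identical inputs.

## Problem sizes in the test-suite and acceptance script

The property suites run at sizes chosen to give stable statistics at
interactive runtimes: scanner-vs-oracle equivalence on 110 random
sequence/motif instances; planted-pair sensitivity on 200 noiseless loci
(every planted pair must be recovered at its exact coordinates and
spacing); background specificity on 600 unplanted loci of 3 kb, compared to
the analytic expectation with a Poisson-scale standard error — the
model-based SE is used rather than the sample SD so that a legitimately
zero-count draw cannot produce a degenerate zero-width band; null
calibration of the one-tailed Fisher test over 2,500 random assignments.
Larger sizes change none of the conclusions; the law-of-large-numbers check
on the planting fraction runs at 2,000 loci.

## Limitations

* The genome-scale positive count `K` must come from outside (a full-genome
  run of this pipeline on real alignments, or a published figure); without
  it only the two-set Fisher contrast is available.
* Perfect conservation against a single partner is a hard filter: a single
  sequencing or alignment error in the partner genome removes a true site.
  The descriptive panel percentage gives no protection against this.
* The nearest-gene assignment rule is a convention, not a discovery; sites
  regulating a non-nearest gene will be mis-attributed, and the 50 kb flank
  excludes long-range enhancers by construction.
* Consensus matching is all-or-nothing; degenerate but functional sites
  scoring just off-consensus are invisible to the screen.
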