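---
title: "Paralogon detection and relative dating of whole-genome duplications"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Paralogon detection and relative dating of whole-genome duplications}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paralogon)
```

## The problem

Vertebrate genomes passed through two rounds of whole-genome duplication
(tetraploidization) at the base of vertebrate evolution — collectively
"2R" — and teleost fishes through a third, "3R". A gene family that was
single-copy before 2R can therefore have up to four early-vertebrate
subtypes, each potentially doubled again in teleosts into "a" and "b"
ohnologs. The chromosome regions that carry such families form
*paralogons*: sets of chromosome segments, within and across genomes,
that descend from one ancestral region via these doublings and are
recognizable because many neighboring families duplicated together.

Subsequent chromosome fusions, fissions and translocations — especially
in teleost lineages — scramble this signal. The central inferential move
this package implements is *relative dating*: a duplication node in a
gene tree is placed into a time window bounded by speciation events,
using only which taxa appear in its descendant clades. Combined with
gene positions, this both (i) tests whether neighboring families
duplicated in the 2R and 3R windows (conserved-synteny support for the
tetraploidizations) and (ii) times chromosome rearrangements relative to
3R: when many families have *2R-generated* paralogs co-located on one
teleost chromosome — rather than 3R a/b duplicates — the blocks must
have fused *before* 3R.

The motivating application is the somatostatin receptor (SSTR) family:
six ancestral vertebrate subtypes (SSTR1–6, with SSTR6 lost in tetrapods
and SSTR4 in ray-finned fishes), two paralogons (one bearing SSTR1/-4/-6,
one SSTR2/-3/-5), and a teleost history of pre-3R fusions followed by
post-3R paralog exchange and a fission. Its locus table, the two
neighbor-family lists (17 + 30 = 47 families), a species tree with WGD
placements, and the evolutionary scheme as an explicit, replayable event
history all ship as fixtures (`sstr_genomes()`, `sstr_neighbor_families()`,
`sstr_species_tree()`, `sstr_evolution_history()`, `sstr_gene_tree()`).

## Reconciliation and relative dating

`reconcile()` performs Zmasek–Eddy LCA mapping: each gene-tree node maps
to the species-tree most recent common ancestor of its leaf species, and
a node is a duplication exactly when its mapping equals the mapping of
at least one child. Trees are consumed, never inferred; supports are
read from internal node labels, with scale auto-detection (values all
≤ 1 are treated as fractions and multiplied by 100). Polytomies are
processed as-is with a warning; the mapping rule does not require binary
resolution.

A `duplication_window(label, older, younger)` is a pair of named
species-tree nodes with `older` strictly ancestral to `younger`; a
duplication is assigned to the window when its mapped node lies on the
path strictly after `older` and at-or-before `younger`
(`date_duplication_nodes()`). Duplications mapping to a single extant
taxon are `lineage_specific`; anything else outside every window is
`other`. Windows must be disjoint — overlap is a configuration error.
In the packaged species tree the 2R window runs from the deepest
outgroup split (the fruit fly divergence; no tunicate or amphioxus taxon
is packaged, so this is the closest available older bound) to the
lobe-finned/ray-finned split, and the 3R window from the gar–teleost
split to the teleost crown. Both are names in the config, not
hard-coded taxa.

One consequence worth knowing: for a family whose *two ancestral genes*
predate vertebrates (as proposed for the SSTR family), the basal split
of the family also LCA-maps into the 2R window, so a whole-family
analysis merges the two paralogons into one component. The study's own
design — two separate screens, one per ancestral branch — avoids this,
and the packaged analyses do the same by restricting to the relevant
subtype branch.

`classify_family_verdict()` codifies the per-family evidence levels as a
tri-state: `supports_WGD` when any provided tree (e.g. ML and NJ) holds
a window-dated duplication at or above the support threshold (default
50%, matching the usual bootstrap convention), `consistent` when such a
duplication exists only below threshold, `inconclusive` otherwise. The
source analyses describe method disagreement narratively rather than as
a formal rule; this tri-state is an explicit codification and is
documented as such here.

`assign_subtype_and_ab()` assigns a query gene the subtype of the
smallest clade containing it and reference leaves of exactly one
subtype, and resolves teleost a/b labels at the oldest 3R-window
duplication above the query — polarity anchored by a designated
a-reference leaf, or, absent one, by the cluster containing the
alphabetically first species (some convention is required; this one is
deterministic). Queries basal to all reference clades are returned as
`unassignable`, never guessed.

## The conserved-synteny screen

`define_block()` builds the screening unit: an interval ±15 Mb (the
study's radius, tunable) around the focal gene's midpoint, clamped to
the chromosome — often the whole chromosome for compact genomes.
Membership of a family in a block uses the locus midpoint against the
half-open interval; a midpoint exactly at the block end is excluded, an
unambiguous and testable convention. One member suffices for a family to
count as "represented" (the sources do not state a threshold;
`min_members` makes it configurable).

`select_neighbor_families()` implements both screen designs through one
`anchor_spec`: *dual-anchor* (families on both primary-genome blocks,
plus families on both secondary-genome blocks that appear on at least
one primary block — the SSTR1/-4 design) and *triple-anchor* (families
on all three blocks of either genome — the SSTR2/-3/-5 design). The
focal family itself is included by default, since it is part of its own
paralogon's evidence.

## Paralogon assembly and rearrangement timing

`classify_gene_copies()` converts a dated, reconciled family tree into
per-leaf duplication-path classes: which side of each 2R-window
duplication (the `twor_class`) and each 3R-window duplication (the
`threer_copy`) a gene descends from. Genes of one family with different
2R classes are 2R-window paralogs; same 2R class but different 3R copy
are a/b ohnologs.

`assemble_paralogons()` builds a graph over (species, chromosome)
regions, joining two regions when they hold 2R-window paralogs of the
same family, and keeps edges supported by at least `min_support = 2`
distinct families: a single shared family — typically the focal family
itself — cannot distinguish synteny from coincidence, and the evidence
in this kind of analysis is always multi-family. Paralogons are the
connected components. Evidence granularity is the chromosome, matching
per-chromosome location charts; sub-intervals appear only in small-block
calls.

`infer_fusion_timing()` applies the signature timing argument per
chromosome: count families with co-located distinct 2R classes (n2) and
families with co-located a/b copies of one class (n3). With n2 at or
above `min_support` and in the majority, the chromosome records a fusion
`before_3R`; an n3 majority gives `after_3R` (the co-location was
created by rearrangement after the doubling); ties are `indeterminate`,
and genomes whose lineage never passed the 3R marker can only yield
`indeterminate` calls. Majority voting across families is used because
individual trees can mis-assign single genes.

`infer_block_rearrangements()` compares orthologous units (family + 2R
class + 3R side) between a reference and a derived genome: units
confined to one reference chromosome whose derived counterparts are
split across chromosomes mark translocations, and displaced genes within
`window_mb` (default 1 Mb) of each other on one derived chromosome merge
into a single block call with its interval.

## Scenario reconstruction

`reconstruct_scenario()` turns calls and classes into an ordered,
*replayable* event history for one derived lineage: an inferred pre-3R
ancestor, pre-3R fusions, the 3R doubling with the observed ohnolog
retention, then post-3R translocations and fissions that carry each
informative gene to its observed chromosome. Pre-3R chromosomes are
formed by grouping (family, 2R-class) units with identical
tip-chromosome signatures, merged when a `before_3R` fusion call
co-locates them; this deliberately reconstructs only the paralogon
regions, not a genome-wide ancestral karyotype. Post-3R translocations
have no resolvable relative order and are flagged as an unordered group;
contradictory timing on one chromosome is reported in `conflicts`, never
silently resolved. The history must include the 3R doubling itself to be
replayable, so "no inferred rearrangements" yields a history whose only
event is the WGD. Replay equality is judged on the partition of
(family, 2R-class, 3R-side) labels over chromosomes: coordinates are
re-spaced by design and within-chromosome order is not reconstructed.

## The genome-evolution simulator

`simulate_history()` evolves an ancestral genome along a species tree
under WGDs (at the tree's markers), gene loss, fusion, fission, block
translocation, intrachromosomal shuffling and tandem duplication,
returning tip genomes, true gene trees, an ohnolog map and the sampled
history as a fully explicit `event_history()` that `replay_events()`
reproduces exactly. Design choices:

- **Immediate Bernoulli retention.** Each post-WGD copy survives with
  `ohnolog_retention_prob`, applied immediately. Real losses are spread
  over time; immediate loss changes branch lengths of pruned lineages
  but not the topology or window content of surviving duplications,
  which is all the inference consumes.
- **Uniform re-spacing.** Coordinates after rearrangement are re-spaced
  at 1 Mb per gene rather than tracking bp-level breakpoints: every
  inference stage uses only order and co-location.
- **Explicit payloads.** Every sampled event is recorded with enough
  detail (copies lost, breakpoints, block gene ids, orientations) that
  replay is deterministic with no randomness.
- **One global generator**, seeded once; events are sampled branch-major
  in preorder, with per-branch Poisson counts split across the segments
  a WGD marker induces, in proportion to segment length. This is what
  lets a planted event be placed "before" or "after" a named WGD.
- **Defaults.** 30 families on 2 ancestral chromosomes, retention 0.8,
  all rearrangement rates 0 (events are planted or switched on
  explicitly). The sources quantify neither loss nor rearrangement
  rates, so these are package choices: retention 0.8 keeps most
  families informative for synteny (empirical ohnolog retention in
  well-studied paralogons is high), and zero default rates make every
  rearrangement in a test attributable.

What the simulator does **not** emulate: sequence evolution and hence
realistic tree-inference error (perturbation is modeled separately as
random NNI moves via `perturb_gene_tree()`), assembly artifacts
(unplaced scaffolds, missing genes), delayed loss, and gene-order decay
within blocks. Passing recovery tests on simulated data therefore shows
the inference logic is sound under its stated model, not that real
genome databases meet that model.

## Numerical and formatting conventions

- Coordinates are 0-based, half-open; printed point positions become
  1-bp loci at the printed coordinate, converted exactly
  (38.68 Mb → 38,680,000 bp; no re-rounding).
- Mb distances are midpoint-based; "approximately N Mb" comparisons use
  round-half-up to integer (`round_mb()`: 7.99 → 8, 10.95 → 11,
  4.62 → 5).
- Unplaced scaffolds carry `placed = FALSE` and refuse distance, span
  and block computations. The medaka SSTR2b scaffold printed at 160 bp —
  shorter than a gene — is marked unplaced in the fixture. Chromosome
  lengths not printed in the sources are synthetic: last locus + 30 Mb
  (placed) or + 100 Kb (scaffolds); stated lengths (stickleback LG
  V/IX/XI, chicken 14/18) are used verbatim.
- Two source-internal discrepancies are preserved, not reconciled: the
  green puffer SSTR2a/-3a pair is placed on chromosome 3 by the locus
  table but on chromosome 8 by the running text (the fixture follows the
  table), and the stickleback SSTR2a/-3a/-5a span computes to 6.09 Mb
  from the printed coordinates versus "9 Mb" in the text.

## Problem sizes

The test suite and the acceptance script run simulations at 12–30
families on 2 ancestral chromosomes over 5-taxon trees, 500 random
gene trees (≤ 10 leaves) for the reconciliation cross-check, and 20
seeded replicates for planted-fusion recovery — sizes chosen so each
property is exercised across many independent draws while a full run
stays interactive.

## Known limitations

- LCA reconciliation is parsimony-style: incomplete lineage sorting or
  tree error inflates duplications; the verdict layer (support
  thresholds, two-method rule) mitigates but does not remove this.
- Window dating inherits the species tree: a missing outgroup widens the
  older bound of the 2R window (as with the packaged tree's fly-only
  outgroup).
- Fusion timing is evidence-based per chromosome; it cannot distinguish
  one fusion from several that produced the same co-location, and
  reports at most one call per chromosome.
- Scenario reconstruction is per-lineage and minimal: it reproduces the
  observed gene-to-chromosome partition, not gene order, and its
  ancestor covers only the paralogon regions.
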