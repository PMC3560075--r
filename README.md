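# paralogon

Detection of paralogons — chromosome regions related by whole-genome
duplication (WGD) — and relative dating of the duplications that formed
them, from gene coordinate tables, gene-family trees and a species tree.

## The problem and who this is for

Early vertebrate evolution included two rounds of whole-genome
duplication ("2R") and the teleost fish lineage a third ("3R"). A
single-copy ancestral gene can therefore have several vertebrate
*subtypes* plus teleost *a/b* ohnolog pairs, and the chromosome regions
carrying such genes form paralogons recognizable by many neighboring
families having duplicated together. Later chromosome fusions, fissions
and translocations (rampant in teleost genomes) obscure the pattern.
This package is for comparative genomicists who want to:

- screen chromosome blocks around focal genes for syntenic neighbor
  families (±15 Mb blocks, dual- or triple-anchor selection rules);
- date duplication nodes of gene trees into named windows by
  gene-tree/species-tree reconciliation and relative dating;
- assemble paralogons from positional + timing evidence and infer
  chromosome fusions with timing relative to 3R;
- reconstruct replayable rearrangement scenarios; and
- validate all of the above against a genome-evolution simulator with
  known truth.

## The method in brief

Reconciliation uses LCA mapping: gene-tree node *v* maps to
*M(v)* = the species-tree MRCA of its leaf species, and *v* is a
**duplication** iff *M(v) = M(c)* for some child *c*. A duplication is
dated to window *(older, younger]* — e.g. the 2R window from the
invertebrate/vertebrate divergence to the lobe-finned/ray-finned split —
iff *M(v)* lies on that species-tree path. Genes of one family on
different chromosomes whose classes are separated by a 2R-window
duplication are 2R paralogs; regions sharing ≥ 2 such families are
linked into paralogons (connected components of the region graph). The
timing rule for fusions: co-location of **2R-generated paralogs** of
many families on one teleost chromosome ⇒ the blocks fused **before
3R**; co-location of only 3R a/b duplicates ⇒ rearrangement **after
3R**; family-majority vote, ties indeterminate.

The somatostatin receptor (SSTR) system ships as the worked fixture: the
locus table across 15 genomes, the 17 + 30 syntenic neighbor-family
lists, a dated species tree with the 2R/3R markers, the family tree with
the six subtype clades (SSTR1–6), and the full evolutionary scheme as an
explicit event history.

## Worked example

```r
library(paralogon)
genomes <- sstr_genomes()

locus_distance_mb(genomes$zebrafish, "zebrafish_SSTR2a", "zebrafish_SSTR3a")
#> [1] 33.33

define_block(genomes$human, "human_SSTR1")
#> block human:14 [23.68, 53.68] Mb around human_SSTR1
```

The zebrafish SSTR2a–SSTR3a pair sits 33.33 Mb apart on chromosome 3
(the "approximately 33 Mb" co-location produced by a pre-3R fusion), and
the ±15 Mb screening block around human SSTR1 is the 23–53 Mb window of
chromosome 14 used to collect neighbor families.

Replaying the SSTR evolutionary scheme along the species tree gives each
lineage's expected repertoire; gene ids carry their duplication path:

```r
st <- sstr_species_tree()
tips <- replay_events(sstr_evolution_history(), sstr_ancestral_genome(), st)
sort(tips$zebrafish$loci$gene_id)
#> [1] "SSTR145anc_2R-aA_2R-bA_3RA" "SSTR145anc_2R-aB_2R-bA_3RA"
#> [3] "SSTR235anc_2R-aA_2R-bA_3RA" "SSTR235anc_2R-aA_2R-bA_3RB"
#> [5] "SSTR235anc_2R-aA_2R-bB_3RA" "SSTR235anc_2R-aA_2R-bB_3RB"
#> [7] "SSTR235anc_2R-aB_2R-bA_3RA" "SSTR235anc_2R-aB_2R-bA_3RB"
```

Eight genes — SSTR1 and SSTR6 single copies plus a/b pairs for SSTR2,
-3 and -5 — exactly the known zebrafish repertoire. Dating the packaged
SSTR family tree recovers the expected window structure:

```r
rt <- reconcile(sstr_gene_tree(), st)
table(date_duplication_nodes(rt, sstr_windows())$window)
#>        2R_window        3R_window lineage_specific
#>                5                3                3
```

Five early-vertebrate duplications (the subtype splits), three teleost
a/b duplications, and three lineage-specific duplicates (the fly
receptor pair, the coelacanth SSTR2-like extra gene, the green puffer
third SSTR3).

For pipelines: `simulate_history()` generates genomes + true trees +
truth log; `run_pipeline()` chains screen → verdicts → paralogons →
fusion calls → scenario and writes TSV/JSON reports; a thin CLI lives at
`inst/cli/paralogon`.

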