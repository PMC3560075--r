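pkg_extdata <- function(file) {
  path <- system.file("extdata", file, package = "paralogon")
  if (!nzchar(path)) stop("packaged fixture not found: ", file)
  path
}

#' Packaged SSTR gene loci across vertebrate genomes
#'
#' Point coordinates of the somatostatin receptor (SSTR) repertoire in
#' 15 species, stored as 1-bp loci at the printed position with a
#' chromosome-length sidecar. Unplaced scaffolds carry `placed = FALSE`
#' and are excluded from distance computations.
#'
#' @return named list of [genome()] objects.
#' @export
sstr_genomes <- function() {
  read_gene_table(pkg_extdata("sstr_loci.tsv"),
                  pkg_extdata("sstr_chromosomes.tsv"))
}

#' Species tree for the SSTR study taxa
#'
#' Rooted on the fruit fly, with the 2R-a/2R-b markers on the
#' vertebrate stem and the 3R marker on the teleost stem.
#'
#' @return a [species_tree()].
#' @export
sstr_species_tree <- function() {
  read_species_tree(pkg_extdata("sstr_species_tree.yaml"))
}

#' Relative-dating windows for 2R and 3R
#'
#' The 2R window runs from the deepest outgroup divergence in the
#' packaged species tree to the lobe-finned/ray-finned split; the 3R
#' window from the gar-teleost split to the teleost crown.
#'
#' @return data.frame of [duplication_window()] rows with labels
#'   `2R_window` and `3R_window`.
#' @export
sstr_windows <- function() {
  rbind(duplication_window("2R_window", "protostome_deuterostome_split",
                           "sarcopterygian_actinopterygian_split"),
        duplication_window("3R_window", "gar_teleost_split",
                           "teleost_crown"))
}

#' Packaged neighboring gene-family lists
#'
#' The pre-selected syntenic families for the two SSTR paralogons: 17
#' families for the SSTR1/-4/-6-bearing chromosome blocks, 30 for the
#' SSTR2/-3/-5 blocks.
#'
#' @param which `"SSTR146"`, `"SSTR235"` or `"both"`.
#' @return data.frame with columns `symbol`, `description`, `root`.
#' @export
sstr_neighbor_families <- function(which = c("both", "SSTR146", "SSTR235")) {
  which <- match.arg(which)
  rd <- function(f) {
    x <- utils::read.delim(pkg_extdata(f), comment.char = "#",
                           stringsAsFactors = FALSE)
    x$root[is.na(x$root)] <- ""
    x
  }
  t146 <- rd("sstr146_neighbor_families.tsv")
  t235 <- rd("sstr235_neighbor_families.tsv")
  switch(which, SSTR146 = t146, SSTR235 = t235,
         both = rbind(t146, t235))
}

## ids used by the SSTR evolutionary scheme; the suffix chain encodes
## the duplication path through 2R-a, 2R-b and 3R
sstr_id <- function(root, ...) {
  suff <- c(...)
  if (!length(suff)) return(root)
  paste0(root, "_", paste(suff, collapse = "_"))
}

#' Ancestral pre-vertebrate SSTR genome
#'
#' Two ancestral SSTR genes on two different chromosomes, the starting
#' point of the vertebrate SSTR expansion scheme.
#'
#' @return a [genome()].
#' @export
sstr_ancestral_genome <- function() {
  genome("pre_vertebrate_ancestor",
         data.frame(name = c("ancA", "ancB"), length = c(2e6, 2e6),
                    placed = TRUE),
         data.frame(gene_id = c("SSTR145anc", "SSTR235anc"),
                    family_id = "SSTR", subtype_label = NA_character_,
                    chromosome = c("ancA", "ancB"),
                    start = 5e5, end = 5e5 + 1000, strand = "+"))
}

#' The SSTR evolutionary scheme as an explicit event history
#'
#' Encodes the proposed expansion of the somatostatin receptor family:
#' both ancestral genes quadruple in 2R with one quartet member lost on
#' each chromosome set (six subtype genes in the post-2R vertebrate
#' ancestor: SSTR1, -4, -6 and SSTR2, -3, -5); SSTR6 is lost in
#' tetrapods after the coelacanth divergence and SSTR4 in ray-finned
#' fishes before the gar divergence; on the teleost stem the three
#' SSTR2/-3/-5-bearing chromosome blocks fuse before 3R, then all genes
#' double in 3R with only single SSTR1 and SSTR6 copies retained —
#' giving the eight-gene teleost repertoire (SSTR1, -2a, -2b, -3a,
#' -3b, -5a, -5b, -6).
#'
#' Branch names refer to [sstr_species_tree()]. Replay the full history
#' with [replay_events()] to obtain per-species repertoires, or stop at
#' `"sarcopterygian_actinopterygian_split"` for the post-2R ancestor.
#'
#' @return an [event_history()].
#' @export
sstr_evolution_history <- function() {
  stem <- "sarcopterygian_actinopterygian_split"
  ev <- list(
    ## 2R on the vertebrate stem: two rounds, then one loss per quartet
    evo_event("wgd", stem, list(label = "2R-a", lost = character())),
    evo_event("wgd", stem, list(
      label = "2R-b",
      lost = c(sstr_id("SSTR145anc", "2R-aB", "2R-bB"),
               sstr_id("SSTR235anc", "2R-aB", "2R-bB")))),
    ## SSTR6 lost in tetrapods after the coelacanth split
    evo_event("gene_loss", "tetrapoda",
              list(gene = sstr_id("SSTR145anc", "2R-aB", "2R-bA"))),
    ## SSTR4 lost in ray-finned fishes before the gar split
    evo_event("gene_loss", "gar_teleost_split",
              list(gene = sstr_id("SSTR145anc", "2R-aA", "2R-bB"))),
    ## teleost stem: the three SSTR2/-3/-5 blocks fuse before 3R
    evo_event("chromosome_fusion", "teleost_crown", list(
      chr_a = sstr_id("ancB", "2R-aA", "2R-bA"),
      chr_b = sstr_id("ancB", "2R-aA", "2R-bB"),
      rev_a = FALSE, rev_b = FALSE, new_name = "teleost_fused_1")),
    evo_event("chromosome_fusion", "teleost_crown", list(
      chr_a = "teleost_fused_1",
      chr_b = sstr_id("ancB", "2R-aB", "2R-bA"),
      rev_a = FALSE, rev_b = FALSE, new_name = "teleost_fused")),
    ## 3R: SSTR2/-3/-5 duplicates retained, SSTR1/-6 single copies
    evo_event("wgd", "teleost_crown", list(
      label = "3R",
      lost = c(sstr_id("SSTR145anc", "2R-aA", "2R-bA", "3RB"),
               sstr_id("SSTR145anc", "2R-aB", "2R-bA", "3RB"))))
  )
  event_history(ev)
}

#' The SSTR gene-family tree with the established subtype topology
#'
#' A rooted tree over the packaged SSTR loci, encoding the accepted
#' relationships of the family: two ancestral vertebrate branches (one
#' holding the SSTR1/-4/-6 subtype clades, one SSTR2/-3/-5), gar and
#' coelacanth branching basal to the teleost-specific a/b duplicate
#' clusters within each subtype, the coelacanth SSTRX as a
#' lineage-specific sister of coelacanth SSTR2 and the green puffer
#' SSTR3c as a sister of its SSTR3b. Leaves are labeled
#' `species|gene_id` matching [sstr_genomes()]; all internal supports
#' are set to 100. Trees are consumed by the dating machinery, never
#' inferred by this package.
#'
#' @return a rooted `phylo`.
#' @export
sstr_gene_tree <- function() {
  L <- function(sp, g) paste0(sp, "|", sp, "_", g)
  tetra <- function(g, anole = TRUE, dog = TRUE) {
    mam <- if (dog)
      sprintf("(%s,(%s,(%s,%s)))", L("opossum", g), L("dog", g),
              L("human", g), L("mouse", g))
    else
      sprintf("(%s,(%s,%s))", L("opossum", g), L("human", g), L("mouse", g))
    amn <- if (anole)
      sprintf("((%s,%s),%s)", L("anole", g), L("chicken", g), mam)
    else
      sprintf("(%s,%s)", L("chicken", g), mam)
    sprintf("(%s,%s)", L("frog", g), amn)
  }
  sstr1 <- sprintf("((%s,%s),(%s,%s))",
                   L("coelacanth", "SSTR1"), tetra("SSTR1", anole = FALSE),
                   L("gar", "SSTR1"), L("zebrafish", "SSTR1"))
  sstr4 <- sprintf("(%s,%s)", L("coelacanth", "SSTR4"),
                   tetra("SSTR4", anole = FALSE, dog = FALSE))
  sstr6 <- sprintf("(%s,(%s,(%s,(%s,%s))))",
                   L("coelacanth", "SSTR6"), L("gar", "SSTR6"),
                   L("zebrafish", "SSTR6"), L("stickleback", "SSTR6"),
                   L("fugu", "SSTR6"))
  a2 <- sprintf("(%s,(%s,(%s,(%s,%s))))",
                L("zebrafish", "SSTR2a"), L("stickleback", "SSTR2a"),
                L("medaka", "SSTR2a"), L("green_puffer", "SSTR2a"),
                L("fugu", "SSTR2a"))
  b2 <- sprintf("(%s,(%s,(%s,(%s,%s))))",
                L("zebrafish", "SSTR2b"), L("stickleback", "SSTR2b"),
                L("medaka", "SSTR2b"), L("green_puffer", "SSTR2b"),
                L("fugu", "SSTR2b"))
  sstr2 <- sprintf("(((%s,%s),%s),(%s,(%s,%s)))",
                   L("coelacanth", "SSTR2"), L("coelacanth", "SSTRX"),
                   tetra("SSTR2"), L("gar", "SSTR2"), a2, b2)
  a3 <- sprintf("(%s,(%s,(%s,(%s,%s))))",
                L("zebrafish", "SSTR3a"), L("stickleback", "SSTR3a"),
                L("medaka", "SSTR3a"), L("green_puffer", "SSTR3a"),
                L("fugu", "SSTR3a"))
  b3 <- sprintf("(%s,(%s,((%s,%s),%s)))",
                L("zebrafish", "SSTR3b"), L("medaka", "SSTR3b"),
                L("green_puffer", "SSTR3b"), L("green_puffer", "SSTR3c"),
                L("fugu", "SSTR3b"))
  sstr3 <- sprintf("((%s,%s),(%s,(%s,%s)))",
                   L("coelacanth", "SSTR3"), tetra("SSTR3"),
                   L("gar", "SSTR3"), a3, b3)
  a5 <- sprintf("(%s,(%s,%s))",
                L("zebrafish", "SSTR5a"), L("stickleback", "SSTR5a"),
                L("medaka", "SSTR5a"))
  b5 <- sprintf("(%s,(%s,(%s,%s)))",
                L("zebrafish", "SSTR5b"), L("stickleback", "SSTR5b"),
                L("green_puffer", "SSTR5b"), L("fugu", "SSTR5b"))
  sstr5 <- sprintf("((%s,%s),(%s,(%s,%s)))",
                   L("coelacanth", "SSTR5"), tetra("SSTR5"),
                   L("gar", "SSTR5"), a5, b5)
  nwk <- sprintf("((%s,%s),((%s,(%s,%s)),(%s,(%s,%s))));",
                 L("fruit_fly", "Drostar1"), L("fruit_fly", "Drostar2"),
                 sstr1, sstr4, sstr6, sstr2, sstr3, sstr5)
  nwk <- gsub(")", ")100", nwk, fixed = TRUE)
  nwk <- sub("100;$", ";", nwk)
  ape::read.tree(text = nwk)
}
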