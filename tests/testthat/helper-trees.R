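## shared fixtures: small species trees with WGD markers, dating
## windows, and simulation shortcuts

## 2R-only tree (two rounds on the vertebrate stem, no 3R)
tree_2r <- function() {
  species_tree(
    paste0("(outgroup:10,(lobe:6,(fishA:2,fishB:2)crown2:4)",
           "vertebrate_crown:4)root_split;"),
    wgd = data.frame(label = c("2R-a", "2R-b"),
                     branch = c("vertebrate_crown", "vertebrate_crown"),
                     position = c(0.3, 0.5)))
}

## 2R + 3R tree with a gar-like outgroup to the teleost duplication
tree_3r <- function() {
  species_tree(
    paste0("(outgroup:10,(lobe:6,(gar:4,(fishA:2,fishB:2)teleost_crown:2)",
           "gar_teleost_split:2)vertebrate_crown:4)root_split;"),
    wgd = data.frame(
      label = c("2R-a", "2R-b", "3R"),
      branch = c("vertebrate_crown", "vertebrate_crown", "teleost_crown"),
      position = c(0.3, 0.5, 0.5)))
}

win_2r <- function()
  duplication_window("2R_window", "root_split", "vertebrate_crown")

win_3r <- function()
  rbind(win_2r(),
        duplication_window("3R_window", "gar_teleost_split", "teleost_crown"))

## planted fusion of two 2R-paralogous chromosome copies on the teleost
## stem, before 3R (the study's signature scenario)
planted_paralogous_fusion <- function() {
  list(kind = "chromosome_fusion", branch = "teleost_crown",
       timing = "before", wgd = "3R",
       payload = list(chr_a = "chr1_2R-aA_2R-bA", chr_b = "chr1_2R-aA_2R-bB",
                      rev_a = FALSE, rev_b = FALSE, new_name = "fusedX"))
}

sim_noiseless <- function(seed = 1, n_families = 20, planted = NULL) {
  simulate_history(tree_3r(),
                   sim_params(n_families = n_families,
                              n_ancestral_chromosomes = 2,
                              ohnolog_retention_prob = 1, seed = seed,
                              planted_events = planted))
}

## a small genome with three families laid out for block tests
toy_genome <- function() {
  genome("toy",
         data.frame(name = c("c1", "c2", "scaf1"),
                    length = c(50e6, 30e6, 1e6),
                    placed = c(TRUE, TRUE, FALSE)),
         data.frame(gene_id = c("a1", "a2", "b1", "c1g", "b2", "s1"),
                    family_id = c("A", "A", "B", "C", "B", "S"),
                    subtype_label = NA_character_,
                    chromosome = c("c1", "c1", "c1", "c1", "c2", "scaf1"),
                    start = c(1e6, 10e6, 12e6, 40e6, 5e6, 1e3),
                    end = c(1e6, 10e6, 12e6, 40e6, 5e6, 1e3) + 1000,
                    strand = "+"))
}

## independent LCA reconciliation oracle: computes each node's mapped
## species-tree node by intersecting root-to-tip paths (ape::nodepath),
## then labels a node a duplication iff its mapping equals a child's.
## No code shared with the package's getMRCA-based recursion.
oracle_events <- function(tree, st, label_regex = "^([^|]+)\\|(.+)$") {
  leaves <- parse_leaf_labels(tree, label_regex)
  phy <- st$phy
  sroot <- ape::Ntip(phy) + 1L
  rootpath <- function(sp)
    ape::nodepath(phy, from = sroot, to = match(sp, phy$tip.label))
  map_of <- function(species) {
    paths <- lapply(unique(species), rootpath)
    common <- Reduce(intersect, paths)
    common[length(common)]  # deepest shared node on every root path
  }
  ntip <- ape::Ntip(tree)
  out <- rep(NA_character_, ntip + tree$Nnode)
  spsets <- vector("list", ntip + tree$Nnode)
  mapped <- integer(ntip + tree$Nnode)
  kids_of <- split(tree$edge[, 2], tree$edge[, 1])
  visit <- function(id) {
    if (id <= ntip) {
      spsets[[id]] <<- leaves$species[match(tree$tip.label[id], leaves$leaf)]
      mapped[id] <<- map_of(spsets[[id]])
      return(invisible(NULL))
    }
    kids <- kids_of[[as.character(id)]]
    for (k in kids) visit(k)
    spsets[[id]] <<- unique(unlist(spsets[kids]))
    mapped[id] <<- map_of(spsets[[id]])
    out[id] <<- if (any(mapped[kids] == mapped[id])) "duplication"
                else "speciation"
    invisible(NULL)
  }
  visit(ntip + 1L)
  out
}

## random gene tree: random topology over random species assignments
random_gene_tree <- function(n_leaves, species_pool, seed) {
  set.seed(seed)
  tr <- ape::rtree(n_leaves, rooted = TRUE, br = NULL)
  sp <- sample(species_pool, n_leaves, replace = TRUE)
  tr$tip.label <- paste0(sp, "|g", seq_len(n_leaves))
  tr$node.label <- NULL
  tr
}

## bipartition-based Robinson-Foulds distance on unrooted topologies
rf_dist_biparts <- function(t1, t2) {
  bip <- function(tr) {
    tr <- ape::unroot(tr)
    ntip <- ape::Ntip(tr)
    labs <- sort(tr$tip.label)
    parts <- ape::prop.part(tr)
    out <- character()
    for (p in parts) {
      side <- sort(attr(parts, "labels")[p])
      if (length(side) <= 1L || length(side) >= ntip - 1L) next
      other <- setdiff(labs, side)
      canon <- if (paste(side, collapse = ",") <
                   paste(other, collapse = ","))
        paste(side, collapse = ",") else paste(other, collapse = ",")
      out <- c(out, canon)
    }
    unique(out)
  }
  b1 <- bip(t1); b2 <- bip(t2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

pkg_file <- function(...) system.file(..., package = "paralogon")
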