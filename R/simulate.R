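#' Simulation parameters for genome evolution
#'
#' Defaults describe a modest vertebrate-like setting: tens of gene
#' families spread over a few ancestral chromosomes, with most ohnologs
#' retained after a whole-genome duplication and rare interchromosomal
#' rearrangements. Rates are expected event counts per species-tree
#' branch.
#'
#' @param n_families number of ancestral single-copy gene families.
#' @param n_ancestral_chromosomes chromosomes in the root genome;
#'   families are distributed over them round-robin.
#' @param ohnolog_retention_prob per-copy Bernoulli retention
#'   probability applied immediately after each WGD.
#' @param fusion_rate,fission_rate,translocation_rate expected counts
#'   per branch (Poisson).
#' @param shuffle_intensity expected intrachromosomal single-gene moves
#'   per branch.
#' @param lineage_dup_rate expected tandem (lineage-specific) gene
#'   duplications per branch.
#' @param translocation_block_mean mean size (genes) of a translocated
#'   block; block sizes are 1 + geometric.
#' @param planted_events optional list of events to force; each element
#'   is a list with `kind`, `branch`, and optionally `timing`
#'   (`"before"`/`"after"`), `wgd` (marker label the timing is relative
#'   to) and a partial `payload` (missing fields are sampled).
#' @param seed integer seed for the single global generator.
#' @return an object of class `sim_params`.
#' @export
sim_params <- function(n_families = 30,
                       n_ancestral_chromosomes = 2,
                       ohnolog_retention_prob = 0.8,
                       fusion_rate = 0,
                       fission_rate = 0,
                       translocation_rate = 0,
                       shuffle_intensity = 0,
                       lineage_dup_rate = 0,
                       translocation_block_mean = 2,
                       planted_events = NULL,
                       seed = 1L) {
  stopifnot(n_families >= 1, n_ancestral_chromosomes >= 1,
            ohnolog_retention_prob >= 0, ohnolog_retention_prob <= 1,
            fusion_rate >= 0, fission_rate >= 0, translocation_rate >= 0,
            shuffle_intensity >= 0, lineage_dup_rate >= 0,
            translocation_block_mean >= 1)
  structure(list(n_families = as.integer(n_families),
                 n_ancestral_chromosomes = as.integer(n_ancestral_chromosomes),
                 genes_per_chromosome =
                   as.integer(ceiling(n_families / n_ancestral_chromosomes)),
                 ohnolog_retention_prob = ohnolog_retention_prob,
                 fusion_rate = fusion_rate, fission_rate = fission_rate,
                 translocation_rate = translocation_rate,
                 shuffle_intensity = shuffle_intensity,
                 lineage_dup_rate = lineage_dup_rate,
                 translocation_block_mean = translocation_block_mean,
                 planted_events = planted_events,
                 seed = as.integer(seed)),
            class = "sim_params")
}

## ---- gene-tree bookkeeping -------------------------------------------------

new_tree_env <- function(families) {
  env <- new.env(parent = emptyenv())
  env$nodes <- stats::setNames(vector("list", length(families)), families)
  env$counter <- stats::setNames(integer(length(families)), families)
  env
}

add_tree_node <- function(env, fam, parent, kind, depth, label = NA_character_,
                          wgd = NA_character_) {
  id <- env$counter[[fam]] + 1L
  env$counter[[fam]] <- id
  env$nodes[[fam]][[id]] <- list(id = id, parent = parent, kind = kind,
                                 depth = depth, label = label, wgd = wgd)
  id
}

## collapse unary nodes / dead lineages and emit newick (supports = 100,
## branch lengths = depth differences along the species tree)
family_tree_newick <- function(nodes) {
  if (!length(nodes)) return(NULL)
  kids <- split(seq_along(nodes),
                factor(vapply(nodes, function(n)
                  ifelse(is.na(n$parent), 0L, n$parent), integer(1)),
                  levels = 0:length(nodes)))
  build <- function(i) {
    n <- nodes[[i]]
    if (n$kind == "leaf")
      return(list(label = n$label, depth = n$depth, leaf = TRUE))
    ch <- kids[[as.character(i)]]
    sub <- Filter(Negate(is.null), lapply(ch, build))
    if (length(sub) == 0L) return(NULL)
    if (length(sub) == 1L) return(sub[[1L]])
    list(children = sub, depth = n$depth, leaf = FALSE)
  }
  roots <- kids[["0"]]
  if (length(roots) != 1L) return(NULL)
  top <- build(roots[[1L]])
  if (is.null(top) || isTRUE(top$leaf)) return(NULL)
  rec <- function(node, parent_depth) {
    bl <- format(max(node$depth - parent_depth, 0), scientific = FALSE)
    if (isTRUE(node$leaf)) return(paste0(node$label, ":", bl))
    inner <- paste(vapply(node$children, rec, character(1),
                          parent_depth = node$depth), collapse = ",")
    paste0("(", inner, ")100:", bl)
  }
  inner <- paste(vapply(top$children, rec, character(1),
                        parent_depth = top$depth), collapse = ",")
  paste0("(", inner, ")100;")
}

## ---- payload samplers ------------------------------------------------------

sample_fusion_payload <- function(state, payload = list()) {
  if (length(state$chrom) < 2L) return(NULL)
  if (is.null(payload$chr_a) || is.null(payload$chr_b)) {
    pick <- sample(names(state$chrom), 2L)
    payload$chr_a <- pick[1L]; payload$chr_b <- pick[2L]
  }
  if (is.null(payload$rev_a)) payload$rev_a <- sample(c(TRUE, FALSE), 1L)
  if (is.null(payload$rev_b)) payload$rev_b <- sample(c(TRUE, FALSE), 1L)
  if (is.null(payload$new_name))
    payload$new_name <- paste0(payload$chr_a, ".", payload$chr_b)
  payload
}

sample_fission_payload <- function(state, payload = list()) {
  ok <- names(state$chrom)[lengths(state$chrom) >= 2L]
  if (!length(ok)) return(NULL)
  if (is.null(payload$chr)) payload$chr <- sample(ok, 1L)
  n <- length(state$chrom[[payload$chr]])
  if (n < 2L) return(NULL)
  if (is.null(payload$after))
    payload$after <- sample.int(n - 1L, 1L)
  if (is.null(payload$new_names))
    payload$new_names <- paste0(payload$chr, c(".p", ".q"))
  payload
}

sample_translocation_payload <- function(state, block_mean, payload = list()) {
  if (length(state$chrom) < 2L) return(NULL)
  if (is.null(payload$genes)) {
    src <- sample(names(state$chrom), 1L)
    n <- length(state$chrom[[src]])
    k <- min(1L + stats::rgeom(1L, 1 / block_mean), n)
    i <- sample.int(n - k + 1L, 1L)
    payload$genes <- state$chrom[[src]][i:(i + k - 1L)]
  } else {
    src <- state_find_gene(state, payload$genes[1L])$chr
  }
  if (is.null(payload$to))
    payload$to <- sample(setdiff(names(state$chrom), src), 1L)
  if (is.null(payload$at))
    payload$at <- sample.int(length(state$chrom[[payload$to]]) + 1L, 1L) - 1L
  if (is.null(payload$rev)) payload$rev <- sample(c(TRUE, FALSE), 1L)
  payload
}

sample_shuffle_payload <- function(state, payload = list()) {
  ok <- names(state$chrom)[lengths(state$chrom) >= 2L]
  if (!length(ok)) return(NULL)
  if (is.null(payload$chr)) payload$chr <- sample(ok, 1L)
  g <- state$chrom[[payload$chr]]
  if (is.null(payload$gene)) payload$gene <- sample(g, 1L)
  if (is.null(payload$new_index)) payload$new_index <- sample.int(length(g), 1L)
  payload
}

sample_lineage_dup_payload <- function(state, payload = list()) {
  if (!length(state$fam)) return(NULL)
  if (is.null(payload$gene)) payload$gene <- sample(names(state$fam), 1L)
  if (is.null(payload$new_id)) {
    base <- paste0(payload$gene, ".t")
    k <- 1L
    while (paste0(base, k) %in% names(state$fam)) k <- k + 1L
    payload$new_id <- paste0(base, k)
  }
  payload
}

## ---- the simulator ---------------------------------------------------------

#' Simulate genome evolution along a species tree
#'
#' Evolves an ancestral genome root-to-tip under whole-genome
#' duplications (at the tree's WGD markers, with per-copy Bernoulli
#' ohnolog retention applied immediately), chromosome fusions and
#' fissions, block translocations, intrachromosomal shuffling and
#' tandem duplications. Gene trees record the true duplication history
#' (branch lengths proportional to elapsed species-tree depth; all
#' supports 100). The sampled history is returned as a fully explicit,
#' replayable [event_history()].
#'
#' @param tree a [species_tree()] with at least 2 extant taxa.
#' @param params a [sim_params()].
#' @return an object of class `sim_result` with elements `genomes`
#'   (named list of [genome()] per extant taxon), `gene_trees` (named
#'   list of `phylo`, families with >= 2 surviving genes), `truth`
#'   ([event_history()]), `ohnolog_map` (data.frame: species, gene_id,
#'   family_id, wgd_class, ancestral_chromosome), `ancestral_genome`,
#'   and `params`.
#' @export
simulate_history <- function(tree, params) {
  stopifnot(inherits(tree, "species_tree"), inherits(params, "sim_params"))
  phy <- tree$phy
  if (ape::Ntip(phy) < 2L) stop("species tree must have >= 2 extant taxa")
  set.seed(params$seed)
  el <- phy$edge.length
  if (is.null(el)) el <- rep(1, nrow(phy$edge))
  node_depth <- ape::node.depth.edgelength(
    structure(list(edge = phy$edge, edge.length = el,
                   tip.label = phy$tip.label, Nnode = phy$Nnode),
              class = "phylo"))

  nfam <- params$n_families
  fams <- sprintf("F%03d", seq_len(nfam))
  chr_of_fam <- rep(seq_len(params$n_ancestral_chromosomes), length.out = nfam)
  anc_chrom <- lapply(seq_len(params$n_ancestral_chromosomes), function(k)
    paste0(fams[chr_of_fam == k], ".0"))
  names(anc_chrom) <- paste0("chr", seq_len(params$n_ancestral_chromosomes))
  anc_state <- list(
    chrom = anc_chrom,
    fam = stats::setNames(rep(fams, times = 1), paste0(fams, ".0")),
    sub = stats::setNames(rep(NA_character_, nfam), paste0(fams, ".0")))
  ancestral_genome <- state_to_genome(anc_state, "ancestor")

  env <- new_tree_env(fams)
  pend <- stats::setNames(vapply(fams, function(f)
    add_tree_node(env, f, NA_integer_, "root", 0), integer(1)),
    paste0(fams, ".0"))
  klass <- stats::setNames(rep("", nfam), paste0(fams, ".0"))
  anc_of <- stats::setNames(
    rep(names(anc_chrom), times = lengths(anc_chrom)),
    unlist(anc_chrom))

  truth <- list()
  ohno <- list()
  genomes <- list()
  gene_err <- function(...) stop("configuration error: ", ...)

  planted <- params$planted_events
  planted_used <- rep(FALSE, length(planted))

  emit <- function(ev, state, extras) {
    truth[[length(truth) + 1L]] <<- ev
    st2 <- apply_event(state, ev)
    list(state = st2, extras = extras)
  }

  do_wgd <- function(state, extras, label, branch, depth) {
    genes <- unlist(state$chrom, use.names = FALSE)
    lost <- character()
    both <- character()
    single_keep <- character()
    for (g in genes) {
      keepA <- stats::runif(1) < params$ohnolog_retention_prob
      keepB <- stats::runif(1) < params$ohnolog_retention_prob
      if (keepA && keepB) both <- c(both, g)
      else if (keepA) { single_keep <- c(single_keep, wgd_copy_id(g, label, 1))
        lost <- c(lost, wgd_copy_id(g, label, 2)) }
      else if (keepB) { single_keep <- c(single_keep, wgd_copy_id(g, label, 2))
        lost <- c(lost, wgd_copy_id(g, label, 1)) }
      else lost <- c(lost, wgd_copy_id(g, label, 1), wgd_copy_id(g, label, 2))
    }
    ev <- evo_event("wgd", branch, list(label = label, lost = lost))
    truth[[length(truth) + 1L]] <<- ev
    state <- apply_event(state, ev)
    pend2 <- integer(); klass2 <- character(); anc2 <- character()
    for (g in genes) {
      fam <- extras$fam_of[[g]]
      ids <- c(wgd_copy_id(g, label, 1), wgd_copy_id(g, label, 2))
      present <- ids %in% names(state$fam)
      if (all(present)) {
        d <- add_tree_node(env, fam, extras$pend[[g]], "duplication", depth,
                           wgd = label)
        for (ci in 1:2) {
          pend2[ids[ci]] <- d
          klass2[ids[ci]] <- paste0(extras$klass[[g]],
                                    if (nzchar(extras$klass[[g]])) "/" else "",
                                    label, ":", c("A", "B")[ci])
          anc2[ids[ci]] <- extras$anc[[g]]
        }
      } else if (any(present)) {
        id <- ids[present]
        pend2[id] <- extras$pend[[g]]
        klass2[id] <- extras$klass[[g]]
        anc2[id] <- extras$anc[[g]]
      }
    }
    extras$pend <- pend2
    extras$klass <- klass2
    extras$anc <- anc2
    extras$fam_of <- stats::setNames(unname(state$fam), names(state$fam))
    list(state = state, extras = extras)
  }

  apply_sampled <- function(state, extras, branch, kind, payload = list()) {
    payload <- switch(kind,
      chromosome_fusion = sample_fusion_payload(state, payload),
      chromosome_fission = sample_fission_payload(state, payload),
      block_translocation = sample_translocation_payload(
        state, params$translocation_block_mean, payload),
      intra_shuffle = sample_shuffle_payload(state, payload),
      lineage_duplication = sample_lineage_dup_payload(state, payload),
      gene_loss = if (length(state$fam)) {
        if (is.null(payload$gene)) payload$gene <- sample(names(state$fam), 1L)
        payload
      } else NULL,
      stop("cannot sample payload for kind '", kind, "'"))
    if (is.null(payload)) return(list(state = state, extras = extras))
    ev <- evo_event(kind, branch, payload)
    truth[[length(truth) + 1L]] <<- ev
    state <- apply_event(state, ev)
    if (kind == "lineage_duplication") {
      g <- payload$gene; nid <- payload$new_id
      fam <- extras$fam_of[[g]]
      d <- add_tree_node(env, fam, extras$pend[[g]], "duplication",
                         extras$depth_now)
      extras$pend[[g]] <- d
      extras$pend[[nid]] <- d
      extras$klass[[nid]] <- extras$klass[[g]]
      extras$anc[[nid]] <- extras$anc[[g]]
      extras$fam_of[[nid]] <- fam
    }
    if (kind == "gene_loss") {
      g <- payload$gene
      extras$pend <- extras$pend[names(extras$pend) != g]
      extras$klass <- extras$klass[names(extras$klass) != g]
      extras$anc <- extras$anc[names(extras$anc) != g]
      extras$fam_of <- extras$fam_of[names(extras$fam_of) != g]
    }
    list(state = state, extras = extras)
  }

  process_branch <- function(state, extras, child_id) {
    branch <- st_node_name(tree, child_id)
    i_edge <- which(phy$edge[, 2] == child_id)
    L <- el[i_edge]
    d0 <- node_depth[phy$edge[i_edge, 1]]
    markers <- tree$wgd[tree$wgd$branch == branch, , drop = FALSE]
    markers <- markers[order(markers$position), , drop = FALSE]
    if (nrow(markers) && L <= 0)
      gene_err("WGD marker '", markers$label[1L],
               "' lies on a zero-length branch ('", branch, "')")
    cuts <- c(0, markers$position, 1)
    for (seg in seq_len(length(cuts) - 1L)) {
      frac <- cuts[seg + 1L] - cuts[seg]
      extras$depth_now <- d0 + cuts[seg] * L
      ## planted events assigned to this segment
      if (length(planted)) for (pi in seq_along(planted)) {
        pe <- planted[[pi]]
        if (planted_used[pi] || !identical(pe$branch, branch)) next
        seg_ok <- TRUE
        if (!is.null(pe$wgd)) {
          mpos <- match(pe$wgd, markers$label)
          if (is.na(mpos)) seg_ok <- FALSE
          else if (identical(pe$timing, "before")) seg_ok <- (seg <= mpos)
          else if (identical(pe$timing, "after")) seg_ok <- (seg > mpos)
        }
        if (!seg_ok) next
        ## "before" events go in the first eligible segment
        res <- apply_sampled(state, extras, branch, pe$kind,
                             if (is.null(pe$payload)) list() else pe$payload)
        state <- res$state; extras <- res$extras
        planted_used[pi] <<- TRUE
      }
      ## sampled events, scaled by the segment's share of the branch
      for (kind in c("chromosome_fusion", "chromosome_fission",
                     "block_translocation", "intra_shuffle",
                     "lineage_duplication")) {
        rate <- switch(kind,
                       chromosome_fusion = params$fusion_rate,
                       chromosome_fission = params$fission_rate,
                       block_translocation = params$translocation_rate,
                       intra_shuffle = params$shuffle_intensity,
                       lineage_duplication = params$lineage_dup_rate)
        n <- stats::rpois(1L, rate * frac)
        for (k in seq_len(n)) {
          res <- apply_sampled(state, extras, branch, kind)
          state <- res$state; extras <- res$extras
        }
      }
      ## the WGD closing this segment
      if (seg <= nrow(markers)) {
        res <- do_wgd(state, extras, markers$label[seg], branch,
                      d0 + markers$position[seg] * L)
        state <- res$state; extras <- res$extras
      }
    }
    list(state = state, extras = extras)
  }

  recurse <- function(node_id, state, extras) {
    ntip <- ape::Ntip(phy)
    if (node_id <= ntip) {
      sp <- phy$tip.label[node_id]
      depth <- node_depth[node_id]
      for (g in names(state$fam)) {
        fam <- extras$fam_of[[g]]
        add_tree_node(env, fam, extras$pend[[g]], "leaf", depth,
                      label = paste0(sp, "|", g))
      }
      genomes[[sp]] <<- state_to_genome(state, sp)
      if (length(state$fam))
        ohno[[sp]] <<- data.frame(
          species = sp, gene_id = names(state$fam),
          family_id = unname(state$fam),
          wgd_class = unname(extras$klass[names(state$fam)]),
          ancestral_chromosome = unname(extras$anc[names(state$fam)]))
      return(invisible(NULL))
    }
    depth <- node_depth[node_id]
    spec_nodes <- stats::setNames(
      vapply(names(state$fam), function(g)
        add_tree_node(env, extras$fam_of[[g]], extras$pend[[g]],
                      "speciation", depth), integer(1)),
      names(state$fam))
    for (child in st_children(tree, node_id)) {
      ex <- extras
      ex$pend[names(spec_nodes)] <- spec_nodes
      res <- process_branch(state, ex, child)
      recurse(child, res$state, res$extras)
    }
    invisible(NULL)
  }

  root_extras <- list(pend = pend, klass = klass, anc = anc_of,
                      fam_of = stats::setNames(unname(anc_state$fam),
                                               names(anc_state$fam)),
                      depth_now = 0)
  recurse(st_root(tree), anc_state, root_extras)

  gene_trees <- list()
  for (f in fams) {
    nwk <- family_tree_newick(env$nodes[[f]])
    if (!is.null(nwk)) {
      tr <- ape::read.tree(text = nwk)
      if (!is.null(tr) && ape::Ntip(tr) >= 2L) gene_trees[[f]] <- tr
    }
  }
  ohno_df <- if (length(ohno)) do.call(rbind, unname(ohno)) else
    data.frame(species = character(), gene_id = character(),
               family_id = character(), wgd_class = character(),
               ancestral_chromosome = character())
  rownames(ohno_df) <- NULL
  structure(list(genomes = genomes, gene_trees = gene_trees,
                 truth = event_history(truth), ohnolog_map = ohno_df,
                 ancestral_genome = ancestral_genome, params = params,
                 species_tree = tree),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat("sim_result:", length(x$genomes), "genomes,",
      length(x$gene_trees), "gene trees,",
      length(x$truth), "events\n")
  invisible(x)
}

#' Serialize a simulation result to a directory
#'
#' Writes the gene tables (+ chromosome sidecar), one newick per family,
#' the truth log as JSON lines and the ohnolog map as TSV.
#'
#' @param x a `sim_result`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_result <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_gene_table(x$genomes, file.path(dir, "genomes.tsv"),
                   file.path(dir, "chromosomes.tsv"))
  tdir <- file.path(dir, "gene_trees")
  dir.create(tdir, showWarnings = FALSE)
  for (f in names(x$gene_trees))
    ape::write.tree(x$gene_trees[[f]], file.path(tdir, paste0(f, ".nwk")))
  write_event_history(x$truth, file.path(dir, "truth.jsonl"))
  utils::write.table(x$ohnolog_map, file.path(dir, "ohnolog_map.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
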