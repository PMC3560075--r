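## small rooted-tree helpers on ape phylo objects

phy_children <- function(phy, id) phy$edge[phy$edge[, 1] == id, 2]

phy_parent <- function(phy, id) {
  p <- phy$edge[phy$edge[, 2] == id, 1]
  if (length(p)) p else NA_integer_
}

phy_tips_below <- function(phy, id) {
  ntip <- ape::Ntip(phy)
  if (id <= ntip) return(id)
  unlist(lapply(phy_children(phy, id), phy_tips_below, phy = phy))
}

#' Parse species identifiers from gene-tree leaf labels
#'
#' @param tree a `phylo`.
#' @param label_regex regex with two capture groups, species then gene.
#' @return data.frame with columns `leaf`, `species`, `gene_id`.
#' @export
parse_leaf_labels <- function(tree, label_regex = "^([^|]+)\\|(.+)$") {
  m <- regmatches(tree$tip.label, regexec(label_regex, tree$tip.label))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad))
    stop("leaf label '", tree$tip.label[bad][1L],
         "' does not match the species|gene grammar")
  data.frame(leaf = tree$tip.label,
             species = vapply(m, `[`, character(1), 2L),
             gene_id = vapply(m, `[`, character(1), 3L))
}

#' Read a gene-family tree from newick
#'
#' Supports internal-node labels as support values. An unrooted tree is
#' rooted on the given outgroup leaf.
#'
#' @param path newick file path.
#' @param label_regex leaf-label grammar, see [parse_leaf_labels()].
#' @param outgroup optional leaf label to root on.
#' @return a rooted `phylo`.
#' @export
read_newick <- function(path, label_regex = "^([^|]+)\\|(.+)$",
                        outgroup = NULL) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse newick file: ", path)
  if (!ape::is.rooted(tr)) {
    if (is.null(outgroup))
      stop("tree in ", path, " is unrooted and no outgroup was given")
    if (!outgroup %in% tr$tip.label)
      stop("outgroup leaf '", outgroup, "' not present in ", path)
    tr <- ape::root(tr, outgroup = outgroup, resolve.root = TRUE)
  }
  parse_leaf_labels(tr, label_regex)  # validates labels
  tr
}

## numeric supports normalized to percent; NA where absent
node_supports_pct <- function(tree) {
  if (is.null(tree$node.label)) return(rep(NA_real_, tree$Nnode))
  s <- suppressWarnings(as.numeric(tree$node.label))
  if (all(is.na(s) | s <= 1)) s <- s * 100
  s
}

#' Reconcile a gene tree with a species tree by LCA mapping
#'
#' Each gene-tree node maps to the species-tree most recent common
#' ancestor of its leaf species; a node is a duplication when its
#' mapping equals the mapping of at least one child, otherwise a
#' speciation (Zmasek-Eddy style LCA reconciliation).
#'
#' @param gene_tree rooted `phylo` with `species|gene` leaf labels.
#' @param species_tree a [species_tree()].
#' @param label_regex leaf-label grammar.
#' @return an object of class `reconciled_tree`: the tree plus per-node
#'   mapped species-tree node and `speciation`/`duplication` labels.
#' @export
reconcile <- function(gene_tree, species_tree,
                      label_regex = "^([^|]+)\\|(.+)$") {
  stopifnot(inherits(gene_tree, "phylo"), inherits(species_tree, "species_tree"))
  leaves <- parse_leaf_labels(gene_tree, label_regex)
  unknown <- setdiff(leaves$species, species_tree$phy$tip.label)
  if (length(unknown)) {
    bad <- leaves$leaf[leaves$species == unknown[1L]][1L]
    stop("leaf '", bad, "': species '", unknown[1L],
         "' is not in the species tree")
  }
  ntip <- ape::Ntip(gene_tree)
  nnode <- gene_tree$Nnode
  if (any(tabulate(gene_tree$edge[, 1]) > 2))
    warning("gene tree contains polytomies; LCA labels computed as-is")
  spset <- vector("list", ntip + nnode)
  mapped <- integer(ntip + nnode)
  event <- rep(NA_character_, ntip + nnode)
  rec <- function(id) {
    if (id <= ntip) {
      spset[[id]] <<- leaves$species[match(gene_tree$tip.label[id],
                                           leaves$leaf)]
      mapped[id] <<- st_node_id(species_tree, spset[[id]])
      return(invisible(NULL))
    }
    kids <- phy_children(gene_tree, id)
    for (k in kids) rec(k)
    spset[[id]] <<- unique(unlist(spset[kids]))
    mapped[id] <<- st_mrca(species_tree, spset[[id]])
    event[id] <<- if (any(mapped[kids] == mapped[id])) "duplication"
                  else "speciation"
    invisible(NULL)
  }
  rec(ntip + 1L)
  structure(list(tree = gene_tree, species_tree = species_tree,
                 leaves = leaves, mapped = mapped, event = event,
                 support = node_supports_pct(gene_tree)),
            class = "reconciled_tree")
}

#' @export
print.reconciled_tree <- function(x, ...) {
  nd <- sum(x$event == "duplication", na.rm = TRUE)
  cat("reconciled tree:", ape::Ntip(x$tree), "leaves,", nd,
      "duplication node(s)\n")
  invisible(x)
}

#' Define a relative-dating window on the species tree
#'
#' A duplication dated to the window maps strictly after `older` and at
#' or before `younger` on the species tree (both are named nodes;
#' `older` must be strictly ancestral to `younger`).
#'
#' @param label window label, e.g. `"2R_window"`.
#' @param older,younger species-tree node names.
#' @return one-row data.frame.
#' @export
duplication_window <- function(label, older, younger) {
  data.frame(label = label, older = older, younger = younger)
}

window_nodes <- function(st, older, younger) {
  o <- st_node_id(st, older)
  y <- st_node_id(st, younger)
  if (!st_is_ancestor(st, o, y, strict = TRUE))
    stop("window bound '", older, "' is not strictly ancestral to '",
         younger, "'")
  path <- c(y, st_ancestors(st, y))
  path[seq_len(match(o, path) - 1L)]  # nodes after older, up to younger
}

#' Date duplication nodes into relative time windows
#'
#' Assigns each duplication node of a [reconcile()]d tree to the window
#' whose species-tree path contains its mapped node; duplications mapped
#' to a single extant taxon are `lineage_specific`; unmatched ones are
#' `other`.
#'
#' @param rt a `reconciled_tree`.
#' @param windows data.frame of [duplication_window()] rows; windows
#'   must not overlap.
#' @return data.frame with one row per duplication node: `node`,
#'   `mapped` (species-tree node name), `support` (percent or NA),
#'   `window`.
#' @export
date_duplication_nodes <- function(rt, windows) {
  stopifnot(inherits(rt, "reconciled_tree"))
  st <- rt$species_tree
  wsets <- lapply(seq_len(nrow(windows)), function(i)
    window_nodes(st, windows$older[i], windows$younger[i]))
  if (nrow(windows) > 1L)
    for (i in seq_len(nrow(windows) - 1L))
      for (j in (i + 1L):nrow(windows))
        if (length(intersect(wsets[[i]], wsets[[j]])))
          stop("windows '", windows$label[i], "' and '", windows$label[j],
               "' overlap on the species tree")
  ntip <- ape::Ntip(rt$tree)
  dups <- which(rt$event == "duplication")
  if (!length(dups))
    return(data.frame(node = integer(), mapped = character(),
                      support = numeric(), window = character()))
  win <- vapply(dups, function(nd) {
    m <- rt$mapped[nd]
    if (m <= ape::Ntip(st$phy)) return("lineage_specific")
    for (i in seq_along(wsets))
      if (m %in% wsets[[i]]) return(windows$label[i])
    "other"
  }, character(1))
  data.frame(node = dups,
             mapped = st_node_name(st, rt$mapped[dups]),
             support = rt$support[dups - ntip],
             window = win)
}

#' Classify a gene family's evidence for a WGD window
#'
#' Applies the at-least-one-method rule: the family `supports_WGD` when
#' any provided tree (e.g. ML and NJ) contains a duplication dated to
#' the window with support at or above the threshold; `consistent` when
#' a window-dated duplication exists but only below the threshold (or
#' with missing support under a contradicting second method);
#' `inconclusive` when no tree places a duplication in the window.
#'
#' @param trees a single `phylo` or list of 1-2 trees sharing a leaf
#'   set (e.g. ML and NJ topologies).
#' @param species_tree a [species_tree()].
#' @param window one [duplication_window()] row.
#' @param support_threshold percent support required (default 50).
#' @param family_id optional family identifier carried into the result.
#' @param label_regex leaf-label grammar.
#' @return an object of class `family_verdict`.
#' @export
classify_family_verdict <- function(trees, species_tree, window,
                                    support_threshold = 50,
                                    family_id = NA_character_,
                                    label_regex = "^([^|]+)\\|(.+)$") {
  if (inherits(trees, "phylo")) trees <- list(trees)
  stopifnot(length(trees) >= 1L, length(trees) <= 2L)
  leafsets <- lapply(trees, function(t) sort(t$tip.label))
  if (length(trees) == 2L && !identical(leafsets[[1]], leafsets[[2]]))
    stop("trees from different methods must share the same leaf set")
  per_method <- lapply(trees, function(tr) {
    rt <- reconcile(tr, species_tree, label_regex)
    dd <- date_duplication_nodes(rt, window)
    dd[dd$window == window$label, , drop = FALSE]
  })
  has_dup <- vapply(per_method, nrow, integer(1)) > 0L
  best <- suppressWarnings(max(c(-Inf, unlist(lapply(per_method, function(d)
    d$support[!is.na(d$support)])))))
  supported <- any(vapply(per_method, function(d)
    any(!is.na(d$support) & d$support >= support_threshold), logical(1)))
  verdict <- if (supported) "supports_WGD"
             else if (any(has_dup)) "consistent"
             else "inconclusive"
  structure(list(family_id = family_id, verdict = verdict,
                 window = window$label,
                 best_support = if (is.finite(best)) best else NA_real_,
                 method_agreement = all(has_dup),
                 n_window_duplications = vapply(per_method, nrow, integer(1))),
            class = "family_verdict")
}

#' @export
print.family_verdict <- function(x, ...) {
  cat("family", x$family_id, "->", x$verdict, "(window", x$window,
      "; best support", x$best_support, ")\n")
  invisible(x)
}

#' Write family verdicts as TSV
#'
#' @param verdicts list of `family_verdict` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_verdicts <- function(verdicts, path) {
  df <- do.call(rbind, lapply(verdicts, function(v)
    data.frame(family_id = v$family_id, verdict = v$verdict,
               window = v$window, best_support = v$best_support,
               method_agreement = v$method_agreement)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## duplication-path classes per leaf: which side of each window-dated
## duplication a leaf descends from
leaf_dup_paths <- function(rt, dated, window_label) {
  tree <- rt$tree
  ntip <- ape::Ntip(tree)
  dn <- dated$node[dated$window == window_label]
  cls <- character(ntip)
  if (!length(dn)) return(stats::setNames(cls, tree$tip.label))
  for (leaf in seq_len(ntip)) {
    path <- leaf
    p <- phy_parent(tree, leaf)
    while (!is.na(p)) { path <- c(path, p); p <- phy_parent(tree, p) }
    steps <- character()
    for (nd in dn) {
      i <- match(nd, path)
      if (!is.na(i) && i > 1L) {
        kid <- path[i - 1L]
        ci <- match(kid, phy_children(tree, nd))
        steps <- c(steps, paste0("n", nd, ".", ci))
      }
    }
    cls[leaf] <- paste(steps, collapse = "/")
  }
  stats::setNames(cls, tree$tip.label)
}

#' Classify gene copies by their WGD duplication paths
#'
#' For every leaf of a gene tree, records which side of each dated
#' 2R-window and 3R-window duplication it descends from. Leaves sharing
#' the same `twor_class` are 2R-window orthologs/co-orthologs; leaves of
#' one `twor_class` with different `threer_copy` are 3R (a/b) ohnologs.
#'
#' @param tree rooted `phylo` gene tree.
#' @param species_tree a [species_tree()].
#' @param windows data.frame of [duplication_window()] rows containing
#'   labels `twor_label` and (optionally) `threer_label`.
#' @param twor_label,threer_label window labels (defaults `"2R_window"`,
#'   `"3R_window"`).
#' @param support_threshold only duplications at or above this percent
#'   support define classes; unsupported nodes are ignored. Use 0 to
#'   keep all.
#' @param label_regex leaf-label grammar.
#' @return data.frame: `leaf`, `species`, `gene_id`, `twor_class`,
#'   `threer_copy` (empty string where no dated duplication applies).
#' @export
classify_gene_copies <- function(tree, species_tree, windows,
                                 twor_label = "2R_window",
                                 threer_label = "3R_window",
                                 support_threshold = 0,
                                 label_regex = "^([^|]+)\\|(.+)$") {
  rt <- reconcile(tree, species_tree, label_regex)
  dated <- date_duplication_nodes(rt, windows)
  if (support_threshold > 0)
    dated <- dated[is.na(dated$support) |
                     dated$support >= support_threshold, , drop = FALSE]
  twor <- leaf_dup_paths(rt, dated, twor_label)
  threer <- leaf_dup_paths(rt, dated, threer_label)
  out <- rt$leaves
  out$twor_class <- unname(twor[out$leaf])
  out$threer_copy <- unname(threer[out$leaf])
  out
}

#' Assign a query gene to a subtype clade, with teleost a/b labeling
#'
#' The query receives the subtype of the smallest clade containing it
#' and reference leaves of exactly one subtype. Within a subtype, a
#' 3R-window duplication partitions teleost members into a/b clusters;
#' polarity follows the designated a-reference leaf, or, absent one,
#' the cluster holding the alphabetically first species.
#'
#' @param rt a `reconciled_tree`.
#' @param reference_leaves named list: subtype -> character vector of
#'   leaf labels anchoring that subtype's clade.
#' @param query_gene leaf label (or gene id) of the query.
#' @param windows optional [duplication_window()] data.frame enabling
#'   a/b labeling via the `threer_label` window.
#' @param threer_label 3R window label.
#' @param ab_reference optional named list: subtype -> leaf label of the
#'   designated "a" copy.
#' @return list with `status` (`"assigned"` or `"unassignable"`),
#'   `subtype`, and `label` (subtype plus optional a/b suffix).
#' @export
assign_subtype_and_ab <- function(rt, reference_leaves, query_gene,
                                  windows = NULL,
                                  threer_label = "3R_window",
                                  ab_reference = NULL) {
  stopifnot(inherits(rt, "reconciled_tree"))
  tree <- rt$tree
  qi <- match(query_gene, tree$tip.label)
  if (is.na(qi)) qi <- match(query_gene, rt$leaves$gene_id)
  if (is.na(qi)) stop("query gene '", query_gene, "' not found in the tree")
  ref_all <- unlist(reference_leaves, use.names = FALSE)
  missing_ref <- setdiff(ref_all, tree$tip.label)
  if (length(missing_ref))
    stop("reference leaf '", missing_ref[1L], "' not present in the tree")
  subtype_of_leaf <- stats::setNames(
    rep(names(reference_leaves), lengths(reference_leaves)), ref_all)
  ## walk rootward from the query until reference leaves enter the clade
  node <- phy_parent(tree, qi)
  subtype <- NULL
  clade_node <- NA_integer_
  while (!is.na(node)) {
    tips <- tree$tip.label[phy_tips_below(tree, node)]
    refs <- intersect(tips, ref_all)
    if (length(refs)) {
      subs <- unique(subtype_of_leaf[refs])
      if (length(subs) == 1L) { subtype <- subs; clade_node <- node }
      break
    }
    node <- phy_parent(tree, node)
  }
  if (is.null(subtype))
    return(list(status = "unassignable", subtype = NA_character_,
                label = NA_character_))
  label <- subtype
  if (!is.null(windows)) {
    dated <- date_duplication_nodes(rt, windows)
    dn <- dated$node[dated$window == threer_label]
    ## oldest 3R duplication on the query's path within the subtype clade
    path <- qi
    p <- phy_parent(tree, qi)
    while (!is.na(p)) { path <- c(path, p); p <- phy_parent(tree, p)
      if (path[length(path)] == clade_node) break }
    on_path <- intersect(rev(path), dn)  # rootward-first
    if (length(on_path)) {
      d <- on_path[1L]
      kids <- phy_children(tree, d)
      i_q <- match(path[match(d, path) - 1L], kids)
      a_side <- NA_integer_
      aref <- if (!is.null(ab_reference)) ab_reference[[subtype]] else NULL
      if (!is.null(aref) && aref %in% tree$tip.label) {
        ai <- match(aref, tree$tip.label)
        for (ci in seq_along(kids))
          if (ai %in% phy_tips_below(tree, kids[ci])) a_side <- ci
      }
      if (is.na(a_side)) {
        firsts <- vapply(kids, function(k) {
          tps <- phy_tips_below(tree, k)
          min(rt$leaves$species[match(tree$tip.label[tps], rt$leaves$leaf)])
        }, character(1))
        a_side <- which.min(firsts)
      }
      label <- paste0(subtype, if (i_q == a_side) "a" else "b")
    }
  }
  list(status = "assigned", subtype = subtype, label = label)
}
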