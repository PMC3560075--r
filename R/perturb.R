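## nested-list tree representation used for topology surgery
phylo_to_nested <- function(phy) {
  ntip <- ape::Ntip(phy)
  kids <- split(phy$edge[, 2], factor(phy$edge[, 1],
                                      levels = 1:(ntip + phy$Nnode)))
  build <- function(id) {
    if (id <= ntip) return(list(leaf = TRUE, label = phy$tip.label[id]))
    list(leaf = FALSE, children = lapply(kids[[id]], build))
  }
  build(ntip + 1L)
}

nested_to_newick <- function(node) {
  rec <- function(n) {
    if (isTRUE(n$leaf)) return(n$label)
    paste0("(", paste(vapply(n$children, rec, character(1)), collapse = ","),
           ")")
  }
  paste0(rec(node), ";")
}

## count internal edges (parent internal, child internal) of a nested tree
nni_edges <- function(node, path = integer()) {
  if (isTRUE(node$leaf)) return(list())
  out <- list()
  for (i in seq_along(node$children)) {
    ch <- node$children[[i]]
    if (!isTRUE(ch$leaf)) out <- c(out, list(c(path, i)))
    out <- c(out, nni_edges(ch, c(path, i)))
  }
  out
}

nested_get <- function(node, path) {
  for (i in path) node <- node$children[[i]]
  node
}

nested_set <- function(node, path, value) {
  if (!length(path)) return(value)
  node$children[[path[1L]]] <-
    nested_set(node$children[[path[1L]]], path[-1L], value)
  node
}

#' Perturb a gene tree by random nearest-neighbor interchanges
#'
#' Applies `n_nni` random NNI moves to a rooted tree, modeling
#' tree-inference error. Each move picks a random internal edge and
#' swaps one subtree hanging from the edge's child with one sibling
#' subtree at the edge's parent. The leaf set is preserved; branch
#' lengths and support values are dropped (the perturbed topology no
#' longer reflects them).
#'
#' @param tree a rooted `phylo`.
#' @param n_nni number of interchanges (>= 0).
#' @param seed integer seed.
#' @return a `phylo` with the same leaves.
#' @export
perturb_gene_tree <- function(tree, n_nni, seed = 1L) {
  stopifnot(inherits(tree, "phylo"), n_nni >= 0)
  if (n_nni == 0L) return(tree)
  if (ape::Ntip(tree) < 4L)
    stop("NNI perturbation needs a tree with >= 4 leaves")
  set.seed(seed)
  nt <- phylo_to_nested(tree)
  for (k in seq_len(n_nni)) {
    edges <- nni_edges(nt)
    if (!length(edges)) break
    path_c <- edges[[sample.int(length(edges), 1L)]]
    path_p <- path_c[-length(path_c)]
    i_c <- path_c[length(path_c)]
    parent <- nested_get(nt, path_p)
    sibs <- setdiff(seq_along(parent$children), i_c)
    i_s <- if (length(sibs) == 1L) sibs else sample(sibs, 1L)
    child <- parent$children[[i_c]]
    i_g <- sample.int(length(child$children), 1L)
    ## swap sibling subtree with grandchild subtree
    tmp <- parent$children[[i_s]]
    parent$children[[i_s]] <- child$children[[i_g]]
    child$children[[i_g]] <- tmp
    parent$children[[i_c]] <- child
    nt <- nested_set(nt, path_p, parent)
  }
  ape::read.tree(text = nested_to_newick(nt))
}
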