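#' Species tree with named divergence nodes and WGD placements
#'
#' Wraps a rooted `ape::phylo` tree whose internal nodes carry unique
#' names (node labels), together with whole-genome-duplication (WGD)
#' markers placed on branches. A branch is identified by the name of the
#' node at its child end; `position` is the fractional position along the
#' branch from its parent (0 = just after the parent node, 1 = at the
#' child node).
#'
#' @param newick rooted newick string (or `phylo` object) with labeled
#'   internal nodes.
#' @param wgd data.frame with columns `label`, `branch`, `position`, or
#'   `NULL` for none.
#' @return an object of class `species_tree`.
#' @examples
#' st <- species_tree(
#'   "(outgroup,(gar,(teleost1,teleost2)teleost_crown)gar_teleost_split)root;",
#'   wgd = data.frame(label = "3R", branch = "teleost_crown", position = 0.5))
#' @export
species_tree <- function(newick, wgd = NULL) {
  phy <- if (inherits(newick, "phylo")) newick else ape::read.tree(text = newick)
  if (is.null(phy)) stop("could not parse species-tree newick")
  if (!ape::is.rooted(phy)) stop("species tree must be rooted")
  if (is.null(phy$node.label) || any(phy$node.label == ""))
    stop("all internal nodes of the species tree must be named")
  labels <- c(phy$tip.label, phy$node.label)
  if (anyDuplicated(labels))
    stop("species-tree node names must be unique")
  if (is.null(wgd))
    wgd <- data.frame(label = character(), branch = character(),
                      position = numeric())
  wgd <- as.data.frame(wgd)
  stopifnot(all(c("label", "branch", "position") %in% names(wgd)))
  bad <- !(wgd$branch %in% labels)
  if (any(bad))
    stop("WGD marker '", wgd$label[bad][1L],
         "' placed on unknown branch '", wgd$branch[bad][1L], "'")
  if (any(wgd$position < 0 | wgd$position > 1))
    stop("WGD positions must lie in [0, 1]")
  if (anyDuplicated(wgd$label)) stop("WGD labels must be unique")
  root <- ape::Ntip(phy) + 1L
  if (any(st_name_to_id_raw(phy, wgd$branch) == root))
    stop("a WGD marker cannot be placed above the root")
  structure(list(phy = phy, wgd = wgd), class = "species_tree")
}

st_name_to_id_raw <- function(phy, name) {
  id <- match(name, c(phy$tip.label, phy$node.label))
  if (anyNA(id)) stop("unknown species-tree node: ",
                      paste(name[is.na(id)], collapse = ", "))
  id
}

#' @export
print.species_tree <- function(x, ...) {
  cat("species tree:", ape::Ntip(x$phy), "taxa,", nrow(x$wgd),
      "WGD marker(s)\n")
  if (nrow(x$wgd))
    cat(paste0("  ", x$wgd$label, " on branch to ", x$wgd$branch,
               " (position ", x$wgd$position, ")", collapse = "\n"), "\n")
  invisible(x)
}

st_node_id <- function(st, name) st_name_to_id_raw(st$phy, name)

st_node_name <- function(st, id) c(st$phy$tip.label, st$phy$node.label)[id]

st_root <- function(st) ape::Ntip(st$phy) + 1L

st_children <- function(st, id) st$phy$edge[st$phy$edge[, 1] == id, 2]

st_parent <- function(st, id) {
  p <- st$phy$edge[st$phy$edge[, 2] == id, 1]
  if (length(p)) p else NA_integer_
}

## ancestors of id, closest first, excluding id itself
st_ancestors <- function(st, id) {
  out <- integer()
  p <- st_parent(st, id)
  while (!is.na(p)) {
    out <- c(out, p)
    p <- st_parent(st, p)
  }
  out
}

## is a an ancestor of (or equal to) b?
st_is_ancestor <- function(st, a, b, strict = FALSE) {
  if (a == b) return(!strict)
  a %in% st_ancestors(st, b)
}

## MRCA node id of a set of tip labels
st_mrca <- function(st, species) {
  species <- unique(species)
  ids <- st_name_to_id_raw(st$phy, species)
  if (length(ids) == 1L) return(ids)
  ape::getMRCA(st$phy, species)
}

## tip labels descending from node id
st_tips_below <- function(st, id) {
  ntip <- ape::Ntip(st$phy)
  if (id <= ntip) return(st$phy$tip.label[id])
  kids <- st_children(st, id)
  unlist(lapply(kids, st_tips_below, st = st))
}

#' Taxa descended from a WGD event
#'
#' @param st a [species_tree()].
#' @param label WGD marker label.
#' @return character vector of extant taxa whose lineage passed through
#'   the WGD.
#' @export
wgd_descendants <- function(st, label) {
  i <- match(label, st$wgd$label)
  if (is.na(i)) stop("unknown WGD label '", label, "'")
  st_tips_below(st, st_node_id(st, st$wgd$branch[i]))
}

#' Read a species-tree configuration file
#'
#' YAML schema: key `newick` (rooted newick with named internal nodes)
#' and optional key `wgd`, a list of mappings with keys `label`, `branch`
#' (name of the node at the child end of the branch) and `position`
#' (fraction along the branch, default 0.5).
#'
#' @param path path to the YAML config.
#' @return a [species_tree()].
#' @export
read_species_tree <- function(path) {
  if (!file.exists(path)) stop("species-tree config not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$newick)) stop("config lacks a 'newick' key")
  wgd <- NULL
  if (!is.null(cfg$wgd)) {
    wgd <- do.call(rbind, lapply(cfg$wgd, function(w)
      data.frame(label = w$label, branch = w$branch,
                 position = if (is.null(w$position)) 0.5 else w$position)))
  }
  species_tree(cfg$newick, wgd)
}

#' Write a species-tree configuration file
#'
#' @param st a [species_tree()].
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_species_tree <- function(st, path) {
  cfg <- list(newick = ape::write.tree(st$phy))
  if (nrow(st$wgd))
    cfg$wgd <- lapply(seq_len(nrow(st$wgd)), function(i)
      list(label = st$wgd$label[i], branch = st$wgd$branch[i],
           position = st$wgd$position[i]))
  yaml::write_yaml(cfg, path)
  invisible(path)
}
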