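## Internal genome state used by the simulator and by event replay:
##   chrom: named list, chromosome name -> ordered character vector of gene ids
##   fam:   named character vector, gene id -> family id
##   sub:   named character vector, gene id -> subtype label (may be NA)
## Coordinates are not tracked during evolution; genes are re-spaced
## uniformly when a state is exported to a genome (the downstream
## inference uses only order and co-location, not exact bp).

SIM_SPACING_BP <- 1e6
SIM_GENE_BP <- 1000

genome_to_state <- function(g) {
  chrom <- list()
  for (cn in g$chromosomes$name) {
    sub <- g$loci[g$loci$chromosome == cn, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    chrom[[cn]] <- sub$gene_id
  }
  fam <- stats::setNames(g$loci$family_id, g$loci$gene_id)
  sub <- stats::setNames(g$loci$subtype_label, g$loci$gene_id)
  list(chrom = chrom, fam = fam, sub = sub)
}

state_to_genome <- function(state, species) {
  chrom <- state$chrom[lengths(state$chrom) > 0L]
  chrs <- data.frame(name = names(chrom),
                     length = pmax(lengths(chrom), 1L) * SIM_SPACING_BP,
                     placed = TRUE)
  loci <- do.call(rbind, lapply(names(chrom), function(cn) {
    ids <- chrom[[cn]]
    data.frame(gene_id = ids, family_id = unname(state$fam[ids]),
               subtype_label = unname(state$sub[ids]),
               chromosome = cn,
               start = (seq_along(ids) - 1) * SIM_SPACING_BP,
               end = (seq_along(ids) - 1) * SIM_SPACING_BP + SIM_GENE_BP,
               strand = "+")
  }))
  if (is.null(loci))
    loci <- data.frame(gene_id = character(), family_id = character(),
                       subtype_label = character(), chromosome = character(),
                       start = numeric(), end = numeric(),
                       strand = character())
  if (!nrow(chrs))
    chrs <- data.frame(name = "chr0", length = SIM_SPACING_BP, placed = TRUE)
  genome(species, chrs, loci)
}

## deterministic id of a WGD gene/chromosome copy
wgd_copy_id <- function(id, label, copy) paste0(id, "_", label, c("A", "B")[copy])

state_find_gene <- function(state, gene) {
  for (cn in names(state$chrom)) {
    i <- match(gene, state$chrom[[cn]])
    if (!is.na(i)) return(list(chr = cn, index = i))
  }
  stop("gene '", gene, "' does not exist at this point of the history")
}

state_drop_empty <- function(state) {
  state$chrom <- state$chrom[lengths(state$chrom) > 0L]
  state
}

#' Construct an evolutionary event
#'
#' Events are fully explicit: applying an event is deterministic, so an
#' event history sampled by the simulator replays to identical genomes.
#' Kinds and payload fields:
#' \describe{
#'   \item{wgd}{`label`; `lost`: post-duplication gene ids not retained.
#'     Every chromosome and gene is duplicated; copies of `x` are named
#'     `x_<label>A` and `x_<label>B`.}
#'   \item{gene_loss}{`gene`.}
#'   \item{chromosome_fusion}{`chr_a`, `chr_b`, logical `rev_a`, `rev_b`,
#'     `new_name`; joins the two end-to-end.}
#'   \item{chromosome_fission}{`chr`, `after` (genes 1..after stay on the
#'     first product), `new_names` (length 2).}
#'   \item{block_translocation}{`genes` (a contiguous run on one
#'     chromosome), `to`, `at` (0-based insertion offset), `rev`.}
#'   \item{intra_shuffle}{`chr`, `gene`, `new_index` (new 1-based
#'     position of the gene within its chromosome).}
#'   \item{lineage_duplication}{`gene`, `new_id`; tandem duplicate
#'     inserted immediately after its parent.}
#' }
#'
#' @param kind event kind (see Details).
#' @param branch species-tree branch the event belongs to, identified by
#'   the name of the node at the branch's child end.
#' @param payload named list of event parameters.
#' @return an object of class `evo_event`.
#' @export
evo_event <- function(kind, branch, payload = list()) {
  kinds <- c("wgd", "gene_loss", "chromosome_fusion", "chromosome_fission",
             "block_translocation", "intra_shuffle", "lineage_duplication")
  if (!kind %in% kinds)
    stop("unknown event kind '", kind, "'")
  structure(list(kind = kind, branch = branch, payload = payload),
            class = "evo_event")
}

#' Construct an event history
#'
#' An ordered list of [evo_event()]s; events on a branch must appear
#' after events on ancestral branches.
#'
#' @param events list of [evo_event()]s.
#' @return an object of class `event_history`.
#' @export
event_history <- function(events = list()) {
  stopifnot(all(vapply(events, inherits, logical(1), "evo_event")))
  structure(list(events = events), class = "event_history")
}

#' @export
print.event_history <- function(x, ...) {
  cat("event history with", length(x$events), "event(s)\n")
  for (e in x$events)
    cat("  [", e$kind, "] on branch ", e$branch, "\n", sep = "")
  invisible(x)
}

#' @export
length.event_history <- function(x) length(x$events)

apply_event <- function(state, ev) {
  p <- ev$payload
  switch(ev$kind,
    wgd = {
      label <- p$label
      new_chrom <- list()
      for (cn in names(state$chrom)) {
        for (copy in 1:2) {
          ids <- wgd_copy_id(state$chrom[[cn]], label, copy)
          new_chrom[[wgd_copy_id(cn, label, copy)]] <- ids
        }
      }
      old_genes <- names(state$fam)
      fam <- stats::setNames(rep(unname(state$fam), each = 2),
                             as.vector(vapply(old_genes, function(g)
                               c(wgd_copy_id(g, label, 1), wgd_copy_id(g, label, 2)),
                               character(2))))
      sub <- stats::setNames(rep(unname(state$sub), each = 2), names(fam))
      state$chrom <- new_chrom
      state$fam <- fam
      state$sub <- sub
      for (g in p$lost) {
        loc <- state_find_gene(state, g)
        state$chrom[[loc$chr]] <- state$chrom[[loc$chr]][-loc$index]
        state$fam <- state$fam[names(state$fam) != g]
        state$sub <- state$sub[names(state$sub) != g]
      }
      state_drop_empty(state)
    },
    gene_loss = {
      loc <- state_find_gene(state, p$gene)
      state$chrom[[loc$chr]] <- state$chrom[[loc$chr]][-loc$index]
      state$fam <- state$fam[names(state$fam) != p$gene]
      state$sub <- state$sub[names(state$sub) != p$gene]
      state_drop_empty(state)
    },
    chromosome_fusion = {
      if (is.null(state$chrom[[p$chr_a]]) || is.null(state$chrom[[p$chr_b]]))
        stop("fusion references missing chromosome '",
             if (is.null(state$chrom[[p$chr_a]])) p$chr_a else p$chr_b, "'")
      a <- state$chrom[[p$chr_a]]
      b <- state$chrom[[p$chr_b]]
      if (isTRUE(p$rev_a)) a <- rev(a)
      if (isTRUE(p$rev_b)) b <- rev(b)
      state$chrom[[p$chr_a]] <- NULL
      state$chrom[[p$chr_b]] <- NULL
      state$chrom[[p$new_name]] <- c(a, b)
      state
    },
    chromosome_fission = {
      g <- state$chrom[[p$chr]]
      if (is.null(g)) stop("fission references missing chromosome '", p$chr, "'")
      k <- p$after
      if (k < 1 || k >= length(g))
        stop("fission breakpoint out of range on '", p$chr, "'")
      state$chrom[[p$chr]] <- NULL
      state$chrom[[p$new_names[1]]] <- g[seq_len(k)]
      state$chrom[[p$new_names[2]]] <- g[(k + 1):length(g)]
      state
    },
    block_translocation = {
      loc <- state_find_gene(state, p$genes[1])
      run <- state$chrom[[loc$chr]][loc$index + seq_along(p$genes) - 1L]
      if (length(run) != length(p$genes) || !all(run == p$genes))
        stop("translocated genes are not a contiguous run on '", loc$chr, "'")
      if (is.null(state$chrom[[p$to]]))
        stop("translocation destination chromosome '", p$to, "' is missing")
      if (p$to == loc$chr)
        stop("translocation destination equals the source chromosome")
      state$chrom[[loc$chr]] <-
        state$chrom[[loc$chr]][-(loc$index + seq_along(p$genes) - 1L)]
      blk <- if (isTRUE(p$rev)) rev(p$genes) else p$genes
      dst <- state$chrom[[p$to]]
      at <- min(max(p$at, 0L), length(dst))
      state$chrom[[p$to]] <- append(dst, blk, after = at)
      state_drop_empty(state)
    },
    intra_shuffle = {
      loc <- state_find_gene(state, p$gene)
      if (loc$chr != p$chr)
        stop("gene '", p$gene, "' is not on chromosome '", p$chr, "'")
      g <- state$chrom[[p$chr]][-loc$index]
      ni <- min(max(p$new_index, 1L), length(g) + 1L)
      state$chrom[[p$chr]] <- append(g, p$gene, after = ni - 1L)
      state
    },
    lineage_duplication = {
      loc <- state_find_gene(state, p$gene)
      if (p$new_id %in% names(state$fam))
        stop("duplicate gene id '", p$new_id, "'")
      state$chrom[[loc$chr]] <- append(state$chrom[[loc$chr]], p$new_id,
                                       after = loc$index)
      state$fam[p$new_id] <- state$fam[[p$gene]]
      state$sub[p$new_id] <- state$sub[[p$gene]]
      state
    },
    stop("unknown event kind '", ev$kind, "'")
  )
}

#' Replay an explicit event history from an ancestral genome
#'
#' Deterministically applies an [event_history()] to an ancestral
#' [genome()]. With a [species_tree()], each extant taxon receives the
#' prefix of events lying on its root-to-tip path (branches are named by
#' the node at their child end; the root's name labels events preceding
#' the first split). Without a tree the whole history is treated as one
#' linear lineage.
#'
#' Gene coordinates in the returned genomes are re-spaced uniformly
#' (1 Mb per gene): the inference stages consume only gene order and
#' co-location.
#'
#' @param history an [event_history()].
#' @param ancestral the ancestral [genome()].
#' @param species_tree optional [species_tree()] naming the lineages.
#' @param stop_at optional species-tree node name (or, without a tree,
#'   an event index): replay halts after the events at or before that
#'   point and the single genome at that point is returned.
#' @return named list of [genome()] objects, one per lineage tip (or a
#'   single-element list when `species_tree` is `NULL` or `stop_at` is
#'   used).
#' @export
replay_events <- function(history, ancestral, species_tree = NULL,
                          stop_at = NULL) {
  stopifnot(inherits(history, "event_history"))
  evs <- history$events
  apply_seq <- function(state, events, idx) {
    for (j in seq_along(events)) {
      state <- tryCatch(apply_event(state, events[[j]]),
                        error = function(e)
                          stop("replay error at event ", idx[j], ": ",
                               conditionMessage(e), call. = FALSE))
    }
    state
  }
  if (is.null(species_tree)) {
    keep <- seq_along(evs)
    if (!is.null(stop_at)) keep <- keep[keep <= stop_at]
    st0 <- apply_seq(genome_to_state(ancestral), evs[keep], keep)
    return(list(root = state_to_genome(st0, ancestral$species)))
  }
  st <- species_tree
  lineage_names <- function(tip) {
    path <- rev(c(tip, st_ancestors(st, st_node_id(st, tip))))
    st_node_name(st, path[-1])  # branches below the root, plus root events
  }
  replay_to <- function(target_name) {
    id <- st_node_id(st, target_name)
    path_ids <- c(rev(st_ancestors(st, id)), id)
    path_names <- st_node_name(st, path_ids)
    keep <- which(vapply(evs, function(e) e$branch %in% path_names,
                         logical(1)))
    sta <- apply_seq(genome_to_state(ancestral), evs[keep], keep)
    state_to_genome(sta, target_name)
  }
  if (!is.null(stop_at)) {
    out <- list(replay_to(stop_at))
    names(out) <- stop_at
    return(out)
  }
  tips <- st$phy$tip.label
  out <- lapply(tips, replay_to)
  names(out) <- tips
  out
}

#' Write / read an event history as JSON lines
#'
#' One event per line: `{"kind": ..., "branch": ..., "payload": {...}}`.
#'
#' @param history an [event_history()].
#' @param path file path.
#' @return `path` invisibly (writer); an [event_history()] (reader).
#' @export
write_event_history <- function(history, path) {
  lines <- vapply(history$events, function(e)
    jsonlite::toJSON(list(kind = e$kind, branch = e$branch,
                          payload = e$payload),
                     auto_unbox = TRUE, null = "null"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_event_history
#' @export
read_event_history <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  evs <- lapply(lines, function(l) {
    x <- jsonlite::fromJSON(l, simplifyVector = TRUE)
    pl <- lapply(x$payload, function(v) v)
    evo_event(x$kind, x$branch, pl)
  })
  event_history(evs)
}
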