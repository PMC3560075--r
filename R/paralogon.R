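## merge a family-location table with per-gene duplication classes
merge_table_classes <- function(table, classes) {
  m <- merge(as.data.frame(table), classes[, c("species", "gene_id",
                                               "twor_class", "threer_copy")],
             by = c("species", "gene_id"), all.x = TRUE)
  m$twor_class[is.na(m$twor_class)] <- ""
  m$threer_copy[is.na(m$threer_copy)] <- ""
  m[order(m$family_id, m$species, m$chromosome, m$pos_mb), ]
}

#' Combine per-family gene-copy classes
#'
#' Runs [classify_gene_copies()] over a set of family trees and stacks
#' the results with a `family_id` column.
#'
#' @param gene_trees named list of rooted `phylo` (names = family ids).
#' @param species_tree a [species_tree()].
#' @param windows [duplication_window()] data.frame.
#' @param ... passed to [classify_gene_copies()].
#' @return data.frame: `family_id`, `leaf`, `species`, `gene_id`,
#'   `twor_class`, `threer_copy`.
#' @export
classify_all_copies <- function(gene_trees, species_tree, windows, ...) {
  out <- lapply(names(gene_trees), function(f) {
    cc <- classify_gene_copies(gene_trees[[f]], species_tree, windows, ...)
    cbind(family_id = f, cc)
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(family_id = character(), leaf = character(),
                      species = character(), gene_id = character(),
                      twor_class = character(), threer_copy = character())
  rownames(res) <- NULL
  res
}

#' Assemble paralogons from positional and timing evidence
#'
#' Builds a graph whose nodes are (species, chromosome) regions; an edge
#' joins two regions when they hold WGD-window paralogs of the same
#' family (genes of the same family with different duplication-path
#' classes). Edges supported by fewer than `min_support` distinct
#' families are dropped; paralogons are the remaining connected
#' components.
#'
#' @param table a [tabulate_family_locations()] result.
#' @param classes gene-copy classes from [classify_all_copies()]; only
#'   genes present in both are used.
#' @param verdicts optional list of `family_verdict`s: when given, only
#'   families with verdict `supports_WGD` or `consistent` contribute.
#' @param min_support minimum distinct families per edge (default 2: a
#'   single shared family cannot distinguish synteny from coincidence).
#' @param class_col which class column relates the regions
#'   (`"twor_class"` for 2R paralogons, `"threer_copy"` for 3R).
#' @return list of `paralogon` objects, deterministically ordered.
#' @export
assemble_paralogons <- function(table, classes, verdicts = NULL,
                                min_support = 2L,
                                class_col = "twor_class") {
  m <- merge_table_classes(table, classes)
  if (!is.null(verdicts)) {
    ok <- vapply(verdicts, function(v)
      if (v$verdict %in% c("supports_WGD", "consistent")) v$family_id
      else NA_character_, character(1))
    m <- m[m$family_id %in% ok[!is.na(ok)], , drop = FALSE]
  }
  m$region <- paste(m$species, m$chromosome, sep = ":")
  m$cl <- m[[class_col]]
  m <- m[nzchar(m$cl), , drop = FALSE]
  if (!nrow(m)) return(list())
  ## edges: same family, different class, different region
  edges <- list()
  for (f in unique(m$family_id)) {
    sub <- m[m$family_id == f, , drop = FALSE]
    combos <- unique(sub[, c("region", "cl")])
    if (nrow(combos) < 2L) next
    for (i in seq_len(nrow(combos) - 1L))
      for (j in (i + 1L):nrow(combos)) {
        if (combos$region[i] == combos$region[j]) next
        if (combos$cl[i] == combos$cl[j]) next
        r <- sort(c(combos$region[i], combos$region[j]))
        edges[[length(edges) + 1L]] <- data.frame(
          from = r[1L], to = r[2L], family_id = f)
      }
  }
  if (!length(edges)) return(list())
  ed <- unique(do.call(rbind, edges))
  key <- paste(ed$from, ed$to, sep = "~")
  support <- tapply(ed$family_id, key, function(x) length(unique(x)))
  keep <- names(support)[support >= min_support]
  if (!length(keep)) return(list())
  ed <- ed[key %in% keep, , drop = FALSE]
  g <- igraph::graph_from_data_frame(unique(ed[, c("from", "to")]),
                                     directed = FALSE)
  comp <- igraph::components(g)
  out <- list()
  for (ci in seq_len(comp$no)) {
    regions <- sort(names(comp$membership)[comp$membership == ci])
    fams <- sort(unique(ed$family_id[ed$from %in% regions |
                                       ed$to %in% regions]))
    members <- m[m$region %in% regions, , drop = FALSE]
    rownames(members) <- NULL
    parts <- do.call(rbind, strsplit(regions, ":", fixed = TRUE))
    out[[length(out) + 1L]] <- structure(
      list(id = NA_integer_,
           regions = data.frame(species = parts[, 1L],
                                chromosome = parts[, 2L],
                                region = regions),
           supporting_families = fams,
           members = members,
           wgd_label = if (class_col == "twor_class") "2R" else "3R"),
      class = "paralogon")
  }
  ## deterministic ordering by first region name
  ord <- order(vapply(out, function(p) p$regions$region[1L], character(1)))
  out <- out[ord]
  for (i in seq_along(out)) out[[i]]$id <- i
  out
}

#' @export
print.paralogon <- function(x, ...) {
  cat("paralogon", x$id, "(", x$wgd_label, "):",
      nrow(x$regions), "regions,",
      length(x$supporting_families), "supporting families\n")
  cat("  regions:", paste(x$regions$region, collapse = ", "), "\n")
  invisible(x)
}

new_rearrangement_call <- function(kind, species, chromosomes, timing,
                                   families, interval_mb = NULL) {
  structure(list(kind = kind, species = species, chromosomes = chromosomes,
                 timing = timing, families = sort(unique(families)),
                 n_families = length(unique(families)),
                 interval_mb = interval_mb),
            class = "rearrangement_call")
}

#' @export
print.rearrangement_call <- function(x, ...) {
  cat(sprintf("%s in %s (%s), timing %s, %d families\n", x$kind, x$species,
              paste(x$chromosomes, collapse = "+"), x$timing, x$n_families))
  invisible(x)
}

#' Infer chromosome fusions and their timing relative to 3R
#'
#' A chromosome carrying members of two or more distinct 2R-window
#' paralogy classes, each co-location supported by at least
#' `min_support` families, implies a fusion. The fusion predates 3R
#' when the co-located members are 2R-generated paralogs (different 2R
#' classes) rather than 3R a/b duplicates of one class; it postdates 3R
#' when only a/b duplicates are co-located. Conflicts are resolved by
#' family majority; ties, and all calls in lineages that never passed
#' through the 3R event, are `indeterminate`.
#'
#' @param paralogons output of [assemble_paralogons()].
#' @param species_tree a [species_tree()]; its `threer_label` marker
#'   determines which taxa experienced 3R.
#' @param min_support minimum distinct families (default 2).
#' @param threer_label WGD marker label for the teleost duplication.
#' @return list of `rearrangement_call` objects.
#' @export
infer_fusion_timing <- function(paralogons, species_tree, min_support = 2L,
                                threer_label = "3R") {
  post3R <- if (threer_label %in% species_tree$wgd$label)
    wgd_descendants(species_tree, threer_label) else character()
  calls <- list()
  for (p in paralogons) {
    for (ri in seq_len(nrow(p$regions))) {
      sp <- p$regions$species[ri]
      chr <- p$regions$chromosome[ri]
      sub <- p$members[p$members$species == sp &
                         p$members$chromosome == chr, , drop = FALSE]
      if (!nrow(sub)) next
      ## families with co-located distinct 2R classes on this chromosome
      fams2 <- vapply(split(sub, sub$family_id), function(s)
        length(unique(s$twor_class[nzchar(s$twor_class)])) >= 2L, logical(1))
      fams2 <- names(fams2)[fams2]
      ## families with co-located 3R a/b duplicates of one 2R class
      fams3 <- vapply(split(sub, sub$family_id), function(s) {
        any(vapply(split(s, s$twor_class), function(z)
          length(unique(z$threer_copy[nzchar(z$threer_copy)])) >= 2L,
          logical(1)))
      }, logical(1))
      fams3 <- names(fams3)[fams3]
      n2 <- length(fams2); n3 <- length(fams3)
      if (max(n2, n3) < min_support) next
      in3R <- sp %in% post3R
      timing <- if (!in3R) "indeterminate"
        else if (n2 >= min_support && n2 > n3) "before_3R"
        else if (n3 >= min_support && n3 > n2) "after_3R"
        else "indeterminate"
      calls[[length(calls) + 1L]] <-
        new_rearrangement_call("fusion", sp, chr, timing,
                               union(fams2, fams3))
    }
  }
  calls
}

#' Infer small-block translocations between two genomes
#'
#' Compares orthologs (same family and 2R duplication class) between a
#' reference and a derived genome. When the reference copies of several
#' families share one chromosome but their derived counterparts are
#' split across chromosomes, the displaced derived genes (those off the
#' majority chromosome) are reported; displaced genes lying within
#' `window_mb` of each other on one derived chromosome are merged into
#' a single block call with its interval.
#'
#' @param table a [tabulate_family_locations()] result covering both
#'   genomes.
#' @param classes gene-copy classes from [classify_all_copies()].
#' @param reference_species,derived_species species identifiers present
#'   in the table.
#' @param window_mb maximum gap between displaced genes merged into one
#'   block (default 1 Mb).
#' @return list of `rearrangement_call` objects (kind
#'   `"translocation"`, timing `"indeterminate"`).
#' @export
infer_block_rearrangements <- function(table, classes, reference_species,
                                       derived_species, window_mb = 1) {
  tab <- as.data.frame(table)
  if (!reference_species %in% tab$species)
    stop("reference genome '", reference_species, "' absent from the table")
  m <- merge_table_classes(table, classes)
  ## orthology unit: family + 2R class + 3R side, so a/b ohnolog pairs
  ## are compared copy-by-copy
  m$unit <- paste(m$twor_class, m$threer_copy, sep = "&")
  ref <- m[m$species == reference_species, , drop = FALSE]
  der <- m[m$species == derived_species, , drop = FALSE]
  calls <- list()
  for (rc in unique(ref$chromosome)) {
    anchored <- unique(ref[ref$chromosome == rc, c("family_id", "unit")])
    ## require the reference copies of the unit to be confined to rc
    confined <- vapply(seq_len(nrow(anchored)), function(i) {
      rr <- ref[ref$family_id == anchored$family_id[i] &
                  ref$unit == anchored$unit[i], ]
      length(unique(rr$chromosome)) == 1L
    }, logical(1))
    anchored <- anchored[confined, , drop = FALSE]
    if (!nrow(anchored)) next
    dd <- merge(der, anchored, by = c("family_id", "unit"))
    if (!nrow(dd)) next
    main <- names(sort(table(dd$chromosome), decreasing = TRUE))[1L]
    disp <- dd[dd$chromosome != main, , drop = FALSE]
    if (!nrow(disp)) next
    for (dc in unique(disp$chromosome)) {
      sub <- disp[disp$chromosome == dc, , drop = FALSE]
      sub <- sub[order(sub$pos_mb), , drop = FALSE]
      run_id <- cumsum(c(1, diff(sub$pos_mb) > window_mb + 1e-9))
      for (r in unique(run_id)) {
        blk <- sub[run_id == r, , drop = FALSE]
        calls[[length(calls) + 1L]] <- new_rearrangement_call(
          "translocation", derived_species, dc, "indeterminate",
          blk$family_id,
          interval_mb = c(min(blk$pos_mb), max(blk$pos_mb)))
      }
    }
  }
  calls
}
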