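#' Define a chromosome block around a focal gene
#'
#' The screening unit for conserved synteny: an interval extending
#' `radius_mb` megabases in each direction of the focal gene's midpoint,
#' clamped to the chromosome; when the radius exceeds the chromosome the
#' block is the whole chromosome.
#'
#' @param genome a [genome()].
#' @param focal_gene gene identifier; must lie on a placed chromosome.
#' @param radius_mb block radius in Mb (default 15).
#' @return an object of class `chromosome_block` with fields `species`,
#'   `chromosome`, `start`, `end` (bp, half-open) and `focal_gene`.
#' @export
define_block <- function(genome, focal_gene, radius_mb = 15) {
  stopifnot(radius_mb > 0)
  r <- locus_row(genome, focal_gene)
  chr <- genome$chromosomes[match(r$chromosome, genome$chromosomes$name), ]
  if (!chr$placed)
    stop("focal gene '", focal_gene,
         "' lies on an unplaced scaffold; block undefined")
  mid <- (r$start + r$end) / 2
  structure(list(species = genome$species, chromosome = r$chromosome,
                 start = max(0, mid - radius_mb * 1e6),
                 end = min(chr$length, mid + radius_mb * 1e6),
                 focal_gene = focal_gene),
            class = "chromosome_block")
}

#' @export
print.chromosome_block <- function(x, ...) {
  cat(sprintf("block %s:%s [%.2f, %.2f] Mb around %s\n", x$species,
              x$chromosome, x$start / 1e6, x$end / 1e6, x$focal_gene))
  invisible(x)
}

#' Gene families represented in a chromosome block
#'
#' A family is represented when at least `min_members` of its loci have
#' midpoints inside the half-open interval `[start, end)`.
#'
#' @param block a [define_block()] result.
#' @param genome the [genome()] the block belongs to.
#' @param min_members minimum loci required to count as represented
#'   (default 1).
#' @return sorted character vector of family ids.
#' @export
families_in_block <- function(block, genome, min_members = 1L) {
  if (block$species != genome$species)
    stop("block belongs to '", block$species, "', not '", genome$species, "'")
  lo <- genome$loci
  mid <- (lo$start + lo$end) / 2
  inside <- lo$chromosome == block$chromosome &
    mid >= block$start & mid < block$end
  tab <- table(lo$family_id[inside])
  keep <- names(tab)[tab >= min_members]
  sort(as.character(keep))
}

#' Specify anchor blocks for neighboring-family selection
#'
#' `dual_anchor` mirrors the two-chromosome screen (two blocks per
#' genome); `triple_anchor` the three-chromosome screen.
#'
#' @param mode `"dual_anchor"` or `"triple_anchor"`.
#' @param primary_genome,secondary_genome species identifiers.
#' @param primary_blocks,secondary_blocks lists of
#'   [define_block()] results (2 for dual, 3 for triple, per genome).
#' @return an object of class `anchor_spec`.
#' @export
anchor_spec <- function(mode = c("dual_anchor", "triple_anchor"),
                        primary_genome, primary_blocks,
                        secondary_genome, secondary_blocks) {
  mode <- match.arg(mode)
  need <- if (mode == "dual_anchor") 2L else 3L
  if (length(primary_blocks) != need || length(secondary_blocks) != need)
    stop(mode, " requires exactly ", need, " blocks per genome")
  structure(list(mode = mode,
                 primary_genome = primary_genome,
                 primary_blocks = primary_blocks,
                 secondary_genome = secondary_genome,
                 secondary_blocks = secondary_blocks),
            class = "anchor_spec")
}

#' Select neighboring gene families by conserved synteny
#'
#' Dual-anchor rule: families represented on both primary-genome blocks,
#' in union with families on both secondary-genome blocks that also
#' appear on at least one primary block. Triple-anchor rule: families on
#' all three blocks of a genome, for either genome (union of the two
#' triple intersections).
#'
#' @param spec an [anchor_spec()].
#' @param genomes named list of [genome()] objects.
#' @param include_focal keep the focal genes' own family (default TRUE:
#'   the focal family is part of its own paralogon evidence).
#' @param min_members per-block membership threshold, see
#'   [families_in_block()].
#' @return lexicographically sorted character vector of family ids.
#' @export
select_neighbor_families <- function(spec, genomes, include_focal = TRUE,
                                     min_members = 1L) {
  stopifnot(inherits(spec, "anchor_spec"))
  gp <- genomes[[spec$primary_genome]]
  gs <- genomes[[spec$secondary_genome]]
  if (is.null(gp) || is.null(gs))
    stop("anchor genomes must be present in 'genomes'")
  fp <- lapply(spec$primary_blocks, families_in_block, genome = gp,
               min_members = min_members)
  fs <- lapply(spec$secondary_blocks, families_in_block, genome = gs,
               min_members = min_members)
  if (spec$mode == "dual_anchor") {
    both_p <- intersect(fp[[1]], fp[[2]])
    both_s <- intersect(fs[[1]], fs[[2]])
    extra <- intersect(both_s, union(fp[[1]], fp[[2]]))
    out <- union(both_p, extra)
  } else {
    all_p <- Reduce(intersect, fp)
    all_s <- Reduce(intersect, fs)
    out <- union(all_p, all_s)
  }
  if (!include_focal) {
    focal_fams <- unique(c(
      vapply(spec$primary_blocks, function(b)
        locus_row(gp, b$focal_gene)$family_id, character(1)),
      vapply(spec$secondary_blocks, function(b)
        locus_row(gs, b$focal_gene)$family_id, character(1))))
    out <- setdiff(out, focal_fams)
  }
  sort(out)
}

#' Tabulate chromosomal locations of gene families across genomes
#'
#' Builds the family-location chart: one row per (family, species,
#' chromosome, gene), with positions in Mb, ordered by family, species,
#' chromosome, position.
#'
#' @param families character vector of family ids (may be empty).
#' @param genomes named list of [genome()] objects.
#' @return data.frame of class `family_location_table` with columns
#'   `family_id`, `species`, `chromosome`, `gene_id`, `pos_mb`,
#'   `subtype_label`.
#' @export
tabulate_family_locations <- function(families, genomes) {
  rows <- list()
  for (g in genomes) {
    lo <- g$loci[g$loci$family_id %in% families, , drop = FALSE]
    if (!nrow(lo)) next
    rows[[length(rows) + 1L]] <- data.frame(
      family_id = lo$family_id, species = g$species,
      chromosome = lo$chromosome, gene_id = lo$gene_id,
      pos_mb = (lo$start + lo$end) / 2 / 1e6,
      subtype_label = lo$subtype_label)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(family_id = character(), species = character(),
               chromosome = character(), gene_id = character(),
               pos_mb = numeric(), subtype_label = character())
  out <- out[order(out$family_id, out$species, out$chromosome, out$pos_mb), ]
  rownames(out) <- NULL
  class(out) <- c("family_location_table", "data.frame")
  out
}

#' Write a family-location table
#'
#' `format = "tsv"` writes the long chart; `format = "wide"` writes one
#' column per (species, chromosome) with comma-separated
#' `gene@position` entries, emulating per-species chart tabs;
#' `format = "json"` writes the long chart as JSON.
#'
#' @param table a [tabulate_family_locations()] result.
#' @param path output path.
#' @param format `"tsv"`, `"wide"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_family_locations <- function(table, path,
                                   format = c("tsv", "wide", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(table, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else if (format == "json") {
    jsonlite::write_json(as.data.frame(table), path, digits = NA)
  } else {
    key <- paste(table$species, table$chromosome, sep = ":")
    cols <- sort(unique(key))
    fams <- sort(unique(table$family_id))
    m <- matrix("", nrow = length(fams), ncol = length(cols),
                dimnames = list(fams, cols))
    for (i in seq_len(nrow(table))) {
      cell <- paste0(table$gene_id[i], "@",
                     formatC(table$pos_mb[i], format = "f", digits = 2))
      k <- key[i]; f <- table$family_id[i]
      m[f, k] <- if (nzchar(m[f, k])) paste(m[f, k], cell, sep = ",") else cell
    }
    out <- data.frame(family_id = fams, m, check.names = FALSE)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
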