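#' Genome, chromosome and gene-locus containers
#'
#' A `genome` holds the chromosomes (or scaffolds) of one species together
#' with its family-labeled gene loci. Coordinates are 0-based, half-open
#' (BED convention); point positions printed in megabases are stored as
#' 1-bp loci at the printed coordinate.
#'
#' @param species single species identifier.
#' @param chromosomes data.frame with columns `name`, `length` (bp) and
#'   logical `placed` (`FALSE` for unplaced scaffolds). `placed` defaults
#'   to `TRUE` when missing.
#' @param loci data.frame with columns `gene_id`, `family_id`,
#'   `subtype_label` (may be `NA`), `chromosome`, `start`, `end`, `strand`
#'   (one of `"+"`, `"-"`, `"*"`).
#' @return an object of class `genome`.
#' @examples
#' chr <- data.frame(name = "1", length = 5e6, placed = TRUE)
#' loc <- data.frame(gene_id = "g1", family_id = "F1", subtype_label = NA,
#'                   chromosome = "1", start = 1e6, end = 1e6 + 1, strand = "+")
#' g <- genome("sp1", chr, loc)
#' @export
genome <- function(species, chromosomes, loci) {
  stopifnot(is.character(species), length(species) == 1L)
  chromosomes <- as.data.frame(chromosomes)
  loci <- as.data.frame(loci)
  if (is.null(chromosomes$placed)) chromosomes$placed <- TRUE
  if (is.null(loci$subtype_label)) loci$subtype_label <- NA_character_
  if (is.null(loci$strand)) loci$strand <- "*"
  need_chr <- c("name", "length", "placed")
  need_loc <- c("gene_id", "family_id", "subtype_label", "chromosome",
                "start", "end", "strand")
  if (!all(need_chr %in% names(chromosomes)))
    stop("chromosome table must have columns: ", paste(need_chr, collapse = ", "))
  if (!all(need_loc %in% names(loci)))
    stop("locus table must have columns: ", paste(need_loc, collapse = ", "))
  chromosomes <- chromosomes[, need_chr]
  loci <- loci[, need_loc]
  rownames(chromosomes) <- rownames(loci) <- NULL
  obj <- structure(list(species = species, chromosomes = chromosomes,
                        loci = loci),
                   class = "genome")
  validate_genome(obj)
  obj
}

validate_genome <- function(g) {
  ch <- g$chromosomes
  lo <- g$loci
  if (anyDuplicated(ch$name))
    stop("duplicate chromosome names in genome '", g$species, "'")
  if (any(ch$length <= 0))
    stop("chromosome lengths must be positive")
  if (nrow(lo)) {
    if (anyDuplicated(lo$gene_id)) {
      dup <- lo$gene_id[duplicated(lo$gene_id)][1L]
      stop("duplicate gene_id '", dup, "' in genome '", g$species, "'")
    }
    bad <- !(lo$chromosome %in% ch$name)
    if (any(bad))
      stop("locus '", lo$gene_id[bad][1L], "' references unknown chromosome '",
           lo$chromosome[bad][1L], "'")
    if (any(lo$start < 0) || any(lo$start >= lo$end))
      stop("loci must satisfy 0 <= start < end")
    len <- ch$length[match(lo$chromosome, ch$name)]
    if (any(lo$end > len))
      stop("locus '", lo$gene_id[which(lo$end > len)[1L]],
           "' extends beyond its chromosome")
  }
  invisible(g)
}

#' @export
print.genome <- function(x, ...) {
  cat("genome of", x$species, "-", nrow(x$chromosomes), "chromosomes,",
      nrow(x$loci), "loci\n")
  invisible(x)
}

locus_row <- function(genome, gene_id) {
  i <- match(gene_id, genome$loci$gene_id)
  if (is.na(i)) stop("unknown gene '", gene_id, "' in genome '",
                     genome$species, "'")
  genome$loci[i, , drop = FALSE]
}

#' Midpoint of a locus in megabases
#'
#' @param genome a [genome()].
#' @param gene_id gene identifier.
#' @return midpoint position in Mb.
#' @export
locus_midpoint_mb <- function(genome, gene_id) {
  r <- locus_row(genome, gene_id)
  (r$start + r$end) / 2 / 1e6
}

check_placed <- function(genome, rows) {
  pl <- genome$chromosomes$placed[match(rows$chromosome, genome$chromosomes$name)]
  if (any(!pl))
    stop("gene '", rows$gene_id[!pl][1L],
         "' lies on an unplaced scaffold; distances are undefined")
}

#' Distance between two loci in megabases
#'
#' Absolute distance between locus midpoints, in Mb (1 Mb = 1e6 bp).
#' Both genes must lie on the same placed chromosome.
#'
#' @inheritParams locus_midpoint_mb
#' @param gene_a,gene_b gene identifiers.
#' @return non-negative distance in Mb.
#' @export
locus_distance_mb <- function(genome, gene_a, gene_b) {
  ra <- locus_row(genome, gene_a)
  rb <- locus_row(genome, gene_b)
  if (ra$chromosome != rb$chromosome)
    stop("genes '", gene_a, "' and '", gene_b,
         "' lie on different chromosomes; distance undefined")
  check_placed(genome, rbind(ra, rb))
  abs(ra$start + ra$end - rb$start - rb$end) / 2 / 1e6
}

#' Span of a set of loci in megabases
#'
#' Difference between the largest and smallest locus midpoint, in Mb.
#' All genes must lie on one placed chromosome.
#'
#' @inheritParams locus_midpoint_mb
#' @param genes non-empty character vector of gene identifiers.
#' @return span in Mb (0 for a single gene).
#' @export
region_span_mb <- function(genome, genes) {
  if (length(genes) == 0L) stop("gene list must be non-empty")
  rows <- do.call(rbind, lapply(genes, locus_row, genome = genome))
  if (length(unique(rows$chromosome)) > 1L)
    stop("genes span multiple chromosomes; region span undefined")
  check_placed(genome, rows)
  mids <- (rows$start + rows$end) / 2 / 1e6
  max(mids) - min(mids)
}

#' Count loci of a gene family in a genome
#'
#' @inheritParams locus_midpoint_mb
#' @param family_id family identifier; an unknown family counts 0.
#' @return non-negative integer.
#' @export
count_family_loci <- function(genome, family_id) {
  sum(genome$loci$family_id == family_id)
}

#' Round to integer megabases, half away from zero
#'
#' Matches the conventional reading of "approximately N Mb": 7.99 -> 8,
#' 10.95 -> 11, 4.62 -> 5.
#'
#' @param x numeric vector of Mb values.
#' @return integer vector.
#' @export
round_mb <- function(x) as.integer(floor(x + 0.5))
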