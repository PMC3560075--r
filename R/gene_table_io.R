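#' Read a gene coordinate table into genomes
#'
#' The gene table is a TSV with header columns `species`, `chromosome`,
#' `start`, `end`, `strand`, `gene_id`, `family_id`, `subtype_label`;
#' lines beginning with `#` are comments. Chromosome lengths come from a
#' sidecar TSV (`chromosome`, `length`, `placed`, optionally `species`);
#' when no sidecar is given, lengths are padded to the last locus plus
#' 1 Mb and every chromosome is treated as placed.
#'
#' @param path path to the gene table TSV.
#' @param chromosomes_path optional path to the chromosome-length sidecar.
#' @return named list of [genome()] objects, one per species.
#' @export
read_gene_table <- function(path, chromosomes_path = NULL) {
  if (!file.exists(path)) stop("gene table not found: ", path)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("species", "chromosome", "start", "end", "strand", "gene_id",
            "family_id")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("gene table ", path, " is missing required column(s): ",
         paste(miss, collapse = ", "))
  if (is.null(df$subtype_label)) df$subtype_label <- NA_character_
  df$subtype_label[df$subtype_label %in% c("", "NA")] <- NA_character_
  for (col in c("start", "end")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad))
      stop("non-numeric ", col, " at line ", bad[1L] + 1L, " of ", path)
    df[[col]] <- v
  }
  dup <- df$gene_id[duplicated(paste(df$species, df$gene_id))]
  if (length(dup)) {
    lines <- which(df$gene_id == dup[1L]) + 1L
    stop("duplicate gene_id '", dup[1L], "' at lines ",
         paste(lines, collapse = " and "), " of ", path)
  }
  side <- NULL
  if (!is.null(chromosomes_path)) {
    side <- utils::read.delim(chromosomes_path, comment.char = "#",
                              stringsAsFactors = FALSE)
    if (!all(c("chromosome", "length") %in% names(side)))
      stop("chromosome sidecar must have columns chromosome, length")
    if (is.null(side$placed)) side$placed <- TRUE
    side$placed <- as.logical(side$placed)
  }
  out <- list()
  for (sp in unique(df$species)) {
    sub <- df[df$species == sp, , drop = FALSE]
    chr_names <- unique(sub$chromosome)
    if (!is.null(side)) {
      ss <- if (!is.null(side$species)) side[side$species == sp, ] else side
      i <- match(chr_names, ss$chromosome)
      maxend <- vapply(chr_names, function(cn)
        max(sub$end[sub$chromosome == cn]), numeric(1))
      chrs <- data.frame(
        name = chr_names,
        length = ifelse(is.na(i), maxend + 1e6, ss$length[i]),
        placed = ifelse(is.na(i), TRUE, ss$placed[i]))
    } else {
      maxend <- vapply(chr_names, function(cn)
        max(sub$end[sub$chromosome == cn]), numeric(1))
      chrs <- data.frame(name = chr_names, length = maxend + 1e6,
                         placed = TRUE)
    }
    out[[sp]] <- genome(sp, chrs,
                        sub[, c("gene_id", "family_id", "subtype_label",
                                "chromosome", "start", "end", "strand")])
  }
  out
}

#' Write genomes to the gene-table format
#'
#' Inverse of [read_gene_table()]; also writes the chromosome sidecar when
#' `chromosomes_path` is given, so that a round trip reproduces the
#' genomes exactly.
#'
#' @param genomes a [genome()] or list of genomes.
#' @param path output TSV path.
#' @param chromosomes_path optional sidecar TSV path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(genomes, path, chromosomes_path = NULL) {
  if (inherits(genomes, "genome")) genomes <- list(genomes)
  rows <- do.call(rbind, lapply(genomes, function(g) {
    lo <- g$loci
    data.frame(species = g$species, chromosome = lo$chromosome,
               start = lo$start, end = lo$end, strand = lo$strand,
               gene_id = lo$gene_id, family_id = lo$family_id,
               subtype_label = lo$subtype_label)
  }))
  if (is.null(rows))
    rows <- data.frame(species = character(), chromosome = character(),
                       start = numeric(), end = numeric(),
                       strand = character(), gene_id = character(),
                       family_id = character(), subtype_label = character())
  utils::write.table(format(rows, scientific = FALSE, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(chromosomes_path)) {
    side <- do.call(rbind, lapply(genomes, function(g)
      cbind(species = g$species, g$chromosomes)))
    names(side)[names(side) == "name"] <- "chromosome"
    utils::write.table(format(side, scientific = FALSE, trim = TRUE),
                       chromosomes_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
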