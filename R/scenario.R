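#' Reconstruct a replayable rearrangement scenario for one lineage
#'
#' Turns fusion/translocation calls and dated gene-copy classes into an
#' ordered, fully explicit [event_history()] for the lineage of one
#' derived (post-3R) genome: an inferred pre-3R ancestor (one
#' chromosome per 2R paralogy class), pre-3R fusions for classes
#' co-located by `before_3R` fusion calls, the 3R doubling with the
#' observed ohnolog retention, then post-3R translocations and fissions
#' that carry every informative gene to its observed chromosome.
#' Post-3R translocations have no resolvable relative order and are
#' emitted as an unordered group (flagged); contradictory timing on one
#' chromosome is reported in `conflicts`, never silently resolved.
#'
#' Only informative genes (non-empty 2R duplication class) are modeled;
#' within-chromosome gene order is not reconstructed.
#'
#' @param calls list of `rearrangement_call`s (from
#'   [infer_fusion_timing()] / [infer_block_rearrangements()]).
#' @param paralogons output of [assemble_paralogons()] (regions must
#'   cover the calls).
#' @param species_tree a [species_tree()] carrying the `threer_label`
#'   marker.
#' @param table a [tabulate_family_locations()] result.
#' @param classes gene-copy classes from [classify_all_copies()].
#' @param focal_species the derived genome whose lineage is
#'   reconstructed; must descend from the 3R event.
#' @param threer_label WGD marker label (default `"3R"`).
#' @return an object of class `scenario`: `ancestor` (a [genome()]),
#'   `history` (an [event_history()]), `expected` (data.frame mapping
#'   replayed gene ids to family, classes and target chromosome),
#'   `conflicts`, `unordered_translocations`.
#' @export
reconstruct_scenario <- function(calls, paralogons, species_tree, table,
                                 classes, focal_species,
                                 threer_label = "3R") {
  st <- species_tree
  if (!threer_label %in% st$wgd$label)
    stop("species tree lacks a WGD marker labeled '", threer_label, "'")
  post3R <- wgd_descendants(st, threer_label)
  if (!focal_species %in% post3R)
    stop("focal species '", focal_species,
         "' did not pass through the ", threer_label, " event")
  wgd_branch <- st$wgd$branch[st$wgd$label == threer_label]
  ## branch for post-3R events: next step toward the focal tip
  wb_id <- st_node_id(st, wgd_branch)
  tip_id <- st_node_id(st, focal_species)
  post_branch <- if (wb_id == tip_id) wgd_branch else {
    path <- c(rev(st_ancestors(st, tip_id)), tip_id)
    st_node_name(st, path[match(wb_id, path) + 1L])
  }

  m <- merge_table_classes(table, classes)
  m <- m[m$species == focal_species & nzchar(m$twor_class), , drop = FALSE]
  if (!nrow(m)) stop("no informative genes for '", focal_species, "'")

  ## timing conflicts among fusion calls on one chromosome
  fus <- Filter(function(cl) cl$kind == "fusion" &&
                  cl$species == focal_species, calls)
  conflicts <- character()
  chrs_called <- vapply(fus, function(cl) cl$chromosomes[1L], character(1))
  for (ch in unique(chrs_called)) {
    tm <- unique(vapply(fus[chrs_called == ch], `[[`, character(1), "timing"))
    if (all(c("before_3R", "after_3R") %in% tm))
      conflicts <- c(conflicts,
                     paste0("chromosome ", ch,
                            " carries both before_3R and after_3R fusion calls"))
  }

  ## units = (family, 2R class); each unit's 3R copies sit on a set of
  ## tip chromosomes (its "signature"). Units sharing a signature are
  ## taken to descend from one pre-3R chromosome; signature groups are
  ## merged when a before_3R fusion call co-locates them.
  m$unit <- paste(m$family_id, m$twor_class, sep = "&")
  sig <- vapply(split(m$chromosome, m$unit), function(ch)
    paste(sort(unique(ch)), collapse = "|"), character(1))
  sig_levels <- sort(unique(sig))
  grp <- stats::setNames(match(sig, sig_levels), names(sig))
  before_chrs <- unique(chrs_called[vapply(fus, `[[`, character(1),
                                           "timing") == "before_3R"])
  for (ch in before_chrs) {
    here <- unique(grp[unique(m$unit[m$chromosome == ch])])
    if (length(here) >= 2L) grp[grp %in% here] <- min(here)
  }
  subgrp <- stats::setNames(match(sig, sig_levels), names(sig))
  grp <- stats::setNames(match(grp, sort(unique(grp))), names(grp))

  ## per unit: surviving 3R sides and their tip chromosomes
  units <- unique(m[, c("family_id", "twor_class", "unit")])
  genes <- list()
  for (i in seq_len(nrow(units))) {
    f <- units$family_id[i]; cl <- units$twor_class[i]
    u <- units$unit[i]
    sub <- m[m$unit == u, , drop = FALSE]
    ## align the A/B side labels across units by tip chromosome, so
    ## that co-inherited copies land on the same 3R product
    reps <- do.call(rbind, lapply(split(sub, sub$threer_copy), function(z)
      z[order(z$chromosome), ][1L, ]))
    reps <- reps[order(reps$chromosome, reps$threer_copy), , drop = FALSE]
    sides_obs <- reps$threer_copy
    anc_id <- paste0(f, ".u", match(u, sort(units$unit)))
    for (s in seq_along(sides_obs)) {
      row1 <- reps[s, , drop = FALSE]
      genes[[length(genes) + 1L]] <- data.frame(
        family_id = f, twor_class = cl, threer_copy = sides_obs[s],
        unit = u, anc_id = anc_id, side = c("A", "B")[s],
        n_sides = length(sides_obs), tip_chromosome = row1$chromosome)
    }
  }
  genes <- do.call(rbind, genes)
  genes$final_id <- ifelse(
    genes$n_sides == 1L & !nzchar(genes$threer_copy),
    wgd_copy_id(genes$anc_id, threer_label, 1L),
    ifelse(genes$side == "A",
           wgd_copy_id(genes$anc_id, threer_label, 1L),
           wgd_copy_id(genes$anc_id, threer_label, 2L)))
  genes$side[genes$n_sides == 1L & !nzchar(genes$threer_copy)] <- "A"

  ## ancestral (pre-fusion, pre-3R) genome: one chromosome per
  ## signature subgroup
  anc_ids <- unique(genes[, c("anc_id", "unit")])
  sub_chr <- stats::setNames(
    paste0("anc", grp[anc_ids$unit], ".", subgrp[anc_ids$unit]),
    anc_ids$unit)
  chrom <- lapply(split(anc_ids$anc_id, sub_chr[anc_ids$unit]), sort)
  anc_state <- list(
    chrom = chrom[sort(names(chrom))],
    fam = stats::setNames(sub("\\.u[0-9]+$", "", anc_ids$anc_id),
                          anc_ids$anc_id),
    sub = stats::setNames(rep(NA_character_, nrow(anc_ids)),
                          anc_ids$anc_id))
  ancestor <- state_to_genome(anc_state, "inferred_ancestor")

  events <- list()
  ## pre-3R fusions: chain the subgroup chromosomes of each merged group
  fused_name <- character(max(grp))
  for (g in sort(unique(grp))) {
    members <- sort(unique(unname(sub_chr[names(grp)[grp == g]])))
    cur <- members[1L]
    for (nxt in members[-1L]) {
      nm <- paste0(cur, "+", nxt)
      events[[length(events) + 1L]] <- evo_event(
        "chromosome_fusion", wgd_branch,
        list(chr_a = cur, chr_b = nxt, rev_a = FALSE, rev_b = FALSE,
             new_name = nm))
      cur <- nm
    }
    fused_name[g] <- cur
  }
  ## the 3R doubling with observed retention
  lost <- character()
  for (aid in unique(genes$anc_id)) {
    sides <- genes$side[genes$anc_id == aid]
    if (!"B" %in% sides) lost <- c(lost, wgd_copy_id(aid, threer_label, 2L))
    if (!"A" %in% sides) lost <- c(lost, wgd_copy_id(aid, threer_label, 1L))
  }
  events[[length(events) + 1L]] <- evo_event(
    "wgd", wgd_branch, list(label = threer_label, lost = lost))

  ## current chromosome of each surviving copy right after 3R
  genes$post3R_chr <- wgd_copy_id(
    fused_name[grp[genes$unit]], threer_label,
    ifelse(genes$side == "A", 1L, 2L))

  ## assign each tip chromosome a source: the post-3R chromosome
  ## contributing most of its genes
  src_of_tip <- vapply(split(genes, genes$tip_chromosome), function(s)
    names(sort(table(s$post3R_chr), decreasing = TRUE))[1L], character(1))
  ## phase 1: translocate genes whose source chromosome differs
  moved <- genes$post3R_chr != src_of_tip[genes$tip_chromosome]
  for (i in which(moved)) {
    events[[length(events) + 1L]] <- evo_event(
      "block_translocation", post_branch,
      list(genes = genes$final_id[i],
           to = src_of_tip[[genes$tip_chromosome[i]]],
           at = 10000L, rev = FALSE))
  }
  n_transloc <- sum(moved)
  ## phase 2: fission sources that serve several tip chromosomes
  cur_chr <- stats::setNames(genes$post3R_chr, genes$final_id)
  cur_chr[moved] <- src_of_tip[genes$tip_chromosome[moved]]
  for (P in unique(unname(src_of_tip))) {
    tips_here <- names(src_of_tip)[src_of_tip == P]
    if (length(tips_here) < 2L) next
    counts <- vapply(tips_here, function(t)
      sum(cur_chr == P & genes$tip_chromosome == t), integer(1))
    primary <- tips_here[which.max(counts)]
    cur <- P
    for (t in sort(setdiff(tips_here, primary))) {
      ids <- genes$final_id[cur_chr == cur & genes$tip_chromosome == t]
      n_here <- sum(cur_chr == cur)
      for (id in ids)  # gather the departing genes at the end
        events[[length(events) + 1L]] <- evo_event(
          "intra_shuffle", post_branch,
          list(chr = cur, gene = id, new_index = n_here))
      nm <- c(paste0(cur, ".keep"), paste0(cur, ".", t))
      events[[length(events) + 1L]] <- evo_event(
        "chromosome_fission", post_branch,
        list(chr = cur, after = n_here - length(ids), new_names = nm))
      cur_chr[cur_chr == cur & genes$tip_chromosome == t] <- nm[2L]
      cur_chr[cur_chr == cur] <- nm[1L]
      cur <- nm[1L]
    }
  }
  structure(list(focal_species = focal_species, ancestor = ancestor,
                 history = event_history(events),
                 expected = genes[, c("final_id", "family_id", "twor_class",
                                      "threer_copy", "side",
                                      "tip_chromosome")],
                 conflicts = conflicts,
                 unordered_translocations = n_transloc > 1L),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat("scenario for", x$focal_species, "-", length(x$history), "events,",
      nrow(x$ancestor$loci), "ancestral genes\n")
  if (length(x$conflicts)) cat("  conflicts:", length(x$conflicts), "\n")
  invisible(x)
}

## partition of a genome into chromosome -> multiset of labels
partition_signature <- function(chrom_of, label_of) {
  parts <- split(unname(label_of), unname(chrom_of))
  sig <- sort(vapply(parts, function(x) paste(sort(x), collapse = ","),
                     character(1)))
  unname(sig)
}

#' Check that a reconstructed scenario replays to an observed genome
#'
#' Replays `scenario$history` on the inferred ancestor and compares the
#' resulting gene-to-chromosome partition with the observed genome's,
#' over the informative genes, up to chromosome naming and
#' within-chromosome order (coordinates are re-spaced by design).
#'
#' @param scenario a [reconstruct_scenario()] result.
#' @param observed_genome the [genome()] of the focal species.
#' @param classes gene-copy classes from [classify_all_copies()].
#' @return logical.
#' @export
scenario_replay_matches <- function(scenario, observed_genome, classes) {
  rp <- replay_events(scenario$history, scenario$ancestor)$root
  ex <- scenario$expected
  lab <- stats::setNames(paste(ex$family_id, ex$twor_class, ex$side,
                               sep = "!"), ex$final_id)
  keep <- rp$loci$gene_id %in% names(lab)
  sig_replay <- partition_signature(
    stats::setNames(rp$loci$chromosome[keep], rp$loci$gene_id[keep]),
    lab[rp$loci$gene_id[keep]])
  ## observed genome, labeled through the same class/side mapping
  cc <- classes[classes$species == scenario$focal_species, , drop = FALSE]
  cc <- merge(cc, unique(ex[, c("family_id", "twor_class", "threer_copy",
                                "side")]),
              by = c("family_id", "twor_class", "threer_copy"))
  obs <- observed_genome$loci[observed_genome$loci$gene_id %in% cc$gene_id, ]
  i <- match(obs$gene_id, cc$gene_id)
  sig_obs <- partition_signature(
    stats::setNames(obs$chromosome, obs$gene_id),
    stats::setNames(paste(cc$family_id[i], cc$twor_class[i], cc$side[i],
                          sep = "!"), obs$gene_id))
  identical(sig_replay, sig_obs)
}
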