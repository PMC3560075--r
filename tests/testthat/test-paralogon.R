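noiseless_setup <- function(seed = 1, n_families = 8, planted = NULL,
                            tree = tree_2r(), windows = win_2r(),
                            retention = 1) {
  res <- simulate_history(tree,
                          sim_params(n_families = n_families,
                                     n_ancestral_chromosomes = 2,
                                     ohnolog_retention_prob = retention,
                                     seed = seed, planted_events = planted))
  classes <- classify_all_copies(res$gene_trees, tree, windows)
  list(res = res, classes = classes,
       table = function(sp = names(res$genomes))
         tabulate_family_locations(sprintf("F%03d", 1:n_families),
                                   res$genomes[sp]))
}

test_that("a clean 2R quadruplication yields one 4-region paralogon per ancestral chromosome", {
  s <- noiseless_setup(seed = 3)
  pars <- assemble_paralogons(s$table("fishA"), s$classes)
  expect_identical(length(pars), 2L)
  expect_identical(sort(vapply(pars, function(p) nrow(p$regions),
                               integer(1))), c(4L, 4L))
  ## the four regions of one paralogon hold the same families
  for (p in pars)
    expect_identical(length(p$supporting_families), 4L)
})

test_that("min_support above the family count empties the result", {
  s <- noiseless_setup(seed = 3)
  pars <- assemble_paralogons(s$table("fishA"), s$classes,
                              min_support = 100L)
  expect_identical(pars, list())
})

test_that("paralogon assembly ignores input row order", {
  s <- noiseless_setup(seed = 5)
  tab <- s$table("fishA")
  set.seed(9)
  tab_shuffled <- tab[sample(nrow(tab)), ]
  p1 <- assemble_paralogons(tab, s$classes)
  p2 <- assemble_paralogons(tab_shuffled, s$classes)
  expect_identical(lapply(p1, `[[`, "regions"),
                   lapply(p2, `[[`, "regions"))
  expect_identical(lapply(p1, `[[`, "supporting_families"),
                   lapply(p2, `[[`, "supporting_families"))
})

test_that("verdict filtering removes unsupported families from assembly", {
  s <- noiseless_setup(seed = 3)
  vds <- lapply(sprintf("F%03d", 1:8), function(f)
    structure(list(family_id = f,
                   verdict = if (f == "F001") "inconclusive"
                             else "supports_WGD"),
              class = "family_verdict"))
  pars <- assemble_paralogons(s$table("fishA"), s$classes, verdicts = vds)
  expect_false(any(vapply(pars, function(p)
    "F001" %in% p$supporting_families, logical(1))))
})

test_that("rearrangement-free simulations produce zero calls", {
  s <- noiseless_setup(seed = 7, tree = tree_3r(), windows = win_3r())
  pars <- assemble_paralogons(s$table(), s$classes)
  expect_identical(infer_fusion_timing(pars, tree_3r()), list())
  expect_identical(
    infer_block_rearrangements(s$table(), s$classes, "fishB", "fishA"),
    list())
})

test_that("a planted pre-3R fusion of paralogous blocks is called with its timing", {
  s <- noiseless_setup(seed = 11, n_families = 20, tree = tree_3r(),
                       windows = win_3r(),
                       planted = list(planted_paralogous_fusion()),
                       retention = 0.9)
  pars <- assemble_paralogons(s$table(), s$classes)
  calls <- infer_fusion_timing(pars, tree_3r())
  det <- Filter(function(cl) cl$kind == "fusion" &&
                  cl$timing == "before_3R", calls)
  expect_gte(length(det), 1L)
  ## outgroup genomes never receive dated fusion calls
  expect_false(any(vapply(calls, function(cl)
    cl$species %in% c("outgroup", "lobe", "gar") &&
      cl$timing != "indeterminate", logical(1))))
})

test_that("tetrapod-style genomes without 3R yield no dated fusion calls", {
  ## co-located 2R paralogs in a lineage that never passed 3R can only
  ## be timed as indeterminate
  s <- noiseless_setup(seed = 13, n_families = 10, tree = tree_3r(),
                       windows = win_3r(),
                       planted = list(list(
                         kind = "chromosome_fusion", branch = "lobe",
                         payload = list(chr_a = "chr1_2R-aA_2R-bA",
                                        chr_b = "chr1_2R-aA_2R-bB",
                                        rev_a = FALSE, rev_b = FALSE,
                                        new_name = "lobe_fused"))))
  pars <- assemble_paralogons(s$table("lobe"), s$classes)
  calls <- infer_fusion_timing(pars, tree_3r())
  expect_true(length(calls) >= 1L)
  expect_true(all(vapply(calls, `[[`, character(1), "timing") ==
                    "indeterminate"))
})

test_that("a post-3R translocation co-locating a/b copies is not a pre-3R fusion", {
  ## move the b-copies of several families onto the a-copy chromosome
  ## after 3R: only 3R duplicates become co-located
  planted <- lapply(c("F001.0", "F003.0", "F005.0"), function(g)
    list(kind = "block_translocation", branch = "fishA",
         payload = list(genes = paste0(g, "_2R-aA_2R-bA_3RB"),
                        to = "chr1_2R-aA_2R-bA_3RA", at = 0, rev = FALSE)))
  s <- noiseless_setup(seed = 17, n_families = 20, tree = tree_3r(),
                       windows = win_3r(), planted = planted)
  pars <- assemble_paralogons(s$table("fishA"), s$classes)
  calls <- infer_fusion_timing(pars, tree_3r())
  expect_false(any(vapply(calls, function(cl)
    cl$timing == "before_3R", logical(1))))
  after <- Filter(function(cl) cl$timing == "after_3R", calls)
  expect_gte(length(after), 1L)
})

test_that("small-block translocations are recovered as single block calls", {
  planted <- list(list(
    kind = "block_translocation", branch = "fishA",
    payload = list(genes = paste0("F00", c(1, 3, 5), ".0_2R-aA_2R-bA_3RA"),
                   to = "chr2_2R-aA_2R-bA_3RA", at = 0, rev = FALSE)))
  s <- noiseless_setup(seed = 19, n_families = 20, tree = tree_3r(),
                       windows = win_3r(), planted = planted)
  calls <- infer_block_rearrangements(s$table(), s$classes, "fishB", "fishA")
  expect_identical(length(calls), 1L)
  expect_identical(calls[[1]]$kind, "translocation")
  expect_setequal(calls[[1]]$families, c("F001", "F003", "F005"))
  ## identical genomes: no calls
  expect_identical(
    infer_block_rearrangements(s$table(), s$classes, "fishA", "fishA"),
    list())
})

test_that("the packaged human fixture links the SSTR1- and SSTR4-bearing chromosomes", {
  st <- sstr_species_tree()
  tr <- sstr_gene_tree()
  cc <- cbind(family_id = "SSTR",
              classify_gene_copies(tr, st, sstr_windows()))
  ## the SSTR1/-4 screen works within the SSTR1/-4/-6 branch
  keep <- grepl("SSTR[146]$", cc$gene_id)
  g <- sstr_genomes()
  tab <- tabulate_family_locations("SSTR", g["human"])
  tab <- tab[tab$gene_id %in% cc$gene_id[keep], , drop = FALSE]
  pars <- assemble_paralogons(tab, cc[keep, ], min_support = 1L)
  expect_identical(length(pars), 1L)
  expect_setequal(pars[[1]]$regions$chromosome, c("14", "20"))
})
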