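test_that("full retention through two WGDs quadruples a one-gene genome", {
  st <- tree_2r()
  res <- simulate_history(st, sim_params(n_families = 1,
                                         n_ancestral_chromosomes = 1,
                                         ohnolog_retention_prob = 1,
                                         seed = 1))
  for (sp in c("fishA", "fishB", "lobe")) {
    expect_identical(nrow(res$genomes[[sp]]$loci), 4L)
    expect_identical(nrow(res$genomes[[sp]]$chromosomes), 4L)
  }
  ## the outgroup split before the duplications
  expect_identical(nrow(res$genomes$outgroup$loci), 1L)
})

test_that("simulation is byte-identical under a repeated seed", {
  p <- sim_params(n_families = 10, ohnolog_retention_prob = 0.7,
                  fusion_rate = 0.5, fission_rate = 0.5,
                  translocation_rate = 0.5, shuffle_intensity = 1,
                  seed = 99)
  r1 <- simulate_history(tree_3r(), p)
  r2 <- simulate_history(tree_3r(), p)
  expect_identical(serialize(r1, NULL), serialize(r2, NULL))
  r3 <- simulate_history(tree_3r(), sim_params(n_families = 10,
                                               ohnolog_retention_prob = 0.7,
                                               fusion_rate = 0.5,
                                               fission_rate = 0.5,
                                               translocation_rate = 0.5,
                                               shuffle_intensity = 1,
                                               seed = 100))
  expect_false(identical(serialize(r1, NULL), serialize(r3, NULL)))
})

test_that("ohnolog retention matches the binomial expectation", {
  ## one WGD at retention 0.75 over many families: mean retained copies
  ## per family should sit within 3 standard errors of 2 * 0.75
  st <- species_tree("(out:4,(a:1,b:1)crown:3)root;",
                     wgd = data.frame(label = "R", branch = "crown",
                                      position = 0.5))
  res <- simulate_history(st, sim_params(n_families = 1000,
                                         n_ancestral_chromosomes = 4,
                                         ohnolog_retention_prob = 0.75,
                                         seed = 17))
  per_fam <- table(factor(res$genomes$a$loci$family_id,
                          levels = sprintf("F%03d", 1:1000)))
  m <- mean(per_fam)
  se <- sqrt(2 * 0.75 * 0.25 / 1000)
  expect_lt(abs(m - 1.5), 3 * se)
})

test_that("replaying the sampled truth reproduces every tip genome", {
  p <- sim_params(n_families = 12, ohnolog_retention_prob = 0.8,
                  fusion_rate = 0.7, fission_rate = 0.7,
                  translocation_rate = 1, shuffle_intensity = 2,
                  lineage_dup_rate = 0.5, seed = 23)
  res <- simulate_history(tree_3r(), p)
  tips <- replay_events(res$truth, res$ancestral_genome, tree_3r())
  for (sp in names(res$genomes))
    expect_identical(tips[[sp]]$loci, res$genomes[[sp]]$loci)
})

test_that("fusion, fission and translocation conserve what they must", {
  anc <- genome("anc",
                data.frame(name = c("c1", "c2"), length = c(5e6, 5e6),
                           placed = TRUE),
                data.frame(gene_id = paste0("g", 1:6), family_id = "F",
                           subtype_label = NA,
                           chromosome = rep(c("c1", "c2"), each = 3),
                           start = rep(c(1e6, 2e6, 3e6), 2),
                           end = rep(c(1e6, 2e6, 3e6), 2) + 1000,
                           strand = "+"))
  fuse <- event_history(list(evo_event("chromosome_fusion", "x",
                                       list(chr_a = "c1", chr_b = "c2",
                                            rev_a = FALSE, rev_b = TRUE,
                                            new_name = "f"))))
  g <- replay_events(fuse, anc)$root
  expect_identical(nrow(g$chromosomes), 1L)
  expect_identical(nrow(g$loci), 6L)
  fis <- event_history(list(evo_event("chromosome_fission", "x",
                                      list(chr = "c1", after = 1,
                                           new_names = c("p", "q")))))
  g <- replay_events(fis, anc)$root
  expect_identical(nrow(g$chromosomes), 3L)
  expect_identical(nrow(g$loci), 6L)
  tra <- event_history(list(evo_event("block_translocation", "x",
                                      list(genes = c("g1", "g2"), to = "c2",
                                           at = 1, rev = FALSE))))
  g <- replay_events(tra, anc)$root
  expect_identical(nrow(g$chromosomes), 2L)
  expect_identical(nrow(g$loci), 6L)
  expect_identical(sum(g$loci$chromosome == "c2"), 5L)
  ## empty history leaves the gene complement untouched
  g0 <- replay_events(event_history(), anc)$root
  expect_setequal(g0$loci$gene_id, anc$loci$gene_id)
})

test_that("replay errors name the offending event index", {
  anc <- genome("anc", data.frame(name = "c1", length = 5e6, placed = TRUE),
                data.frame(gene_id = c("g1", "g2"), family_id = "F",
                           subtype_label = NA, chromosome = "c1",
                           start = c(1e6, 2e6), end = c(1e6, 2e6) + 1000,
                           strand = "+"))
  h <- event_history(list(
    evo_event("gene_loss", "x", list(gene = "g1")),
    evo_event("gene_loss", "x", list(gene = "g1"))))
  expect_error(replay_events(h, anc), "replay error at event 2")
})

test_that("a WGD marker on a zero-length branch is a configuration error", {
  st <- species_tree("(out:4,(a:1,b:1)crown:0)root;",
                     wgd = data.frame(label = "R", branch = "crown",
                                      position = 0.5))
  expect_error(simulate_history(st, sim_params(n_families = 2)),
               "configuration error")
})

test_that("gene trees cross exactly the WGDs their lineage retained", {
  res <- sim_noiseless(seed = 4, n_families = 6)
  om <- res$ohnolog_map
  ## with full retention every post-3R gene carries all three WGDs
  fish <- om[om$species %in% c("fishA", "fishB"), ]
  expect_true(all(grepl("2R-a", fish$wgd_class) &
                    grepl("2R-b", fish$wgd_class) &
                    grepl("3R", fish$wgd_class)))
  lobe <- om[om$species == "lobe", ]
  expect_true(all(grepl("2R-a", lobe$wgd_class) &
                    !grepl("3R", lobe$wgd_class)))
  outg <- om[om$species == "outgroup", ]
  expect_true(all(outg$wgd_class == ""))
  ## every extant gene appears exactly once in its family's tree
  for (f in names(res$gene_trees)) {
    leaves <- parse_leaf_labels(res$gene_trees[[f]])
    genes <- om[om$family_id == f, ]
    expect_setequal(paste0(leaves$species, "|", leaves$gene_id),
                    paste0(genes$species, "|", genes$gene_id))
  }
})

test_that("tree perturbation preserves leaves and bounds RF distance", {
  res <- sim_noiseless(seed = 6, n_families = 2)
  tr <- res$gene_trees[["F001"]]
  p0 <- perturb_gene_tree(tr, 0)
  expect_identical(ape::write.tree(p0), ape::write.tree(tr))
  for (n_nni in c(1, 2, 4)) {
    pt <- perturb_gene_tree(tr, n_nni, seed = n_nni)
    expect_setequal(pt$tip.label, tr$tip.label)
    expect_lte(rf_dist_biparts(tr, pt), 2 * n_nni)
  }
  ## reproducible under a fixed seed
  expect_identical(ape::write.tree(perturb_gene_tree(tr, 3, seed = 8)),
                   ape::write.tree(perturb_gene_tree(tr, 3, seed = 8)))
  small <- ape::read.tree(text = "(A|g1,(B|g1,C|g1));")
  expect_error(perturb_gene_tree(small, 1), ">= 4 leaves")
})
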