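test_that("blocks around focal SSTR genes match the screening windows", {
  g <- sstr_genomes()
  b <- define_block(g$human, "human_SSTR1")
  expect_equal(b$start / 1e6, 23.68, tolerance = 1e-6)
  expect_equal(b$end / 1e6, 53.68, tolerance = 1e-6)
  expect_identical(b$chromosome, "14")
  ## clamped at the chromosome start
  b2 <- define_block(g$chicken, "chicken_SSTR4")
  expect_identical(b2$start, 0)
  expect_equal(b2$end / 1e6, 18.27, tolerance = 1e-6)
  ## the 15.8 Mb chicken chromosome 14 is engulfed entirely
  b3 <- define_block(g$chicken, "chicken_SSTR5")
  expect_identical(b3$start, 0)
  expect_identical(b3$end, 15.8e6)
  ## unplaced scaffolds cannot anchor a block
  expect_error(define_block(g$stickleback, "stickleback_SSTR6"),
               "unplaced")
})

test_that("block bounds stay inside the chromosome at any radius", {
  g <- toy_genome()
  for (r in c(0.5, 5, 15, 100)) {
    for (gene in c("a1", "a2", "c1g", "b2")) {
      b <- define_block(g, gene, radius_mb = r)
      chr_len <- g$chromosomes$length[g$chromosomes$name == b$chromosome]
      expect_gte(b$start, 0)
      expect_lte(b$end, chr_len)
      expect_lte(b$end - b$start, 2 * r * 1e6)
    }
  }
})

test_that("family membership in blocks matches a brute-force scan", {
  g <- toy_genome()
  ## planted: A and B inside a tight block around a2; C outside
  b <- define_block(g, "a2", radius_mb = 5)
  expect_setequal(families_in_block(b, g), c("A", "B"))
  ## a whole-chromosome block holds every family on the chromosome
  b_all <- define_block(g, "a2", radius_mb = 100)
  expect_setequal(families_in_block(b_all, g), c("A", "B", "C"))
  ## an empty interval yields the empty set
  b_empty <- structure(list(species = "toy", chromosome = "c2",
                            start = 20e6, end = 25e6, focal_gene = "b2"),
                       class = "chromosome_block")
  expect_identical(families_in_block(b_empty, g), character(0))
  ## brute force over random blocks
  set.seed(1)
  for (i in 1:10) {
    s <- runif(1, 0, 45e6)
    bb <- structure(list(species = "toy", chromosome = "c1", start = s,
                         end = s + 8e6, focal_gene = "a1"),
                    class = "chromosome_block")
    lo <- g$loci
    mid <- (lo$start + lo$end) / 2
    manual <- sort(unique(lo$family_id[lo$chromosome == "c1" &
                                         mid >= s & mid < s + 8e6]))
    expect_identical(families_in_block(bb, g), manual)
  }
})

test_that("enlarging the radius never removes a family", {
  g <- toy_genome()
  prev <- character()
  for (r in c(1, 2, 5, 12, 40)) {
    fams <- families_in_block(define_block(g, "a2", radius_mb = r), g)
    expect_true(all(prev %in% fams))
    prev <- fams
  }
})

make_anchor_genomes <- function() {
  ## families planted to exercise each selection clause:
  ## AA on both primary blocks; BB on both secondary + one primary;
  ## CC on both secondary only; DD on one block in each genome
  mk <- function(sp, placements) {
    loci <- do.call(rbind, lapply(seq_along(placements), function(i)
      data.frame(gene_id = paste0(sp, "_g", i),
                 family_id = placements[[i]][1],
                 subtype_label = NA,
                 chromosome = placements[[i]][2],
                 start = as.numeric(placements[[i]][3]),
                 end = as.numeric(placements[[i]][3]) + 1000,
                 strand = "+")))
    genome(sp, data.frame(name = c("x", "y"), length = 40e6, placed = TRUE),
           loci)
  }
  list(
    prim = mk("prim", list(c("AA", "x", 1e6), c("AA", "y", 1e6),
                           c("BB", "x", 2e6), c("DD", "x", 3e6),
                           c("FOC", "x", 5e6), c("FOC", "y", 5e6))),
    sec = mk("sec", list(c("BB", "x", 1e6), c("BB", "y", 1e6),
                         c("CC", "x", 2e6), c("CC", "y", 2e6),
                         c("DD", "y", 3e6),
                         c("FOC", "x", 5e6), c("FOC", "y", 5e6))))
}

test_that("dual-anchor family selection follows the two-genome rule", {
  gs <- make_anchor_genomes()
  spec <- anchor_spec("dual_anchor",
                      "prim", list(define_block(gs$prim, "prim_g5", 10),
                                   define_block(gs$prim, "prim_g6", 10)),
                      "sec", list(define_block(gs$sec, "sec_g6", 10),
                                  define_block(gs$sec, "sec_g7", 10)))
  got <- select_neighbor_families(spec, gs)
  ## brute-force set algebra over block membership
  fp <- lapply(spec$primary_blocks, families_in_block, genome = gs$prim)
  fs <- lapply(spec$secondary_blocks, families_in_block, genome = gs$sec)
  want <- sort(union(intersect(fp[[1]], fp[[2]]),
                     intersect(intersect(fs[[1]], fs[[2]]),
                               union(fp[[1]], fp[[2]]))))
  expect_identical(got, want)
  ## AA qualifies on the primary clause, BB via the secondary clause,
  ## DD (one block per genome) and CC (secondary only) are excluded
  expect_true(all(c("AA", "BB") %in% got))
  expect_false("DD" %in% got)
  expect_false("CC" %in% got)
  ## the focal family can be excluded on request
  got2 <- select_neighbor_families(spec, gs, include_focal = FALSE)
  expect_false("FOC" %in% got2)
  ## output never leaves the union of block families
  expect_true(all(got %in% union(unlist(fp), unlist(fs))))
})

test_that("anchor specs enforce their block counts", {
  gs <- make_anchor_genomes()
  expect_error(anchor_spec("triple_anchor",
                           "prim", list(define_block(gs$prim, "prim_g5", 10)),
                           "sec", list(define_block(gs$sec, "sec_g6", 10))),
               "exactly 3 blocks")
})

test_that("family location tables are complete and ordered", {
  expect_identical(nrow(tabulate_family_locations(character(),
                                                  sstr_genomes())), 0L)
  g <- sstr_genomes()
  tab <- tabulate_family_locations("SSTR", g)
  ## every cell verified against direct genome lookup
  for (i in sample(nrow(tab), 20)) {
    gg <- g[[tab$species[i]]]
    expect_equal(locus_midpoint_mb(gg, tab$gene_id[i]), tab$pos_mb[i])
    r <- gg$loci[gg$loci$gene_id == tab$gene_id[i], ]
    expect_identical(r$chromosome, tab$chromosome[i])
  }
  expect_false(is.unsorted(tab$family_id))
})

test_that("the packaged neighbor-family lists have the reported sizes", {
  expect_identical(nrow(sstr_neighbor_families("SSTR146")), 17L)
  expect_identical(nrow(sstr_neighbor_families("SSTR235")), 30L)
  expect_identical(nrow(sstr_neighbor_families("both")), 47L)
})
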