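simple_st <- function()
  species_tree("(A,(B,(C,(D,E)cde)bcde)root_inner)root;")

test_that("LCA reconciliation labels the textbook cases", {
  st <- species_tree("(A,B)ab;")
  tr <- ape::read.tree(text = "((A|g1,B|g1),(A|g2,B|g2));")
  rt <- reconcile(tr, st)
  ntip <- 4L
  expect_identical(rt$event[ntip + 1L], "duplication")  # root
  expect_identical(rt$event[ntip + 2L], "speciation")
  expect_identical(rt$event[ntip + 3L], "speciation")
  tr2 <- ape::read.tree(text = "((A|g1,A|g2),B|g1);")
  rt2 <- reconcile(tr2, st)
  inner <- 3L + 2L
  expect_identical(rt2$event[inner], "duplication")
  expect_identical(st_node_name(st, rt2$mapped[inner]), "A")
})

test_that("reconciliation equals an independent LCA-mapping oracle", {
  st <- simple_st()
  for (seed in 1:120) {
    tr <- random_gene_tree(sample(4:10, 1), c("A", "B", "C", "D", "E"),
                           seed = seed)
    rt <- reconcile(tr, st)
    expect_identical(rt$event, oracle_events(tr, st), label = paste("seed", seed))
  }
})

test_that("unknown leaf species are reported by name", {
  st <- species_tree("(A,B)ab;")
  tr <- ape::read.tree(text = "((A|g1,Z|g1),B|g1);")
  expect_error(reconcile(tr, st), "Z\\|g1")
})

test_that("duplication nodes are dated into the correct windows", {
  st <- sstr_species_tree()
  win <- sstr_windows()
  ## a duplication whose child clades both span lobe- and ray-finned
  ## fishes maps to the vertebrate crown: 2R window
  tr <- ape::read.tree(text = paste0(
    "(fruit_fly|f1,((human|g1,zebrafish|g1),(human|g2,zebrafish|g2)));"))
  rt <- reconcile(tr, st)
  dd <- date_duplication_nodes(rt, win)
  expect_identical(nrow(dd), 1L)
  expect_identical(dd$window, "2R_window")
  expect_identical(dd$mapped, "sarcopterygian_actinopterygian_split")
  ## teleost-only duplicate clusters with gar basal: 3R window
  tr3 <- ape::read.tree(text = paste0(
    "(human|g0,(gar|g1,((zebrafish|a,medaka|a),(zebrafish|b,medaka|b))));"))
  dd3 <- date_duplication_nodes(reconcile(tr3, st), win)
  expect_identical(dd3$window, "3R_window")
  expect_identical(dd3$mapped, "teleost_crown")
  ## a within-species pair is lineage specific
  trl <- ape::read.tree(text =
    "(human|g0,((coelacanth|g1,coelacanth|g2),gar|g1));")
  ddl <- date_duplication_nodes(reconcile(trl, st), win)
  lsd <- ddl[ddl$window == "lineage_specific", ]
  expect_identical(nrow(lsd), 1L)
  expect_identical(lsd$mapped, "coelacanth")
})

test_that("overlapping windows are rejected", {
  st <- sstr_species_tree()
  bad <- rbind(duplication_window("w1", "protostome_deuterostome_split",
                                  "teleost_crown"),
               duplication_window("w2", "gar_teleost_split",
                                  "teleost_crown"))
  tr <- ape::read.tree(text = "((human|g1,zebrafish|g1),fruit_fly|f1);")
  expect_error(date_duplication_nodes(reconcile(tr, st), bad), "overlap")
})

test_that("window assignment ignores leaf order and subtree rotation", {
  st <- sstr_species_tree()
  win <- sstr_windows()
  a <- "((human|g1,zebrafish|g1),(zebrafish|g2,human|g2))"
  b <- "((zebrafish|g2,human|g2),(zebrafish|g1,human|g1))"
  for (nwk in c(a, b)) {
    tr <- ape::read.tree(text = paste0("(fruit_fly|f1,", nwk, ");"))
    dd <- date_duplication_nodes(reconcile(tr, st), win)
    expect_identical(dd$window, "2R_window")
  }
})

test_that("adding an outgroup leaf leaves unrelated node labels alone", {
  st <- simple_st()
  tr <- ape::read.tree(text = "((B|g1,C|g1),(B|g2,C|g2));")
  tr_plus <- ape::read.tree(text = "(A|g0,((B|g1,C|g1),(B|g2,C|g2)));")
  rt <- reconcile(tr, st)
  rtp <- reconcile(tr_plus, st)
  ## compare events by the leaf sets of each internal node
  clade_events <- function(r) {
    ntip <- ape::Ntip(r$tree)
    sapply((ntip + 1L):(ntip + r$tree$Nnode), function(nd) {
      tips <- sort(r$tree$tip.label[phy_tips_below(r$tree, nd)])
      stats::setNames(r$event[nd], paste(tips, collapse = ","))
    })
  }
  e1 <- clade_events(rt)
  e2 <- clade_events(rtp)
  shared <- intersect(names(e1), names(e2))
  expect_true(length(shared) >= 3)
  expect_identical(e1[shared], e2[shared])
})

test_that("family verdicts apply the at-least-one-method rule", {
  st <- sstr_species_tree()
  w2 <- sstr_windows()[1, , drop = FALSE]
  supported <- ape::read.tree(text = paste0(
    "(fruit_fly|f1,((human|g1,zebrafish|g1),(human|g2,zebrafish|g2))0.9);"))
  ## duplication present but mapped to the outgroup split: outside the
  ## 2R window
  predup <- ape::read.tree(text = paste0(
    "((human|g1,zebrafish|g1),(fruit_fly|f1,(human|g2,zebrafish|g2)));"))
  weak <- ape::read.tree(text = paste0(
    "(fruit_fly|f1,((human|g1,zebrafish|g1),(human|g2,zebrafish|g2))0.3);"))
  ## ML supported, NJ agreeing
  v <- classify_family_verdict(list(supported, supported), st, w2)
  expect_identical(v$verdict, "supports_WGD")
  expect_true(v$method_agreement)
  ## supports under one method even when the other places the
  ## duplication before the outgroup divergence
  v2 <- classify_family_verdict(list(supported, predup), st, w2)
  expect_identical(v2$verdict, "supports_WGD")
  expect_false(v2$method_agreement)
  ## no window-dated duplication at all
  v3 <- classify_family_verdict(predup, st, w2)
  expect_identical(v3$verdict, "inconclusive")
  ## dated duplication below the support threshold
  v4 <- classify_family_verdict(weak, st, w2)
  expect_identical(v4$verdict, "consistent")
  ## support scale auto-detection: 0.9 on a 0-1 scale reads as 90%
  expect_identical(v$best_support, 90)
  ## differing leaf sets across methods are an input error
  other <- ape::read.tree(text = "((human|g9,zebrafish|g9),fruit_fly|f1);")
  expect_error(classify_family_verdict(list(supported, other), st, w2),
               "leaf set")
})

test_that("subtype assignment places queries by clade membership", {
  st <- sstr_species_tree()
  tr <- sstr_gene_tree()
  rt <- reconcile(tr, st)
  refs <- list(
    SSTR1 = c("human|human_SSTR1"),
    SSTR4 = c("human|human_SSTR4"),
    SSTR6 = c("coelacanth|coelacanth_SSTR6"),
    SSTR2 = c("human|human_SSTR2"),
    SSTR3 = c("human|human_SSTR3"),
    SSTR5 = c("human|human_SSTR5"))
  ## a teleost gene mis-annotated as SSTR1a falls in the SSTR6 clade
  r <- assign_subtype_and_ab(rt, refs, "zebrafish|zebrafish_SSTR6")
  expect_identical(r$subtype, "SSTR6")
  ## teleost a/b labeling anchored on the designated a-reference
  r2 <- assign_subtype_and_ab(rt, refs, "zebrafish|zebrafish_SSTR5b",
                              windows = sstr_windows(),
                              ab_reference = list(
                                SSTR5 = "zebrafish|zebrafish_SSTR5a"))
  expect_identical(r2$label, "SSTR5b")
  r2a <- assign_subtype_and_ab(rt, refs, "medaka|medaka_SSTR5a",
                               windows = sstr_windows(),
                               ab_reference = list(
                                 SSTR5 = "zebrafish|zebrafish_SSTR5a"))
  expect_identical(r2a$label, "SSTR5a")
  ## two within-subtype copies both resolve to the same subtype
  for (q in c("zebrafish|zebrafish_SSTR6", "stickleback|stickleback_SSTR6")) {
    expect_identical(assign_subtype_and_ab(rt, refs, q)$subtype, "SSTR6")
  }
  ## a query basal to every reference clade is flagged, not guessed
  r3 <- assign_subtype_and_ab(rt, refs, "fruit_fly|fruit_fly_Drostar1")
  expect_identical(r3$status, "unassignable")
  refs_sub <- list(SSTR5a = "zebrafish|zebrafish_SSTR5a",
                   SSTR5b = "zebrafish|zebrafish_SSTR5b")
  r4 <- assign_subtype_and_ab(rt, refs_sub, "gar|gar_SSTR5")
  expect_identical(r4$status, "unassignable")
})
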