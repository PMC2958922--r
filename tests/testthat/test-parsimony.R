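test_that("Fitch length matches hand-executed passes", {
  cm <- char_matrix(c("a", "b", "c", "d"),
                    cbind(c(1L, 1L, 4L, 4L),    # A,A,G,G
                          c(1L, 1L, 1L, 1L)))   # constant
  t_right <- ape::read.tree(text = "((a,b),(c,d));")
  t_wrong <- ape::read.tree(text = "((a,c),(b,d));")
  expect_equal(fitch_length(t_right, cm), 1)
  expect_equal(fitch_length(t_wrong, cm), 2)
  expect_equal(fitch_length(t_right, cm, per_character = TRUE), c(1L, 0L))
})

test_that("missing data and ambiguity reduce to state-set scoring", {
  cm <- char_matrix(c("a", "b", "c", "d"),
                    cbind(c(15L, 1L, 1L, 1L),   # N,A,A,A: free tip, no cost
                          c(15L, 1L, 4L, 4L),   # N,A,G,G: A/G conflict remains
                          c(5L, 1L, 4L, 4L),    # R,A,G,G: R covers G
                          c(1L, 1L, 2L, 3L)),   # indel P,P,A,missing over {0,1}
                    type = c("nuc", "nuc", "nuc", "indel"))
  tr <- ape::read.tree(text = "((a,b),(c,d));")
  expect_equal(fitch_length(tr, cm, per_character = TRUE),
               c(0L, 1L, 1L, 1L))
})

test_that("Fitch length is invariant to rooting and taxon order", {
  for (s in 1:10) {
    cm <- random_cm(7, 15, seed = 2000 + s)
    tr <- withr::with_seed(s, ape::rtree(7, tip.label = sample(cm$taxa)))
    len <- fitch_length(ape::unroot(tr), cm)
    for (og in cm$taxa[c(1, 4)])
      expect_equal(fitch_length(ape::root(tr, og, resolve.root = TRUE), cm),
                   len)
    # permuting matrix rows changes nothing
    perm <- withr::with_seed(s, sample(7))
    cmp <- char_matrix(cm$taxa[perm], cm$states[perm, ], cm$type)
    expect_equal(fitch_length(ape::unroot(tr), cmp), len)
  }
})

test_that("our Fitch agrees with phangorn on random trees and matrices", {
  for (s in 1:10) {
    cm <- random_cm(8, 30, seed = 2100 + s)
    tr <- withr::with_seed(s, ape::rtree(8, tip.label = cm$taxa))
    expect_equal(fitch_length(tr, cm),
                 as.integer(phangorn::fitch(tr, cm_to_phydat(cm))))
  }
})

test_that("heuristic search equals exhaustive search on small matrices", {
  for (s in 1:15) {
    n <- sample(5:7, 1)
    cm <- random_cm(n, 12, seed = 2200 + s)
    ex <- exhaustive_search(cm)
    he <- heuristic_search(cm, n_replicates = 3, seed = s)
    expect_equal(he$best_length, ex$best_length)
  }
})

test_that("a single informative character yields all trees with that split", {
  cm <- char_matrix(c("a", "b", "c", "d", "e"),
                    matrix(c(1L, 1L, 4L, 4L, 4L), ncol = 1))
  ex <- exhaustive_search(cm, max_trees = 1000)
  expect_equal(ex$best_length, 1)
  # 15 unrooted 5-taxon topologies; 3 contain the split ab|cde
  expect_equal(length(ex$best_trees), 3)
  for (tr in ex$best_trees)
    expect_true(ape::is.monophyletic(tr, c("a", "b")))
})

test_that("search is deterministic given its seed", {
  cm <- random_cm(8, 25, seed = 2300)
  r1 <- heuristic_search(cm, n_replicates = 3, seed = 77)
  r2 <- heuristic_search(cm, n_replicates = 3, seed = 77)
  expect_equal(r1$best_length, r2$best_length)
  expect_identical(lapply(r1$best_trees, ape::write.tree),
                   lapply(r2$best_trees, ape::write.tree))
})

test_that("searches refuse matrices with fewer than 4 taxa", {
  cm <- random_cm(3, 5, seed = 1)
  expect_error(heuristic_search(cm), ">= 4")
  expect_error(exhaustive_search(cm), ">= 4")
})

test_that("strict consensus keeps exactly the shared splits", {
  t1 <- ape::read.tree(text = "((a,b),(c,d),(e,f));")
  expect_equal(rf(strict_consensus(list(t1, t1)), t1), 0)
  t2 <- ape::read.tree(text = "((a,c),(b,d),(e,f));")
  cons <- strict_consensus(list(t1, t2))
  expect_true(ape::is.monophyletic(cons, c("e", "f")))
  expect_false(ape::is.monophyletic(cons, c("a", "b")))
  expect_error(strict_consensus(list(t1, ape::rtree(4))), "leaf sets")
})

test_that("consensus splits are contained in every input tree's splits", {
  for (s in 1:5) {
    trees <- withr::with_seed(3000 + s, {
      base <- ape::rtree(8)
      lapply(1:4, function(i) phangorn::rSPR(base, moves = 1))
    })
    cons <- strict_consensus(trees)
    taxa <- sort(trees[[1]]$tip.label)
    usplits <- function(tr)
      polyhap:::ut_splits(polyhap:::phylo_to_ut(tr, taxa))
    cons_splits <- usplits(cons)
    for (tr in trees)
      expect_true(all(cons_splits %in% usplits(tr)))
  }
})

test_that("CI and RI follow their definitions", {
  # homoplasy-free matrix -> CI = 1
  cm <- char_matrix(c("a", "b", "c", "d"),
                    cbind(c(1L, 1L, 4L, 4L), c(2L, 8L, 8L, 8L)))
  expect_equal(unname(ci_ri(cm, 2)["CI"]), 1.0)
  # single character A,A,G,G on the wrong tree: CI = 1/2, RI = 0
  cm1 <- char_matrix(c("a", "b", "c", "d"),
                     matrix(c(1L, 1L, 4L, 4L), ncol = 1))
  fit <- ci_ri(cm1, 2)
  expect_equal(unname(fit["CI"]), 0.5)
  expect_equal(unname(fit["RI"]), 0)
  # zero length -> CI defined as 1
  const <- char_matrix(c("a", "b", "c", "d"),
                       matrix(rep(1L, 4), ncol = 1))
  expect_equal(unname(ci_ri(const, 0)["CI"]), 1.0)
  expect_true(is.na(ci_ri(const, 0)["RI"]))
})

test_that("excluding uninformative characters removes their fixed cost", {
  cm <- char_matrix(c("a", "b", "c", "d"),
                    cbind(c(1L, 1L, 4L, 4L),   # informative
                          c(1L, 2L, 1L, 1L)))  # autapomorphy: adds 1 anywhere
  # on the wrong tree: total length 3 (2 + 1)
  incl <- ci_ri(cm, 3, include_uninformative = TRUE)
  excl <- ci_ri(cm, 3, include_uninformative = FALSE)
  expect_equal(unname(incl["CI"]), 2 / 3)
  expect_equal(unname(excl["CI"]), 1 / 2)
})

test_that("bootstrap gives full support on clean congruent characters", {
  # 50 congruent characters per split of ((a,b),(c,d),(e,f))
  states <- cbind(matrix(rep(c(1L, 1L, 4L, 4L, 4L, 4L), 50), ncol = 50),
                  matrix(rep(c(8L, 8L, 8L, 8L, 2L, 2L), 50), ncol = 50))
  cm <- char_matrix(letters[1:6], states)
  bs <- bootstrap_support(cm, n_replicates = 50, seed = 5)
  expect_true(all(bs$support >= 95))
  labs <- suppressWarnings(as.numeric(bs$tree$node.label))
  expect_true(all(labs[!is.na(labs)] >= 95))
  # constant matrix -> no supported splits
  const <- char_matrix(letters[1:6], matrix(1L, 6, 10))
  bs0 <- bootstrap_support(const, n_replicates = 10, seed = 5)
  expect_length(bs0$support, 0)
})

test_that("bootstrap is deterministic given its seed", {
  cm <- random_cm(6, 30, seed = 2400)
  b1 <- bootstrap_support(cm, n_replicates = 20, seed = 13)
  b2 <- bootstrap_support(cm, n_replicates = 20, seed = 13)
  expect_identical(b1$support, b2$support)
  expect_identical(b1$tree$node.label, b2$tree$node.label)
  expect_error(bootstrap_support(cm, n_replicates = 0), ">= 1")
})

test_that("outgroup rooting splits outgroup from ingroup and round-trips", {
  tr <- ape::read.tree(text = "((a,b),(c,d));")
  r <- root_with_outgroup(ape::unroot(tr), "d")
  expect_true(ape::is.rooted(r))
  expect_true(ape::is.monophyletic(r, c("a", "b", "c")))
  # multi-outgroup clade
  tr2 <- ape::read.tree(text = "((a,b),(c,(x,y)));")
  r2 <- root_with_outgroup(ape::unroot(tr2), c("x", "y"))
  expect_true(ape::is.monophyletic(r2, c("x", "y")))
  # rooting then unrooting restores the splits
  expect_equal(rf(ape::unroot(r2), ape::unroot(tr2)), 0)
  expect_error(root_with_outgroup(tr, "zz"), "not in tree")
  expect_warning(root_with_outgroup(ape::unroot(tr2), c("a", "c")),
                 "monophyletic")
})

test_that("MP recovers the generating topology on high-signal data", {
  hits <- 0
  for (s in 1:10) {
    pan <- simulate_marker_panel(n_taxa = 7, locus_length = 600,
                                 mode = "congruent", seed = 4000 + s,
                                 branch_length = 0.08, n_markers = 1)
    cm <- build_matrix(pan$alignments$marker1, list())
    res <- heuristic_search(cm, n_replicates = 2, seed = s)
    if (length(res$best_trees) == 1 &&
        rf(res$best_trees[[1]], pan$true_trees$marker1) == 0)
      hits <- hits + 1
  }
  expect_gte(hits, 9)
})
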