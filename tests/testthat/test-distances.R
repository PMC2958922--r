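test_that("identical sequences have zero distance under every model", {
  s <- "ACGTACGTAA"
  for (m in c("p", "JC69", "TN93"))
    expect_equal(pairwise_distance(s, s, m), 0)
})

test_that("p and JC69 match their closed forms on a hand example", {
  expect_equal(pairwise_distance("AAAA", "AAAT", "p"), 0.25)
  expect_equal(pairwise_distance("AAAA", "AAAT", "JC69"),
               -0.75 * log(1 - 1 / 3), tolerance = 1e-12)
})

test_that("sites with gap/?/ambiguity are excluded pairwise", {
  # comparable sites: positions 1-4 only; one mismatch
  expect_equal(pairwise_distance("ACGTR-A?", "ACGAAT??", "p"), 0.25)
  expect_error(pairwise_distance("ACGT", "ACG"), "length")
  expect_warning(d <- pairwise_distance("----", "AAAA", "p"),
                 "no comparable sites")
  expect_true(is.na(d))
})

test_that("TN93 >= p wherever TN93 is defined (random pairs)", {
  for (seed in 1:20) {
    recs <- random_records(2, 300, seed = 300 + seed)
    p <- pairwise_distance(recs[1], recs[2], "p")
    tn <- suppressWarnings(pairwise_distance(recs[1], recs[2], "TN93"))
    if (!is.na(tn)) expect_gte(tn, p)
  }
})

test_that("all models agree to first order as p -> 0", {
  withr::with_seed(42, {
    for (i in 1:10) {
      base <- strsplit(random_records(1, 1000, seed = 500 + i), "")[[1]]
      mut <- base
      k <- sample(1000, sample(5:15, 1))
      mut[k] <- vapply(mut[k], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
      a <- paste(base, collapse = ""); b <- paste(mut, collapse = "")
      p <- pairwise_distance(a, b, "p")
      for (m in c("JC69", "TN93")) {
        d <- pairwise_distance(a, b, m)
        expect_lte(abs(d - p), p^2 * 3)
      }
    }
  })
})

test_that("our TN93 and JC69 agree with ape::dist.dna on diverged kin", {
  # families of sequences mutated from a common parent (5-15% divergence),
  # where both implementations are well defined
  for (seed in 1:5) {
    recs <- withr::with_seed(700 + seed, {
      parent <- sample(c("A", "C", "G", "T"), 600, replace = TRUE)
      vapply(1:4, function(i) {
        x <- parent
        k <- sample(600, 45)
        x[k] <- vapply(x[k], function(b)
          sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
        paste(x, collapse = "")
      }, "")
    })
    names(recs) <- paste0("s", 1:4)
    m <- do.call(rbind, strsplit(tolower(recs), ""))
    rownames(m) <- names(recs)
    dna <- ape::as.DNAbin(m)
    for (model in c("JC69", "TN93")) {
      ours <- unclass(distance_matrix(recs, model))
      apes <- as.matrix(ape::dist.dna(dna, model = model,
                                      pairwise.deletion = TRUE))
      # base-frequency estimation conventions differ slightly for TN93
      expect_equal(ours[names(recs), names(recs)],
                   apes[names(recs), names(recs)],
                   tolerance = 2e-3, ignore_attr = TRUE)
    }
  }
})

test_that("distance matrices are symmetric, zero-diagonal, permutation-consistent", {
  recs <- random_records(6, 200, seed = 900)
  m <- distance_matrix(recs, "TN93-composite")
  expect_equal(unname(diag(m)), rep(0, 6))
  expect_equal(unclass(m), t(unclass(m)), ignore_attr = TRUE)
  perm <- c(3, 1, 6, 2, 5, 4)
  m2 <- distance_matrix(recs[perm], "TN93-composite")
  expect_equal(unclass(m2), unclass(m)[perm, perm], ignore_attr = TRUE)
})

test_that("composite distances separate simulated haplotype groups at 0.01", {
  sim <- simulate_accession(simulation_config(seed = 21,
                                              subgenome_divergence = 0.05,
                                              clone_error_rate = 0.0005))
  d <- distance_matrix(sim$clone_set$clones, "TN93-composite")
  sg <- sim$truth$clone_assignments[rownames(d)]
  same <- outer(sg, sg, "==")
  expect_true(all(d[same & upper.tri(d)] < 0.01))
  expect_true(all(d[!same & upper.tri(d)] > 0.01))
})

test_that("composite and per-pair TN93 agree on low-divergence pairs", {
  sim <- simulate_accession(simulation_config(seed = 31))
  clones <- sim$clone_set$clones[c(1, 2, 13, 14, 25, 26)]
  comp <- distance_matrix(clones, "TN93-composite")
  tn <- distance_matrix(clones, "TN93")
  off <- upper.tri(comp)
  rel <- abs(comp[off] - tn[off]) / pmax(tn[off], 1e-9)
  expect_true(all(rel[tn[off] > 0] < 0.10))
})

test_that("clones one substitution apart in 1000 bp fall below 0.01", {
  base <- unname(random_records(1, 1000, seed = 11))
  mut <- sub("A", "G", base)  # first A -> G
  d <- distance_matrix(c(a = base, b = mut), "TN93-composite")
  expect_lt(d["a", "b"], 0.01)
})
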