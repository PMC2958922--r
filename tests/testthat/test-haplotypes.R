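test_that("threshold calibration rounds up from the diploid maximum", {
  # identical clones -> default floor 0.01 (the published working threshold)
  cs <- clone_set("dip", "L", c(c1 = "ACGTACGTAC", c2 = "ACGTACGTAC"),
                  expected_subgenomes = 1)
  expect_equal(calibrate_threshold(list(cs)), 0.01)
  expect_error(calibrate_threshold(list(clone_set("dip", "L",
                                                  c(c1 = "ACGT")))),
               "manually")
})

test_that("calibrated threshold strictly exceeds observed allelic variation", {
  sets <- lapply(1:3, function(s)
    simulate_accession(simulation_config(seed = 40 + s, n_subgenomes = 1,
                                         allelic_divergence = 0.015,
                                         subgenome_divergence = 0.05,
                                         indel_rate = 0))$clone_set)
  thr <- calibrate_threshold(sets)
  dmax <- max(vapply(sets, function(cs) {
    d <- distance_matrix(cs$clones, "TN93-composite")
    max(d[upper.tri(d)])
  }, 0))
  expect_gt(thr, dmax)
  expect_gte(thr, 0.02)
  expect_equal(thr %% 0.01, 0, tolerance = 1e-9)
})

test_that("clones at exactly the threshold distance are kept apart", {
  # 2 mismatches in 100 bp -> p = 0.02 exactly
  a <- paste(rep("A", 100), collapse = "")
  b <- paste(c(rep("A", 98), "C", "C"), collapse = "")
  cs <- clone_set("x", "L", c(c1 = a, c2 = b))
  g <- separate_haplotypes(cs, separation_params(threshold = 0.02,
                                                 model = "p"))
  expect_length(g, 2)
  # strictly-below distances merge
  g2 <- separate_haplotypes(cs, separation_params(threshold = 0.0201,
                                                  model = "p"))
  expect_length(g2, 1)
})

test_that("a single clone yields one group containing it", {
  g <- separate_haplotypes(clone_set("x", "L", c(only = "ACGT")))
  expect_length(g, 1)
  expect_identical(g[[1]]$member_ids, "only")
  expect_identical(g[[1]]$consensus, "ACGT")
})

test_that("groups partition the clones and respect intra-distance bounds", {
  for (s in c(3, 17)) {
    sim <- simulate_accession(simulation_config(seed = s))
    params <- separation_params()
    g <- separate_haplotypes(sim$clone_set, params)
    ids <- unlist(lapply(g, `[[`, "member_ids"))
    expect_setequal(ids, names(sim$clone_set$clones))
    expect_equal(length(ids), length(unique(ids)))
    for (grp in g) expect_lt(grp$max_intra_distance, params$threshold)
  }
})

test_that("raising the threshold never increases the group count", {
  sim <- simulate_accession(simulation_config(seed = 9))
  counts <- vapply(c(0.005, 0.01, 0.02, 0.04, 0.08), function(th)
    length(separate_haplotypes(sim$clone_set,
                               separation_params(threshold = th))), 1L)
  expect_true(all(diff(counts) <= 0))
})

test_that("hexaploid clone sets resolve into three correct sub-genome groups", {
  ok <- 0
  for (s in 1:12) {
    sim <- simulate_accession(simulation_config(seed = 60 + s))
    g <- separate_haplotypes(sim$clone_set, separation_params())
    part <- lapply(g, function(x) sort(x$member_ids))
    truth <- lapply(split(names(sim$truth$clone_assignments),
                          sim$truth$clone_assignments), sort)
    if (length(g) == 3 && setequal(part, truth)) ok <- ok + 1
  }
  expect_gte(ok, 11)
})

test_that("consensus calling follows the majority/IUPAC/gap rules", {
  expect_identical(consensus_sequence(c("ACGT", "ACGT", "ACGT")), "ACGT")
  # column {A,A,G} -> A; column {A,G} -> R
  expect_identical(consensus_sequence(c("A", "A", "G")), "A")
  expect_identical(consensus_sequence(c("A", "G")), "R")
  # gap wins only by strict majority
  expect_identical(consensus_sequence(c("-", "-", "A")), "-")
  expect_identical(consensus_sequence(c("-", "A")), "A")
  expect_identical(consensus_sequence(c("-", "-")), "-")
  # ? and ambiguity codes do not vote
  expect_identical(consensus_sequence(c("?", "R", "C")), "C")
  expect_identical(consensus_sequence(c("?", "?")), "?")
  # three-way tie -> three-base code
  expect_identical(consensus_sequence(c("A", "C", "T")), "H")
})

test_that("consensus of noisy clones matches the true haplotype", {
  for (s in 1:5) {
    sim <- simulate_accession(simulation_config(seed = 80 + s,
                                                n_subgenomes = 1,
                                                clone_error_rate = 0.002,
                                                indel_rate = 0))
    cons <- consensus_sequence(sim$clone_set$clones)
    truth <- unname(sim$truth$true_haplotypes[1])
    ident <- mean(strsplit(cons, "")[[1]] == strsplit(truth, "")[[1]])
    expect_gte(ident, 0.999)
  }
})

test_that("haplotype report counts groups and flags shortfalls", {
  dip <- simulate_accession(simulation_config(seed = 91, n_subgenomes = 1),
                            accession_id = "dip")$clone_set
  hex <- simulate_accession(simulation_config(seed = 92),
                            accession_id = "hex")$clone_set
  rep <- haplotype_report(list(dip, hex))
  expect_equal(rep$n_haplotypes, c(1, 3))
  expect_identical(rep$status, c("ok", "ok"))
  expect_equal(nrow(haplotype_report(list())), 0)
})

test_that("two nearly identical sub-genomes merge with a shortfall flag", {
  # Mediterranean-like scenario: two of three sub-genomes nearly identical
  sim <- simulate_accession(simulation_config(seed = 95))
  cs <- sim$clone_set
  # replace sub-genome 3 clones with near-copies of sub-genome 1 clones
  sg <- sim$truth$clone_assignments
  src <- names(sg)[sg == 1][1:12]
  dst <- names(sg)[sg == 3]
  cs$clones[dst] <- cs$clones[src]
  rep <- haplotype_report(list(cs))
  expect_equal(rep$n_haplotypes, 2)
  expect_identical(rep$status, "shortfall")
})
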