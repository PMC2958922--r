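# Synthetic allopolyploid clone sets, multi-marker alignments and
# flow-cytometry readings with known ground truth.

BASES <- c("A", "C", "G", "T")
TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")
TRANSVERSIONS <- list(A = c("C", "T"), G = c("C", "T"),
                      C = c("A", "G"), T = c("A", "G"))

#' Simulation configuration for one accession-locus clone set
#'
#' The defaults describe the study conditions the pipeline is built for: an
#' allohexaploid with three diploid sub-genomes (the PPG1G1G2G2
#' constitution of Continental tall fescue), 12 clones sampled per predicted
#' diploid sub-genome, sub-genome divergence well above the 0.01 allelic
#' threshold and allelic variation plus clone error well below it.
#'
#' @param seed integer seed; the whole accession is deterministic given it.
#' @param n_subgenomes number of diploid sub-genomes (diploid 1, hexaploid 3).
#' @param subgenome_divergence expected pairwise substitutions/site between
#'   sub-genome haplotypes.
#' @param allelic_divergence expected within-sub-genome (homologous) distance.
#' @param clones_per_subgenome clones sampled per sub-genome (default 12).
#' @param clone_error_rate per-base miscall probability per clone.
#' @param indel_rate per-site indel initiation probability (sub-genome level).
#' @param indel_length_geometric_p geometric parameter of indel lengths.
#' @param locus_length locus length in bp.
#' @param ts_tv_ratio transition/transversion ratio of the substitution
#'   process (Kimura-style two-parameter process).
#' @param genome_size_cv coefficient of variation of flow-cytometry readings.
#' @return A `sim_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              n_subgenomes = 3L,
                              subgenome_divergence = 0.05,
                              allelic_divergence = 0.002,
                              clones_per_subgenome = 12L,
                              clone_error_rate = 0.001,
                              indel_rate = 0.001,
                              indel_length_geometric_p = 0.5,
                              locus_length = 1000L,
                              ts_tv_ratio = 2,
                              genome_size_cv = 0.03) {
  cfg <- list(seed = as.integer(seed),
              n_subgenomes = as.integer(n_subgenomes),
              subgenome_divergence = subgenome_divergence,
              allelic_divergence = allelic_divergence,
              clones_per_subgenome = as.integer(clones_per_subgenome),
              clone_error_rate = clone_error_rate,
              indel_rate = indel_rate,
              indel_length_geometric_p = indel_length_geometric_p,
              locus_length = as.integer(locus_length),
              ts_tv_ratio = ts_tv_ratio,
              genome_size_cv = genome_size_cv)
  if (cfg$n_subgenomes < 1) stop("n_subgenomes must be >= 1")
  if (cfg$locus_length <= 0) stop("locus_length must be > 0")
  if (cfg$n_subgenomes > 1 &&
      cfg$allelic_divergence >= cfg$subgenome_divergence)
    stop("allelic_divergence must be < subgenome_divergence")
  rates <- c(cfg$allelic_divergence, cfg$clone_error_rate, cfg$indel_rate,
             cfg$indel_length_geometric_p)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (cfg$genome_size_cv < 0) stop("genome_size_cv must be >= 0")
  structure(cfg, class = "sim_config")
}

# evolve `seq` (character vector) along a branch of expected `subs` total
# substitution events per site, transition:transversion ratio kappa
evolve_branch <- function(chars, subs, kappa) {
  if (subs <= 0) return(chars)
  n_events <- rpois(length(chars), subs)
  for (i in which(n_events > 0)) {
    b <- chars[i]
    for (k in seq_len(n_events[i])) {
      b <- if (runif(1) < kappa / (kappa + 1)) TRANSITION[[b]]
           else sample(TRANSVERSIONS[[b]], 1)
    }
    chars[i] <- b
  }
  chars
}

#' Simulate one accession's clone set with known truth
#'
#' Sub-genome haplotypes evolve independently from a random common ancestor
#' (branch length `subgenome_divergence / 2` each, so expected pairwise
#' divergence equals `subgenome_divergence`).  Each sub-genome receives
#' shared indels (deletions; geometric lengths) and two allelic variants at
#' `allelic_divergence`; clones are drawn uniformly from the alleles with
#' per-base miscalls at `clone_error_rate`.  Deterministic given
#' `config$seed`.
#'
#' @param config a [simulation_config()].
#' @param accession_id,locus_id labels for the generated clone set.
#' @return A list with `clone_set` (a [clone_set()]; clones are mutually
#'   aligned, gaps mark sub-genome deletions) and `truth` (list:
#'   `true_haplotypes` gap-free per sub-genome, `true_alignment` a
#'   [nucleotide_alignment()] of the gapped haplotypes, `clone_assignments`
#'   named integer vector, `true_tree` an [ape::phylo] star relating the
#'   sub-genomes when there are >= 2).
#' @export
simulate_accession <- function(config, accession_id = "acc1",
                               locus_id = "locus1") {
  stopifnot(inherits(config, "sim_config"))
  with_local_seed(config$seed, {
    L <- config$locus_length
    k <- config$n_subgenomes
    ancestor <- sample(BASES, L, replace = TRUE)
    haps <- lapply(seq_len(k), function(i)
      evolve_branch(ancestor, config$subgenome_divergence / 2,
                    config$ts_tv_ratio))
    # sub-genome level deletions, shared by all clones of the sub-genome
    deleted <- lapply(seq_len(k), function(i) {
      del <- rep(FALSE, L)
      starts <- which(runif(L) < config$indel_rate)
      for (s in starts) {
        len <- rgeom(1, config$indel_length_geometric_p) + 1L
        del[s:min(L, s + len - 1L)] <- TRUE
      }
      del
    })
    # two allelic variants per sub-genome at the configured divergence
    alleles <- lapply(seq_len(k), function(i)
      lapply(1:2, function(a)
        evolve_branch(haps[[i]], config$allelic_divergence / 2,
                      config$ts_tv_ratio)))
    clones <- character(0)
    assign <- integer(0)
    for (i in seq_len(k)) {
      for (cl in seq_len(config$clones_per_subgenome)) {
        al <- alleles[[i]][[sample.int(2, 1)]]
        miss <- runif(L) < config$clone_error_rate
        if (any(miss)) {
          al[miss] <- vapply(al[miss], function(b)
            sample(setdiff(BASES, b), 1), "")
        }
        al[deleted[[i]]] <- "-"
        id <- sprintf("%s_sg%d_c%02d", accession_id, i, cl)
        clones[id] <- paste(al, collapse = "")
        assign[id] <- i
      }
    }
    gapped <- vapply(seq_len(k), function(i) {
      h <- haps[[i]]
      h[deleted[[i]]] <- "-"
      paste(h, collapse = "")
    }, "")
    sg_names <- paste0("subgenome", seq_len(k))
    truth <- list(
      true_haplotypes = setNames(vapply(seq_len(k), function(i)
        paste(haps[[i]][!deleted[[i]]], collapse = ""), ""), sg_names),
      true_alignment = nucleotide_alignment(sg_names, gapped),
      clone_assignments = assign,
      true_tree = if (k >= 2)
        ape::stree(k, type = "star", tip.label = sg_names) else NULL)
    list(clone_set = clone_set(accession_id, locus_id, clones,
                               expected_subgenomes = k),
         truth = truth)
  })
}

#' Simulate a congruent or incongruent multi-marker alignment panel
#'
#' Marker A evolves on a random unrooted tree; in `"congruent"` mode marker
#' B evolves on the same tree, in `"incongruent"` mode on a tree altered by
#' one subtree regraft (SPR move).  Sequence evolution along the tree is
#' delegated to [phangorn::simSeq()] (Jukes-Cantor).
#'
#' @param n_taxa number of taxa (>= 4; 5 for incongruent mode).
#' @param locus_length sites per marker.
#' @param mode `"congruent"` or `"incongruent"`.
#' @param seed integer seed.
#' @param branch_length expected substitutions/site per branch (signal
#'   strength).
#' @param n_markers number of markers (default 2).
#' @return A list with `alignments` (named list of
#'   [nucleotide_alignment()]s), `true_trees` (one per marker) and `taxa`.
#' @export
simulate_marker_panel <- function(n_taxa = 10, locus_length = 500,
                                  mode = c("congruent", "incongruent"),
                                  seed = 1L, branch_length = 0.08,
                                  n_markers = 2L) {
  mode <- match.arg(mode)
  if (n_taxa < 4) stop("need >= 4 taxa")
  if (mode == "incongruent" && n_taxa < 5)
    stop("incongruent mode needs >= 5 taxa for a detectable regraft")
  with_local_seed(seed, {
    taxa <- sprintf("t%02d", seq_len(n_taxa))
    tree_a <- ape::unroot(ape::rtree(n_taxa, tip.label = taxa))
    tree_a$edge.length <- rep(branch_length, nrow(tree_a$edge))
    trees <- vector("list", n_markers)
    trees[[1]] <- tree_a
    for (m in seq_len(n_markers)[-1]) {
      if (mode == "congruent") trees[[m]] <- tree_a
      else {
        repeat {  # one SPR regraft that actually changes the topology
          tb <- phangorn::rSPR(tree_a, moves = 1)
          tb$edge.length <- rep(branch_length, nrow(tb$edge))
          if (phangorn::RF.dist(ape::unroot(tb), tree_a) > 0) break
        }
        trees[[m]] <- tb
      }
    }
    alns <- lapply(trees, function(tr) {
      sim <- phangorn::simSeq(tr, l = locus_length, type = "DNA")
      m <- toupper(as.character(sim))
      nucleotide_alignment(rownames(m), apply(m, 1, paste, collapse = ""))
    })
    names(alns) <- paste0("marker", seq_len(n_markers))
    names(trees) <- names(alns)
    list(alignments = alns, true_trees = trees, taxa = taxa, mode = mode)
  })
}

#' Simulate flow-cytometry fluorescence readings
#'
#' Readings are normal with mean `relative_size * standard_mean` and the
#' configured coefficient of variation, emulating duplicate fluorescence
#' measurements against a diploid standard.
#'
#' @param relative_size true genome size relative to the diploid standard
#'   (> 0).
#' @param n_readings number of readings (default 2, i.e. duplicates).
#' @param cv coefficient of variation (>= 0; 0 gives exact readings).
#' @param standard_mean mean fluorescence of the diploid standard.
#' @param seed optional integer seed.
#' @return Numeric vector of positive readings.
#' @export
simulate_flow_readings <- function(relative_size, n_readings = 2,
                                   cv = 0.03, standard_mean = 100,
                                   seed = NULL) {
  if (!is.numeric(relative_size) || relative_size <= 0)
    stop("relative_size must be > 0")
  if (cv < 0) stop("cv must be >= 0")
  with_local_seed(seed, {
    mu <- relative_size * standard_mean
    if (cv == 0) return(rep(mu, n_readings))
    r <- rnorm(n_readings, mean = mu, sd = cv * mu)
    pmax(r, mu * 1e-3)  # fluorescence means are positive
  })
}
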