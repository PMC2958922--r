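# Maximum parsimony: Fitch scoring, exhaustive and heuristic (random
# addition + TBR) search, strict consensus, CI/RI, nonparametric bootstrap.

states_for_tree <- function(tree, cm) {
  if (!setequal(tree$tip.label, cm$taxa))
    stop("tree leaves do not match matrix taxa")
  cm$states[match(tree$tip.label, cm$taxa), , drop = FALSE]
}

#' Fitch parsimony length of a tree
#'
#' Sum over all characters of the minimum number of state changes on the
#' tree.  State sets (IUPAC ambiguity, missing data) are handled natively;
#' binary indel characters are scored over \{present, absent\} with missing
#' as the full set.  Multifurcations are scored exactly (Hartigan's count
#' rule).
#'
#' @param tree an [ape::phylo] whose leaf set equals the matrix taxa.
#' @param cm a [char_matrix()].
#' @param per_character return the per-character vector instead of the sum.
#' @return Integer tree length (or per-character integer vector).
#' @export
fitch_length <- function(tree, cm, per_character = FALSE) {
  st <- states_for_tree(tree, cm)
  per <- fitch_per_char_cpp(tree$edge, length(tree$tip.label), st)
  if (per_character) per else sum(per)
}

# --- search internals ------------------------------------------------------

# one random-addition stepwise tree; ties broken by first encountered in a
# shuffled edge order
addition_tree <- function(states, ntip, tip_order) {
  ut <- ut_star3(tip_order[1], tip_order[2], tip_order[3], ntip)
  for (tip in tip_order[-(1:3)]) {
    idxs <- sample.int(nrow(ut$edges))
    best <- Inf; best_ut <- NULL
    for (e in idxs) {
      cand <- ut_insert(ut, tip, e)
      s <- ut_score(cand, states)
      if (s < best) { best <- s; best_ut <- cand }
    }
    ut <- best_ut
  }
  ut
}

# TBR swapping to a local optimum, keeping all equally parsimonious trees
# (bounded by max_trees); returns list(trees, length)
tbr_swap <- function(start_trees, states, max_trees, max_rounds = Inf) {
  scores <- vapply(start_trees, ut_score, 0L, states = states)
  best_len <- min(scores)
  best <- start_trees[scores == best_len]
  keys <- vapply(best, ut_key, "")
  dup <- duplicated(keys)
  best <- best[!dup]; keys <- keys[!dup]
  if (length(best) > max_trees) best <- best[seq_len(max_trees)]
  pending <- rep(TRUE, length(best))
  rounds <- 0
  while (any(pending) && rounds < max_rounds) {
    rounds <- rounds + 1
    i <- which(pending)[1]
    pending[i] <- FALSE
    improved <- FALSE
    for (nb in ut_tbr_neighbors(best[[i]])) {
      s <- ut_score(nb, states)
      if (s < best_len) {
        best_len <- s
        best <- list(nb)
        keys <- ut_key(nb)
        pending <- TRUE
        improved <- TRUE
        break
      } else if (s == best_len && length(best) < max_trees) {
        k <- ut_key(nb)
        if (!(k %in% keys)) {
          best <- c(best, list(nb))
          keys <- c(keys, k)
          pending <- c(pending, TRUE)
        }
      }
    }
    if (improved) next
  }
  list(trees = best, keys = keys, length = best_len)
}

search_result <- function(trees_ut, best_len, cm, n_replicates, seed,
                          include_uninformative = TRUE) {
  phylos <- lapply(trees_ut, ut_to_phylo, labels = cm$taxa)
  class(phylos) <- "multiPhylo"
  cons <- if (length(phylos) == 1) phylos[[1]] else
    ape::consensus(phylos, p = 1, check.labels = TRUE)
  fit <- ci_ri(cm, best_len, include_uninformative = include_uninformative)
  structure(list(best_length = best_len,
                 best_trees = phylos,
                 strict_consensus = cons,
                 CI = fit[["CI"]], RI = fit[["RI"]],
                 n_addition_replicates = n_replicates,
                 seed = seed),
            class = "mp_search")
}

#' @export
print.mp_search <- function(x, ...) {
  cat("MP search: length ", x$best_length, ", ", length(x$best_trees),
      " tree(s), CI = ", round(x$CI, 3), ", RI = ",
      if (is.na(x$RI)) "NA" else round(x$RI, 3), "\n", sep = "")
  invisible(x)
}

#' Heuristic maximum-parsimony search
#'
#' Per replicate: a random taxon-addition order, greedy stepwise addition
#' (ties broken by the first optimum met in a seeded shuffle of insertion
#' edges), then TBR branch swapping to a local optimum keeping all equally
#' parsimonious trees.  The result pools the best trees across replicates,
#' deduplicated by topology.  Deterministic for a fixed seed.
#'
#' @param cm a [char_matrix()] with >= 4 taxa.
#' @param n_replicates number of random-addition replicates.
#' @param seed integer seed (`NULL` uses the current RNG stream).
#' @param tbr perform TBR swapping (disable for the cheapest search).
#' @param max_trees cap on equally parsimonious trees retained.
#' @param max_rounds cap on TBR swap rounds per replicate (default
#'   unbounded: swap to completion).
#' @param include_uninformative include parsimony-uninformative characters
#'   in CI/RI (the conventional default).
#' @return An `mp_search` object: `best_length`, `best_trees` (multiPhylo),
#'   `strict_consensus`, `CI`, `RI`, `n_addition_replicates`, `seed`.
#' @export
heuristic_search <- function(cm, n_replicates = 10, seed = NULL,
                             tbr = TRUE, max_trees = 100, max_rounds = Inf,
                             include_uninformative = TRUE) {
  ntaxa <- length(cm$taxa)
  if (ntaxa < 4) stop("heuristic search requires >= 4 taxa")
  states <- cm$states
  with_local_seed(seed, {
    all_best <- list(); all_keys <- character(0); best_len <- Inf
    for (r in seq_len(n_replicates)) {
      ord <- sample.int(ntaxa)
      ut <- addition_tree(states, ntaxa, ord)
      if (tbr) {
        sw <- tbr_swap(list(ut), states, max_trees, max_rounds)
        trees <- sw$trees; len <- sw$length; keys <- sw$keys
      } else {
        trees <- list(ut); len <- ut_score(ut, states)
        keys <- ut_key(ut)
      }
      if (len < best_len) {
        best_len <- len; all_best <- trees; all_keys <- keys
      } else if (len == best_len) {
        fresh <- !(keys %in% all_keys)
        take <- which(fresh)[seq_len(min(sum(fresh),
                                         max(0, max_trees - length(all_best))))]
        all_best <- c(all_best, trees[take])
        all_keys <- c(all_keys, keys[take])
      }
    }
    search_result(all_best, best_len, cm, n_replicates, seed,
                  include_uninformative)
  })
}

#' Exhaustive maximum-parsimony search
#'
#' Enumerates every unrooted binary topology (up to 9 taxa, 135135 trees)
#' and returns all trees attaining the minimum length.
#'
#' @inheritParams heuristic_search
#' @param max_trees cap on retained optimal trees.
#' @return An `mp_search` object.
#' @export
exhaustive_search <- function(cm, max_trees = 1000,
                              include_uninformative = TRUE) {
  ntaxa <- length(cm$taxa)
  if (ntaxa < 4) stop("exhaustive search requires >= 4 taxa")
  if (ntaxa > 9) stop("exhaustive search limited to 9 taxa")
  states <- cm$states
  best_len <- Inf
  best <- list()
  recurse <- function(ut, next_tip) {
    if (next_tip > ntaxa) {
      s <- ut_score(ut, states)
      if (s < best_len) {
        best_len <<- s
        best <<- list(ut)
      } else if (s == best_len && length(best) < max_trees) {
        best[[length(best) + 1]] <<- ut
      }
      return(invisible())
    }
    for (e in seq_len(nrow(ut$edges)))
      recurse(ut_insert(ut, next_tip, e), next_tip + 1)
  }
  recurse(ut_star3(1L, 2L, 3L, ntaxa), 4L)
  search_result(best, best_len, cm, NA_integer_, NULL,
                include_uninformative)
}

#' Strict consensus of trees
#'
#' Retains exactly the splits present in every input tree.
#'
#' @param trees a list or multiPhylo of trees over the same leaf set.
#' @return An [ape::phylo] (possibly multifurcating).
#' @export
strict_consensus <- function(trees) {
  trees <- unclass(trees)
  if (length(trees) == 0) stop("no trees given")
  # degree-2 internal nodes (e.g. from external tree manipulations) break
  # split counting downstream
  trees <- lapply(trees, ape::collapse.singles)
  ref <- trees[[1]]$tip.label
  ok <- vapply(trees, function(t) setequal(t$tip.label, ref), TRUE)
  if (!all(ok)) stop("trees have different leaf sets")
  if (length(trees) == 1) return(trees[[1]])
  class(trees) <- "multiPhylo"
  ape::consensus(trees, p = 1, check.labels = TRUE)
}

#' Consistency and retention indices
#'
#' `CI = min_steps / observed_length` and
#' `RI = (max_steps - observed_length) / (max_steps - min_steps)`, where per
#' character `min_steps` is (number of observed states among unambiguous
#' taxa) - 1 and `max_steps` is (number of unambiguous taxa) - (count of the
#' most frequent state).  Computed over all characters by default;
#' `include_uninformative = FALSE` removes uninformative characters (whose
#' contribution to tree length is constant) from both indices.
#'
#' @param cm a [char_matrix()].
#' @param best_length observed tree length from a completed search over the
#'   full matrix.
#' @param include_uninformative logical.
#' @return Named numeric vector `c(CI, RI)`; `RI` is `NA` when its
#'   denominator is zero, `CI` is 1 when the length is zero.
#' @export
ci_ri <- function(cm, best_length, include_uninformative = TRUE) {
  bounds <- char_step_bounds(cm)
  minb <- bounds["min", ]; maxb <- bounds["max", ]
  len <- best_length
  if (!include_uninformative) {
    uninf <- minb == maxb
    len <- len - sum(minb[uninf])  # uninformative characters add a fixed cost
    minb <- minb[!uninf]; maxb <- maxb[!uninf]
  }
  ci <- if (len == 0) 1.0 else sum(minb) / len
  denom <- sum(maxb) - sum(minb)
  ri <- if (denom > 0) (sum(maxb) - len) / denom else NA_real_
  c(CI = ci, RI = ri)
}

#' Nonparametric bootstrap support
#'
#' Characters are resampled with replacement to the original matrix width;
#' each replicate is analysed with a reduced-effort heuristic search and the
#' splits of the replicate's strict consensus are recorded.  Support is the
#' percentage of replicates containing each split, mapped onto the full-data
#' strict consensus as internal node labels.
#'
#' @param cm a [char_matrix()] with >= 4 taxa.
#' @param n_replicates bootstrap replicates (>= 1).
#' @param seed integer seed.
#' @param search_effort addition replicates per bootstrap search.
#' @param max_trees tree cap per bootstrap search.
#' @param full_search optional precomputed `mp_search` on the full matrix
#'   (saves repeating it).
#' @return A list: `tree` (full-data strict consensus with support
#'   percentages as `node.label`), `support` (named vector keyed by split).
#' @export
bootstrap_support <- function(cm, n_replicates = 100, seed = NULL,
                              search_effort = 1, max_trees = 20,
                              full_search = NULL) {
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  if (length(cm$taxa) < 4) stop("bootstrap requires >= 4 taxa")
  if (is.null(full_search))
    full_search <- heuristic_search(cm, n_replicates = max(2, search_effort),
                                    seed = derive_seed(seed, "fullsearch"),
                                    max_trees = max_trees)
  counts <- new.env(parent = emptyenv())
  with_local_seed(seed, {
    for (b in seq_len(n_replicates)) {
      idx <- sample.int(n_char(cm), replace = TRUE)
      bcm <- subset_chars(cm, idx)
      res <- heuristic_search(bcm, n_replicates = search_effort,
                              max_trees = max_trees)
      uts <- lapply(unclass(res$best_trees), phylo_to_ut, taxa = cm$taxa)
      splits <- Reduce(intersect, lapply(uts, ut_splits))
      for (s in splits)
        assign(s, (if (exists(s, counts)) get(s, counts) else 0) + 1,
               envir = counts)
    }
  })
  support <- setNames(
    vapply(ls(counts), get, 0, envir = counts) / n_replicates * 100,
    ls(counts))
  cons <- full_search$strict_consensus
  # label internal nodes of the consensus with the support of their split
  ntip <- length(cons$tip.label)
  labs <- rep("", cons$Nnode)
  tipmap <- match(cons$tip.label, cm$taxa)
  for (node in seq_len(cons$Nnode) + ntip) {
    below <- tipmap[unlist(phangorn::Descendants(cons, node, "tips"))]
    if (length(below) %in% c(1, ntip)) next
    side <- sort(below)
    if (1 %in% side) side <- sort(setdiff(tipmap, side))
    if (length(side) < 2 || length(side) > ntip - 2) next
    key <- paste(side, collapse = ",")
    if (key %in% names(support))
      labs[node - ntip] <- format(round(support[[key]]))
  }
  cons$node.label <- labs
  list(tree = cons, support = support)
}

#' Root a tree with an outgroup
#'
#' Roots on the edge separating the outgroup (or outgroup clade) from the
#' remaining taxa.  If the outgroup is not monophyletic in the unrooted
#' tree, the tree is rooted on the first outgroup leaf with a warning.
#'
#' @param tree an [ape::phylo].
#' @param outgroup character vector of leaf labels.
#' @return A rooted [ape::phylo].
#' @export
root_with_outgroup <- function(tree, outgroup) {
  missing <- setdiff(outgroup, tree$tip.label)
  if (length(missing) > 0)
    stop("outgroup leaves not in tree: ", paste(missing, collapse = ", "))
  mono <- length(outgroup) == 1 ||
    ape::is.monophyletic(tree, outgroup)
  if (!mono) {
    warning("outgroup not monophyletic; rooting on '", outgroup[1], "'")
    outgroup <- outgroup[1]
  }
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
}
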