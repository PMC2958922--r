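# Homoeologous haplotype separation: calibrate an allelic-variation distance
# threshold on diploids, cluster polyploid clones into sub-genome groups at
# that threshold, and call IUPAC consensus haplotypes per group.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

# base set -> minimal IUPAC code
iupac_code <- function(bases) {
  key <- paste(sort(unique(bases)), collapse = "")
  codes <- vapply(IUPAC_SETS, function(s) paste(sort(s), collapse = ""), "")
  names(codes)[match(key, codes)]
}

#' Bundle clones of one locus from one accession
#'
#' @param accession_id,locus_id labels.
#' @param clones named character vector of mutually aligned clone sequences
#'   (equal length; gaps allowed).
#' @param expected_subgenomes predicted number of diploid sub-genomes
#'   (`NA` if unknown); a diploid is 1, an allohexaploid 3.
#' @return An object of class `clone_set`.
#' @export
clone_set <- function(accession_id, locus_id, clones,
                      expected_subgenomes = NA_integer_) {
  if (length(clones) < 1) stop("clone set must contain at least one clone")
  if (is.null(names(clones))) names(clones) <- paste0("clone", seq_along(clones))
  if (length(unique(nchar(clones))) != 1)
    stop("clones are not mutually aligned (unequal lengths)")
  structure(list(accession_id = accession_id, locus_id = locus_id,
                 clones = toupper(clones),
                 expected_subgenomes = as.integer(expected_subgenomes)),
            class = "clone_set")
}

#' @export
print.clone_set <- function(x, ...) {
  cat("Clone set ", x$accession_id, "/", x$locus_id, ": ",
      length(x$clones), " clones x ", nchar(x$clones[1]), " bp\n", sep = "")
  invisible(x)
}

#' Separation parameters
#'
#' @param threshold pairwise-distance threshold separating allelic from
#'   homoeologous variation (default 0.01, the value calibrated on diploids).
#'   Clones at distance strictly below the threshold are grouped.
#' @param model distance model tag (see [distance_matrix()]).
#' @param linkage `"single"` (connected components of the sub-threshold
#'   graph) or `"complete"`.
#' @param min_group_size groups smaller than this are dropped from the
#'   result (default 1: singletons kept, a real sub-genome may be sampled
#'   once).
#' @export
separation_params <- function(threshold = 0.01, model = "TN93-composite",
                              linkage = c("single", "complete"),
                              min_group_size = 1L) {
  if (!is.numeric(threshold) || threshold <= 0)
    stop("threshold must be > 0")
  structure(list(threshold = threshold,
                 model = match.arg(model, DIST_MODELS),
                 linkage = match.arg(linkage),
                 min_group_size = as.integer(min_group_size)),
            class = "separation_params")
}

#' Calibrate the allelic-variation threshold on diploid clone sets
#'
#' Diploids carry no homoeologous variation, so their maximum intra-accession
#' pairwise distance bounds what allelic variation plus clone error can
#' produce.  The returned threshold is strictly greater than that maximum,
#' rounded up to `granularity`, and never below `floor`.
#'
#' @param diploid_clone_sets list of [clone_set()]s from diploid accessions.
#' @param model distance model tag.
#' @param granularity rounding step for the returned threshold.
#' @param floor minimum returned threshold (default 0.01, the published
#'   working value).
#' @return A distance threshold.
#' @export
calibrate_threshold <- function(diploid_clone_sets, model = "TN93-composite",
                                granularity = 0.01, floor = 0.01) {
  if (inherits(diploid_clone_sets, "clone_set"))
    diploid_clone_sets <- list(diploid_clone_sets)
  dmax <- -Inf
  for (cs in diploid_clone_sets) {
    if (length(cs$clones) < 2) next
    m <- distance_matrix(cs$clones, model)
    vals <- m[upper.tri(m)]
    if (any(!is.na(vals))) dmax <- max(dmax, vals, na.rm = TRUE)
  }
  if (!is.finite(dmax))
    stop("no diploid clone pair available to calibrate on; ",
         "set the threshold manually via separation_params()")
  max(floor, granularity * (base::floor(dmax / granularity) + 1))
}

# strict-inequality clustering of a distance matrix
cluster_below <- function(d, threshold, linkage) {
  n <- nrow(d)
  if (linkage == "single") {
    # connected components of the graph with edges where distance < threshold
    comp <- seq_len(n)
    repeat {
      changed <- FALSE
      for (i in seq_len(n)) for (j in seq_len(n)) {
        if (i != j && !is.na(d[i, j]) && d[i, j] < threshold &&
            comp[j] != comp[i]) {
          comp[comp == comp[j]] <- comp[i]
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    match(comp, unique(comp))
  } else {
    if (n == 1) return(1L)
    hc <- stats::hclust(stats::as.dist(d), method = "complete")
    h <- hc$height[hc$height < threshold]
    if (length(h) == 0) return(seq_len(n))
    unname(stats::cutree(hc, h = max(h)))
  }
}

#' Separate clones into putative sub-genome haplotype groups
#'
#' Clones whose pairwise distance falls strictly below the threshold are
#' attributed to allelic variation or clone error and grouped; clones at or
#' above it are considered of different sub-genome origin.  One IUPAC
#' consensus haplotype is called per group.
#'
#' @param cs a [clone_set()].
#' @param params a [separation_params()].
#' @return A list of `haplotype_group`s (fields `member_ids`, `members`,
#'   `consensus`, `max_intra_distance`), ordered by decreasing size then by
#'   first member label.
#' @export
separate_haplotypes <- function(cs, params = separation_params()) {
  stopifnot(inherits(cs, "clone_set"))
  if (length(cs$clones) == 1) {
    g <- list(member_ids = names(cs$clones),
              members = cs$clones,
              consensus = unname(cs$clones[1]),
              max_intra_distance = 0)
    return(structure(list(structure(g, class = "haplotype_group")),
                     class = "haplotype_groups"))
  }
  d <- distance_matrix(cs$clones, params$model)
  und <- which(is.na(d) & upper.tri(d), arr.ind = TRUE)
  if (nrow(und) > 0)
    stop("undefined distance between clone pair(s): ",
         paste(rownames(d)[und[, 1]], colnames(d)[und[, 2]],
               sep = " / ", collapse = "; "))
  cl <- cluster_below(d, params$threshold, params$linkage)
  groups <- lapply(split(seq_along(cl), cl), function(idx) {
    ids <- names(cs$clones)[idx]
    sub <- d[idx, idx, drop = FALSE]
    structure(list(member_ids = ids,
                   members = cs$clones[idx],
                   consensus = consensus_sequence(cs$clones[idx]),
                   max_intra_distance =
                     if (length(idx) > 1) max(sub[upper.tri(sub)]) else 0),
              class = "haplotype_group")
  })
  groups <- groups[vapply(groups, function(g) length(g$member_ids), 1L) >=
                     params$min_group_size]
  ord <- order(-vapply(groups, function(g) length(g$member_ids), 1L),
               vapply(groups, function(g) min(g$member_ids), ""))
  structure(unname(groups[ord]), class = "haplotype_groups")
}

#' @export
print.haplotype_groups <- function(x, ...) {
  cat(length(x), "haplotype group(s):",
      paste(vapply(x, function(g) length(g$member_ids), 1L), collapse = ", "),
      "clones\n")
  invisible(x)
}

#' IUPAC consensus of aligned sequences
#'
#' Per column: the strict-majority base wins; bases tied for the top count
#' are reported as the minimal IUPAC code covering them; a gap wins only by
#' strict majority of the column's votes, otherwise gaps are absent from the
#' vote; columns with only gaps yield a gap, columns with no votes at all
#' (only `?`/ambiguity) yield `?`.  Ambiguity codes and `?` in the input do
#' not vote.
#'
#' @param seqs character vector of aligned sequences (>= 1).
#' @return The consensus sequence (single string, gaps allowed).
#' @export
consensus_sequence <- function(seqs) {
  if (length(seqs) < 1) stop("need at least one sequence")
  if (length(seqs) == 1) return(unname(toupper(seqs)))
  m <- do.call(rbind, strsplit(toupper(seqs), ""))
  out <- apply(m, 2, function(col) {
    votes <- col[col %in% c("A", "C", "G", "T", "-")]
    if (length(votes) == 0) return("?")
    gaps <- sum(votes == "-")
    if (gaps > length(votes) / 2) return("-")
    bases <- votes[votes != "-"]
    if (length(bases) == 0) return("-")
    tab <- table(bases)
    top <- names(tab)[tab == max(tab)]
    if (length(top) == 1) top else iupac_code(top)
  })
  paste(out, collapse = "")
}

#' Haplotype counts per accession and locus
#'
#' Mirrors the published per-sample haplotype count table: one row per clone
#' set with the recovered group count, the expected sub-genome number and a
#' status flag (`shortfall` when fewer groups than expected sub-genomes were
#' recovered, `excess` when more, `ok` otherwise, `NA` when no expectation).
#'
#' @param clone_sets list of [clone_set()]s.
#' @param params a [separation_params()].
#' @return A data.frame with columns `accession_id`, `locus_id`,
#'   `n_haplotypes`, `expected_subgenomes`, `status`.
#' @export
haplotype_report <- function(clone_sets, params = separation_params()) {
  if (length(clone_sets) == 0)
    return(data.frame(accession_id = character(), locus_id = character(),
                      n_haplotypes = integer(),
                      expected_subgenomes = integer(),
                      status = character(), stringsAsFactors = FALSE))
  rows <- lapply(clone_sets, function(cs) {
    n <- length(separate_haplotypes(cs, params))
    exp <- cs$expected_subgenomes
    status <- if (is.na(exp)) NA_character_
              else if (n < exp) "shortfall"
              else if (n > exp) "excess"
              else "ok"
    data.frame(accession_id = cs$accession_id, locus_id = cs$locus_id,
               n_haplotypes = n, expected_subgenomes = exp,
               status = status, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
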