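# Alignment descriptive statistics and assembly of the parsimony character
# matrix, including binary gap characters from simple indel coding.

# bitmask encoding of nucleotide state sets (A=1, C=2, G=4, T=8)
IUPAC_MASK <- c(A = 1L, C = 2L, G = 4L, T = 8L,
                M = 3L, R = 5L, S = 6L, W = 9L, K = 12L, Y = 10L,
                V = 7L, D = 13L, H = 11L, B = 14L, N = 15L,
                "-" = 15L, "?" = 15L)

#' Alignment site statistics
#'
#' Variable sites are columns with at least two distinct unambiguous bases
#' (gaps and ambiguity codes ignored); parsimony-informative sites
#' additionally require at least two of those bases to occur in at least two
#' taxa each.  `indel_events` counts the distinct maximal gap runs across
#' all taxa (the events simple indel coding turns into characters);
#' `min_len`/`max_len` are the ungapped row lengths.
#'
#' @param aln a [nucleotide_alignment()].
#' @return A list with `aligned_length`, `variable_sites`,
#'   `parsimony_informative_sites`, `indel_events`, `min_len`, `max_len`
#'   and `ungapped_lengths` (named per taxon).
#' @export
site_stats <- function(aln) {
  m <- aln_matrix(aln)
  is_base <- m %in% c("A", "C", "G", "T")
  dim(is_base) <- dim(m)
  variable <- 0L
  informative <- 0L
  for (j in seq_len(ncol(m))) {
    bases <- m[is_base[, j], j]
    tab <- table(bases)
    if (length(tab) >= 2) {
      variable <- variable + 1L
      if (sum(tab >= 2) >= 2) informative <- informative + 1L
    }
  }
  lens <- apply(m, 1, function(r) sum(r != "-" & r != "?"))
  list(aligned_length = aln$length,
       variable_sites = variable,
       parsimony_informative_sites = informative,
       indel_events = length(gap_runs_all(m)),
       min_len = min(lens), max_len = max(lens),
       ungapped_lengths = lens)
}

# maximal gap runs per taxon as 0-based half-open (start, end) pairs
gap_runs_taxon <- function(row) {
  r <- rle(row == "-")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  cbind(start = starts[r$values], end = ends[r$values])
}

gap_runs_all <- function(m) {
  runs <- unique(do.call(rbind, lapply(seq_len(nrow(m)), function(i)
    gap_runs_taxon(m[i, ]))))
  if (is.null(runs) || nrow(runs) == 0) return(list())
  ord <- order(runs[, 1], runs[, 2])
  lapply(ord, function(k) runs[k, ])
}

#' Simple indel coding of alignment gaps
#'
#' Every distinct maximal gap run `[start, end)` observed in at least one
#' taxon becomes one binary character.  A taxon whose own gap run equals the
#' interval is `present`; a taxon whose gap run strictly contains it (or
#' whose `?` region overlaps it) is `missing`; all other taxa are `absent`.
#' Characters are ordered by `(start, end)`.
#'
#' @param aln a [nucleotide_alignment()].
#' @return A list of indel characters, each a list with `start`, `end`
#'   (0-based half-open columns) and `states` (factor-like character vector
#'   over `present`/`absent`/`missing`, named by taxon).
#' @export
simple_indel_coding <- function(aln) {
  m <- aln_matrix(aln)
  runs <- gap_runs_all(m)
  taxon_runs <- lapply(seq_len(nrow(m)), function(i) gap_runs_taxon(m[i, ]))
  lapply(runs, function(rn) {
    s <- rn[1]; e <- rn[2]
    states <- vapply(seq_len(nrow(m)), function(i) {
      tr <- taxon_runs[[i]]
      if (nrow(tr) > 0) {
        if (any(tr[, 1] == s & tr[, 2] == e)) return("present")
        contains <- tr[, 1] <= s & tr[, 2] >= e &
          (tr[, 1] < s | tr[, 2] > e)
        if (any(contains)) return("missing")
      }
      if (any(m[i, (s + 1):e] == "?")) return("missing")
      "absent"
    }, "")
    list(start = unname(s), end = unname(e),
         states = setNames(states, rownames(m)))
  })
}

#' Build the parsimony character matrix
#'
#' Nucleotide columns become per-taxon state sets ({A,C,G,T}, IUPAC codes
#' expanded); once indel characters are appended, `-` (like `?`) becomes
#' missing in the nucleotide characters so that each indel is counted once,
#' as a binary character only.  All characters are weighted equally.
#'
#' @param aln a [nucleotide_alignment()].
#' @param indel_chars output of [simple_indel_coding()] (possibly empty).
#' @return An object of class `char_matrix`: list with `taxa`, `states`
#'   (integer bitmask matrix, taxa x characters), `type`
#'   (`"nuc"`/`"indel"` per character).
#' @export
build_matrix <- function(aln, indel_chars = list()) {
  m <- aln_matrix(aln)
  nuc <- matrix(IUPAC_MASK[m], nrow = nrow(m))
  if (length(indel_chars) > 0) {
    bad <- vapply(indel_chars, function(ic)
      !setequal(names(ic$states), aln$taxa), TRUE)
    if (any(bad)) stop("indel character taxa do not match alignment taxa")
    bin <- vapply(indel_chars, function(ic) {
      st <- ic$states[aln$taxa]
      unname(c(present = 1L, absent = 2L, missing = 3L)[st])
    }, integer(nrow(m)))
    if (nrow(m) == 1) bin <- matrix(bin, nrow = 1)
    states <- cbind(nuc, bin)
    type <- c(rep("nuc", ncol(nuc)), rep("indel", length(indel_chars)))
  } else {
    states <- nuc
    type <- rep("nuc", ncol(nuc))
  }
  char_matrix(aln$taxa, states, type)
}

#' Construct a character matrix from state-set bitmasks
#'
#' Low-level constructor used by [build_matrix()] and the test fixtures.
#' Nucleotide characters use bits A=1, C=2, G=4, T=8 (missing = 15); binary
#' characters use present=1, absent=2, missing=3.
#'
#' @param taxa taxon labels.
#' @param states integer matrix of bitmasks, one row per taxon.
#' @param type character vector (`"nuc"` or `"indel"`) per column.
#' @export
char_matrix <- function(taxa, states,
                        type = rep("nuc", ncol(states))) {
  states <- as.matrix(states)
  storage.mode(states) <- "integer"
  if (nrow(states) != length(taxa)) stop("one row per taxon required")
  if (ncol(states) != length(type)) stop("one type per character required")
  if (any(is.na(states)) || any(states < 1L) || any(states > 15L))
    stop("state masks must be integers in 1..15")
  rownames(states) <- taxa
  structure(list(taxa = as.character(taxa), states = states,
                 type = type),
            class = "char_matrix")
}

#' @export
print.char_matrix <- function(x, ...) {
  cat("Character matrix:", length(x$taxa), "taxa x", ncol(x$states),
      "characters (", sum(x$type == "nuc"), "nucleotide,",
      sum(x$type == "indel"), "indel )\n")
  invisible(x)
}

n_char <- function(cm) ncol(cm$states)

popcount <- function(x) {
  (x %% 2L) + (x %/% 2L %% 2L) + (x %/% 4L %% 2L) + (x %/% 8L %% 2L)
}

# per-character minimum steps on any tree and maximum steps on the worst
# tree (the star); only taxa with a single unambiguous state are scoreable
char_step_bounds <- function(cm) {
  apply(cm$states, 2, function(col) {
    single <- col[popcount(col) == 1L]
    if (length(single) == 0) return(c(min = 0, max = 0))
    tab <- table(single)
    c(min = length(tab) - 1L, max = length(single) - max(tab))
  })
}

# parsimony-informative characters: >= 2 singleton states each in >= 2 taxa
informative_chars <- function(cm) {
  apply(cm$states, 2, function(col) {
    single <- col[popcount(col) == 1L]
    tab <- table(single)
    sum(tab >= 2) >= 2
  })
}

# subset characters of a char_matrix
subset_chars <- function(cm, idx) {
  char_matrix(cm$taxa, cm$states[, idx, drop = FALSE], cm$type[idx])
}

#' Combine two character matrices over the same taxa
#' @param a,b `char_matrix` objects with identical taxa.
#' @export
combine_matrices <- function(a, b) {
  if (!setequal(a$taxa, b$taxa)) stop("taxa mismatch between matrices")
  char_matrix(a$taxa, cbind(a$states, b$states[a$taxa, , drop = FALSE]),
              c(a$type, b$type))
}

#' Write a combined nucleotide + indel character matrix as NEXUS
#'
#' Nucleotide characters are written as a DATA block; binary indel
#' characters, if any, follow as a second CHARACTERS block with 0/1/?
#' symbols.
#'
#' @param aln a [nucleotide_alignment()].
#' @param indel_chars output of [simple_indel_coding()].
#' @param path output path.
#' @export
write_nexus_matrix <- function(aln, indel_chars, path) {
  write_nexus_alignment(aln, path)
  if (length(indel_chars) == 0) return(invisible(path))
  sym <- c(present = "1", absent = "0", missing = "?")
  rows <- vapply(aln$taxa, function(tx)
    paste(vapply(indel_chars, function(ic) sym[[ic$states[[tx]]]], ""),
          collapse = ""), "")
  con <- file(path, open = "a")
  on.exit(close(con))
  writeLines(c("BEGIN CHARACTERS;",
               paste0("  DIMENSIONS NCHAR=", length(indel_chars), ";"),
               "  FORMAT SYMBOLS=\"01\" MISSING=?;",
               "  MATRIX",
               paste0("    ", aln$taxa, "  ", rows),
               "  ;", "END;"), con)
  invisible(path)
}
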