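# Pairwise nucleotide distances used for haplotype thresholding.
#
# Sites where either sequence carries a gap, '?', or an IUPAC ambiguity code
# are excluded pair by pair (pairwise deletion): cloned amplicons carry
# idiosyncratic errors and the thresholding is inherently pairwise.

DIST_MODELS <- c("p", "JC69", "TN93", "TN93-composite")

# integer codes for fast comparison; only 1..4 (A,C,G,T) enter distances
code_seq <- function(chars) {
  match(chars, c("A", "C", "G", "T"))
}

# substitution-class counts between two coded sequences
pair_counts <- function(ca, cb) {
  ok <- !is.na(ca) & !is.na(cb)
  a <- ca[ok]; b <- cb[ok]
  n <- length(a)
  diff <- a != b
  ag <- sum((a == 1L & b == 3L) | (a == 3L & b == 1L))  # purine transitions
  ct <- sum((a == 2L & b == 4L) | (a == 4L & b == 2L))  # pyrimidine transitions
  tv <- sum(diff) - ag - ct
  freq <- (tabulate(a, 4L) + tabulate(b, 4L))
  list(n = n, mismatch = sum(diff), P1 = ag, P2 = ct, Q = tv, freq = freq)
}

# TN93 closed form from proportions and base frequencies; NA when a log
# argument is non-positive or a frequency class is degenerate.
tn93_from_props <- function(P1, P2, Q, g) {
  gA <- g[1]; gC <- g[2]; gG <- g[3]; gT <- g[4]
  gR <- gA + gG; gY <- gC + gT
  if (gR <= 0 || gY <= 0) return(NA_real_)
  k1 <- 2 * gA * gG / gR
  k2 <- 2 * gT * gC / gY
  k3 <- 2 * (gR * gY - gA * gG * gY / gR - gT * gC * gR / gY)
  w3 <- 1 - Q / (2 * gR * gY)
  if (w3 <= 0) return(NA_real_)
  d <- -k3 * log(w3)
  if (k1 > 0) {
    w1 <- 1 - P1 / k1 - Q / (2 * gR)
    if (w1 <= 0) return(NA_real_)
    d <- d - k1 * log(w1)
  } else if (P1 > 0) return(NA_real_)
  if (k2 > 0) {
    w2 <- 1 - P2 / k2 - Q / (2 * gY)
    if (w2 <= 0) return(NA_real_)
    d <- d - k2 * log(w2)
  } else if (P2 > 0) return(NA_real_)
  d
}

#' Pairwise distance between two aligned sequences
#'
#' Supported models: `"p"` (proportion of mismatching sites), `"JC69"`
#' (`-3/4 * log(1 - 4p/3)`) and `"TN93"` (Tamura-Nei closed form from
#' transition/transversion proportions and the pair's base frequencies).
#' Sites with a gap, `?` or ambiguity code in either sequence are excluded.
#'
#' @param a,b aligned sequences (equal-length character strings).
#' @param model one of `"p"`, `"JC69"`, `"TN93"`.
#' @return A non-negative distance, or `NA` (with a warning) when no site is
#'   comparable or a model logarithm is undefined.
#' @export
pairwise_distance <- function(a, b, model = c("p", "JC69", "TN93")) {
  model <- match.arg(model)
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) != nchar(b))
    stop("sequences differ in length (", nchar(a), " vs ", nchar(b), ")")
  cc <- pair_counts(code_seq(strsplit(a, "")[[1]]),
                    code_seq(strsplit(b, "")[[1]]))
  dist_from_counts(cc, model)
}

dist_from_counts <- function(cc, model, pooled_freq = NULL) {
  if (cc$n == 0) {
    warning("no comparable sites; distance undefined")
    return(NA_real_)
  }
  p <- cc$mismatch / cc$n
  if (model == "p") return(p)
  if (model == "JC69") {
    arg <- 1 - 4 * p / 3
    if (arg <= 0) {
      warning("JC69 undefined (log argument <= 0)")
      return(NA_real_)
    }
    return(-0.75 * log(arg))
  }
  g <- if (is.null(pooled_freq)) cc$freq / sum(cc$freq) else pooled_freq
  d <- tn93_from_props(cc$P1 / cc$n, cc$P2 / cc$n, cc$Q / cc$n, g)
  if (is.na(d)) warning("TN93 undefined for this pair")
  d
}

#' Distance matrix for a set of aligned sequences
#'
#' `model = "TN93-composite"` approximates the maximum composite likelihood
#' distance of MEGA4: base frequencies are pooled over all pairs (shared
#' parameters), then each pair's distance is evaluated from its own
#' substitution-class proportions under the pooled frequencies.  If pooling
#' is degenerate (a purine or pyrimidine class absent) the matrix falls back
#' to per-pair TN93 with a message.
#'
#' @param seqs named character vector of aligned sequences (>= 2), or a
#'   [nucleotide_alignment()].
#' @param model one of `"p"`, `"JC69"`, `"TN93"`, `"TN93-composite"`.
#' @return A symmetric numeric matrix with zero diagonal and a `model`
#'   attribute; undefined entries are `NA`.
#' @export
distance_matrix <- function(seqs, model = "TN93-composite") {
  if (inherits(seqs, "nuc_alignment")) seqs <- seqs$seqs
  model <- match.arg(model, DIST_MODELS)
  if (length(seqs) < 2) stop("need at least 2 sequences")
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  if (length(unique(nchar(seqs))) != 1) stop("sequences differ in length")
  coded <- lapply(strsplit(toupper(seqs), ""), code_seq)
  if (all(vapply(coded, function(x) all(is.na(x)), TRUE)))
    stop("no unambiguous nucleotide sites in input")
  n <- length(seqs)
  counts <- vector("list", n * (n - 1) / 2)
  k <- 0
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    k <- k + 1
    counts[[k]] <- c(list(i = i, j = j), pair_counts(coded[[i]], coded[[j]]))
  }
  pooled_freq <- NULL
  eff_model <- model
  if (model == "TN93-composite") {
    tot <- Reduce(`+`, lapply(counts, `[[`, "freq"))
    pooled_freq <- tot / sum(tot)
    gR <- pooled_freq[1] + pooled_freq[3]
    gY <- pooled_freq[2] + pooled_freq[4]
    if (gR * gY == 0 || any(pooled_freq[c(1, 3)] == 0) &&
        any(pooled_freq[c(2, 4)] == 0)) {
      message("composite pooling degenerate; falling back to per-pair TN93")
      pooled_freq <- NULL
      eff_model <- "TN93"
    } else eff_model <- "TN93"
  }
  m <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (cc in counts) {
    d <- suppressWarnings(
      dist_from_counts(cc[-(1:2)], eff_model, pooled_freq = pooled_freq))
    m[cc$i, cc$j] <- m[cc$j, cc$i] <- d
  }
  attr(m, "model") <- model
  m
}
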