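# Shared fixture builders: everything is generated in code, no data files.

random_records <- function(n, len, seed) {
  withr::with_seed(seed, {
    seqs <- vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
            collapse = ""), "")
    setNames(seqs, sprintf("rec%02d", seq_len(n)))
  })
}

# random all-nucleotide character matrix (no ambiguity)
random_cm <- function(ntaxa, nchar, seed) {
  withr::with_seed(seed, {
    st <- matrix(sample(c(1L, 2L, 4L, 8L), ntaxa * nchar, replace = TRUE),
                 nrow = ntaxa)
    char_matrix(sprintf("t%02d", seq_len(ntaxa)), st)
  })
}

# character matrix from aligned sequence strings (with indel coding)
cm_from_seqs <- function(seqs) {
  aln <- nucleotide_alignment(names(seqs), seqs)
  build_matrix(aln, simple_indel_coding(aln))
}

aln_from <- function(...) {
  seqs <- c(...)
  nucleotide_alignment(names(seqs), seqs)
}

rf <- function(a, b) phangorn::RF.dist(ape::unroot(a), ape::unroot(b))

# states matrix -> phangorn phyDat (for cross-checking Fitch lengths)
cm_to_phydat <- function(cm) {
  stopifnot(all(cm$type == "nuc"))
  lut <- setNames(c("a", "c", "g", "t"), c(1L, 2L, 4L, 8L))
  m <- matrix(lut[as.character(cm$states)], nrow = nrow(cm$states))
  m[is.na(m)] <- "n"
  rownames(m) <- cm$taxa
  phangorn::phyDat(m, type = "DNA")
}
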