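# Sequence and tree I/O plus the alignment container shared by all stages.

ALLOWED_CHARS <- c("A", "C", "G", "T",
                   "R", "Y", "S", "W", "K", "M",
                   "B", "D", "H", "V", "N", "-", "?")

#' Construct a nucleotide alignment
#'
#' The container every pipeline stage shares: an ordered set of uniquely
#' labelled, equal-length rows over the nucleotide alphabet (IUPAC ambiguity
#' codes allowed, `-` is an alignment gap, `?` is missing data).  Column
#' coordinates are 0-based half-open throughout the package.
#'
#' @param taxa character vector of unique taxon labels.
#' @param seqs character vector of aligned sequences, same length as `taxa`.
#' @return An object of class `nuc_alignment`: a list with elements `taxa`,
#'   `seqs` (upper-cased) and `length` (number of columns).
#' @export
nucleotide_alignment <- function(taxa, seqs) {
  taxa <- as.character(taxa)
  seqs <- toupper(gsub("[[:space:]]", "", as.character(seqs)))
  if (length(taxa) != length(seqs))
    stop("taxa and seqs must have the same length")
  if (length(taxa) == 0) stop("alignment must contain at least one row")
  if (anyDuplicated(taxa))
    stop("duplicate taxon labels: ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1)
    stop("rows differ in length (", paste(unique(widths), collapse = ", "), ")")
  if (widths[1] == 0) stop("alignment has zero columns")
  bad <- !grepl("^[ACGTRYSWKMBDHVN?-]*$", seqs)
  if (any(bad)) {
    row <- which(bad)[1]
    chars <- strsplit(seqs[row], "")[[1]]
    pos <- which(!chars %in% ALLOWED_CHARS)[1]
    stop("illegal symbol '", chars[pos], "' in row '", taxa[row],
         "' at column ", pos - 1L, " (0-based)")
  }
  structure(list(taxa = taxa, seqs = setNames(seqs, taxa),
                 length = widths[1]),
            class = "nuc_alignment")
}

#' @export
print.nuc_alignment <- function(x, ...) {
  cat("Nucleotide alignment:", length(x$taxa), "taxa x", x$length,
      "columns\n")
  invisible(x)
}

# alignment as a character matrix (rows = taxa, columns = sites)
aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(unname(aln$seqs), ""))
  rownames(m) <- aln$taxa
  m
}

matrix_to_alignment <- function(m) {
  nucleotide_alignment(rownames(m), apply(m, 1, paste, collapse = ""))
}

#' Read sequences from a FASTA file
#'
#' @param path path to a FASTA file.
#' @return A named character vector of upper-cased sequences in file order;
#'   names are the full header lines (without `>`), whitespace-trimmed.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0)
    stop("FASTA format error in ", path, ": file is empty (line 1)")
  if (!startsWith(trimws(first), ">"))
    stop("FASTA format error in ", path, ": line 1 does not start with '>'")
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e)
                    stop("FASTA format error in ", path, ": ",
                         conditionMessage(e), call. = FALSE))
  if (length(set) == 0) stop("FASTA format error in ", path, ": no records")
  seqs <- toupper(gsub("[[:space:]]", "", as.character(set)))
  names(seqs) <- trimws(names(set))
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs)) || any(names(seqs) == ""))
    stop("all sequences must be named")
  set <- Biostrings::BStringSet(toupper(seqs))
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}

#' Read a NEXUS alignment
#'
#' Accepts a DATA or CHARACTERS block with a MATRIX, interleaved or not
#' (parsing is delegated to [ape::read.nexus.data()]).  NTAX/NCHAR from the
#' DIMENSIONS line are cross-checked against the parsed matrix and every
#' symbol is validated against the nucleotide/IUPAC alphabet.  SETS or
#' ASSUMPTIONS blocks are ignored with a warning.
#'
#' @param path path to a NEXUS file.
#' @return A [nucleotide_alignment()].
#' @export
read_nexus_alignment <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  txt <- readLines(path, warn = FALSE)
  if (any(grepl("begin\\s+(sets|assumptions)", txt, ignore.case = TRUE)))
    warning("SETS/ASSUMPTIONS block(s) ignored in ", path)
  dat <- tryCatch({
    out <- utils::capture.output(res <- ape::read.nexus.data(path))
    res
  }, error = function(e)
    stop("NEXUS format error in ", path, ": ",
         conditionMessage(e), call. = FALSE))
  aln <- nucleotide_alignment(names(dat),
                              vapply(dat, paste, "", collapse = ""))
  dims <- grep("dimensions", txt, ignore.case = TRUE, value = TRUE)[1]
  if (!is.na(dims)) {
    ntax <- regmatches(dims, regexpr("ntax\\s*=\\s*[0-9]+", dims,
                                     ignore.case = TRUE))
    nchr <- regmatches(dims, regexpr("nchar\\s*=\\s*[0-9]+", dims,
                                     ignore.case = TRUE))
    if (length(ntax) == 1) {
      ntax <- as.integer(sub(".*=\\s*", "", ntax))
      if (ntax != length(aln$taxa))
        stop("NEXUS format error in ", path, ": NTAX=", ntax,
             " but matrix has ", length(aln$taxa), " taxa")
    }
    if (length(nchr) == 1) {
      nchr <- as.integer(sub(".*=\\s*", "", nchr))
      if (nchr != aln$length)
        stop("NEXUS format error in ", path, ": NCHAR=", nchr,
             " but matrix has ", aln$length, " columns")
    }
  }
  aln
}

#' Write a NEXUS alignment
#'
#' @param aln a [nucleotide_alignment()].
#' @param path output path.
#' @param interleave logical; write the matrix interleaved.
#' @export
write_nexus_alignment <- function(aln, path, interleave = FALSE) {
  dat <- lapply(strsplit(unname(aln$seqs), ""), tolower)
  names(dat) <- aln$taxa
  ape::write.nexus.data(dat, file = path, format = "dna",
                        interleaved = interleave)
  # drop ape's date-stamped comment so identical alignments write
  # byte-identical files
  txt <- readLines(path, warn = FALSE)
  writeLines(txt[!grepl("^\\[Data written by", txt)], path)
  invisible(path)
}

#' Write a tree in newick format
#'
#' Internal-node labels (e.g. bootstrap percentages) are preserved; leaf
#' labels containing spaces are single-quoted.
#'
#' @param tree an [ape::phylo] object.
#' @param path output path.
#' @export
write_newick <- function(tree, path) {
  if (anyDuplicated(tree$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  if (any(tree$tip.label == "")) stop("empty leaf label")
  t2 <- tree
  sp <- grepl(" ", t2$tip.label)
  t2$tip.label[sp] <- paste0("'", t2$tip.label[sp], "'")
  ape::write.tree(t2, file = path)
  invisible(path)
}

#' Read a newick tree
#'
#' @param path path to a newick file.
#' @return An [ape::phylo] object; quoted labels are unquoted.
#' @export
read_newick <- function(path) {
  tr <- ape::read.tree(path)
  tr$tip.label <- gsub("^'(.*)'$", "\\1", tr$tip.label)
  tr
}
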