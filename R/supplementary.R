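# Access to the published supplementary haplotype alignments, when present.

#' Load a published marker alignment from the package's extdata
#'
#' The four deposited haplotype alignments (markers ITS, matK, Acc1, CEN;
#' NEXUS format) are not redistributed with the package.  To analyse them,
#' place the files as `<marker>.nex` under
#' `inst/extdata/supplementary/` before installation (or under the
#' installed package's `extdata/supplementary/`) and load them here.
#'
#' @param marker one of `"ITS"`, `"matK"`, `"Acc1"`, `"CEN"`.
#' @return A [nucleotide_alignment()].
#' @export
supplementary_alignment <- function(marker = c("ITS", "matK", "Acc1", "CEN")) {
  marker <- match.arg(marker)
  path <- system.file("extdata", "supplementary", paste0(marker, ".nex"),
                      package = "polyhap")
  if (path == "" || !file.exists(path))
    stop("supplementary alignment for ", marker, " is not installed; ",
         "place the published NEXUS file at ",
         "inst/extdata/supplementary/", marker,
         ".nex and reinstall the package")
  read_nexus_alignment(path)
}
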