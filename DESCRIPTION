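Package: polyhap
Title: Homoeologous Haplotype Separation and Parsimony Phylogenetics for
    Allopolyploids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Separates homoeologous sequence haplotypes from cloned amplicon
    sequences of allopolyploid plants and reconstructs their phylogeny by
    maximum parsimony.  Provides flow-cytometry based ploidy confirmation
    against a diploid standard, pairwise nucleotide distances (p, JC69, TN93
    and a pooled-parameter composite TN93) with distance-threshold clustering
    of clones into sub-genome groups, IUPAC consensus haplotype calling,
    simple indel coding of alignment gaps, Fitch parsimony with heuristic
    (random addition + TBR) and exhaustive search, consistency and retention
    indices, nonparametric bootstrap, the incongruence length difference
    (partition homogeneity) permutation test, and a synthetic-data generator
    that produces allopolyploid clone sets with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    Biostrings,
    Rcpp,
    yaml,
    stats,
    utils,
    tools,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
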