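---
title: "Separating homoeologous haplotypes and inferring polyploid phylogenies with polyhap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating homoeologous haplotypes and inferring polyploid phylogenies with polyhap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyhap)
```

## The problem

Allopolyploid plants such as hexaploid tall fescue (*Festuca arundinacea*,
genomic constitution PPG~1~G~1~G~2~G~2~) carry several diverged diploid
sub-genomes.  When a low-copy nuclear gene is PCR-amplified from such a
plant and the products are cloned, the resulting clone sequences are a
mixture of three kinds of variation:

* **homoeologous** variation between sub-genomes — the phylogenetic signal
  of interest, pointing at the diploid progenitors;
* **allelic (homologous)** variation between the two chromosomes of one
  sub-genome;
* **clone error** from polymerase miscalls and sequencing noise.

`polyhap` implements the complete analysis that turns per-accession clone
sets into sub-genome *haplotypes* and a maximum-parsimony phylogeny:
flow-cytometry ploidy confirmation, distance-threshold clustering of
clones, IUPAC consensus calling, alignment statistics, simple indel coding,
heuristic parsimony search with bootstrap and fit indices, and the
incongruence length difference (ILD) test between loci.  A synthetic-data
generator produces clone sets and marker panels with known ground truth so
that every stage is testable without any external data.

## Ploidy confirmation

Relative genome size is the ratio of mean stained-nuclei fluorescence of a
sample to that of a confirmed diploid standard (*F. pratensis* in the
motivating study), averaging readings within each separately prepared
sample first.  The measurement is compared to the previously published
relative size with a symmetric fold difference,

$$ f = \frac{\max(m, p)}{\min(m, p)} - 1 , $$

and classified: **confirmed** when $f \le 0.6$ (the 0.6-fold agreement
bound), **excluded** when $f \ge 1$ (an over two-fold disagreement — such
samples are dropped from all further analysis), **flagged** in between.
"Fold" arithmetic is not defined unambiguously in common usage; this
ratio-minus-one reading is isolated in `classify_ploidy()` and both bounds
are arguments.  The in-between zone is flagged rather than silently kept
because neither printed rule covers it.

## Distances and the allelic threshold

Pairwise distances between clones use pairwise deletion: any site holding a
gap, `?`, or IUPAC ambiguity code in either sequence is excluded for that
pair, because clone errors are idiosyncratic and the decision rule is
inherently pairwise.  Available models are the raw proportion `p`, `JC69`,
per-pair `TN93`, and the default `TN93-composite`, which pools base
frequencies across all pairs and evaluates each pair's Tamura–Nei distance
under the pooled frequencies.  This is an approximation to the maximum
composite likelihood distance of MEGA4 (which is itself TN93-based); exact
MEGA4 numerics are not reproduced, but at the 0.01 threshold scale the
difference between all of these models is far below the decision boundary
(they agree to first order as $p \to 0$, a property the test suite checks).

The threshold separating allelic from homoeologous variation defaults to
**0.01**, the published working value.  `calibrate_threshold()` re-derives
it from diploid clone sets — diploids carry no homoeologous variation, so
their maximum intra-accession distance bounds allelic variation plus clone
error; the threshold is the next 0.01 step strictly above that maximum,
never below 0.01.

`separate_haplotypes()` clusters clones with single linkage: connected
components of the graph with an edge wherever the distance is *strictly*
below the threshold ("less than 0.01" is the published rule, so two clones
at exactly the threshold stay apart).  Single linkage is the minimal
reading of pairwise thresholding; complete linkage is available for
chaining pathologies.  Groups of size one are kept — a real sub-genome may
be sampled once.  Each group receives an IUPAC consensus: per column the
strict-majority base wins, bases tied for the top count collapse to the
minimal covering IUPAC code, and a gap is called only on a strict majority
of the column's votes.  All clones of a cluster feed one consensus — the
two allelic variants within a sub-genome are not merged beforehand, since
sub-threshold variation is by construction absorbed by the consensus.

`haplotype_report()` tabulates group counts per accession and locus and
flags counts below the expected sub-genome number as `shortfall` (the
pattern shown by Mediterranean tall fescue, which yields two haplotypes for
a predicted three sub-genomes).  The package reports the shortfall; it
never adjudicates between the biological explanations.

## Character matrices

`site_stats()` reproduces the standard alignment descriptors: variable
sites are columns with at least two distinct unambiguous bases (gaps and
ambiguity codes ignored), parsimony-informative sites additionally need two
such bases in two taxa each, and indel events are the distinct maximal gap
runs across taxa.  Indel event counts depend on the counting convention of
the original software and are therefore reported but not treated as a hard
reference value.

Gaps enter the parsimony matrix through **simple indel coding**: every
distinct maximal gap run $[start, end)$ becomes one binary
presence/absence character; a taxon whose own gap run strictly contains the
interval cannot be scored and is missing.  Once coded, `-` becomes missing
data in the nucleotide characters so that no indel is counted twice.  This
gap-handling convention is the single biggest risk when comparing fit
indices with values computed by other programs, and is therefore stated
prominently here and in `?build_matrix`.

## Parsimony

Tree length is Fitch parsimony over state sets (IUPAC codes expand to
sets; missing data is the full set; binary indel characters score over
{present, absent}), computed in C++ with Hartigan's count rule so that a
multifurcating root is scored exactly.  `heuristic_search()` follows the
classical protocol: random-addition stepwise insertion (ties broken by the
first optimum met in a seeded shuffle) followed by TBR branch swapping to a
local optimum, keeping all equally parsimonious trees up to a cap, pooling
across replicates, and deduplicating by topology.  Exact PAUP* tie-breaking
is not reproducible, so the *number* of equally parsimonious trees is not a
quantity this package tries to match — lengths, consensus topologies and
fit indices are.  Zero-length branches are not collapsed when
deduplicating.  `exhaustive_search()` enumerates all unrooted topologies up
to nine taxa and anchors the test suite: the heuristic must reach the
exhaustive optimum on every small random matrix tried.

Fit indices use the standard bounds per character — minimum steps = number
of observed unambiguous states − 1, maximum steps = scoreable taxa − count
of the most frequent state:

$$ CI = \frac{\sum \text{min}}{L}, \qquad
   RI = \frac{\sum \text{max} - L}{\sum \text{max} - \sum \text{min}} . $$

Uninformative characters are included by default (their contribution to
$L$ is constant on every tree); `include_uninformative = FALSE` removes
that fixed cost from both indices, since the convention used for any given
published value is rarely stated.

Bootstrap support resamples characters with replacement to the original
width, runs a reduced-effort search per replicate, records the splits of
the replicate's strict consensus, and maps the percentage of replicates
containing each split onto the full-data strict consensus.  Trees are
rooted with the designated outgroup (*Cynosurus cristatus* in the
motivating study); a non-monophyletic outgroup triggers a warning and
rooting on its first member.

## The ILD test

`ild_test()` pools the characters of two matrices, repeatedly repartitions
them into blocks of the original sizes, and compares the observed sum of
block tree lengths with the permutation distribution:

$$ p = \frac{1 + \#\{\text{permuted sum} \le \text{observed sum}\}}
            {1 + n_{\text{permutations}}} . $$

Parsimony-uninformative characters are excluded before permutation by
default (their length contribution is partition-independent).  Searches
inside permutations use reduced effort — by default a single
random-addition pass without TBR; the test suite verifies on matrices of
the sizes used here that this reaches the exhaustive optimum.  The +1
correction keeps $p > 0$.

Two properties of the test are worth understanding before interpreting a
`p` value.  First, the statistic is a sum of integer tree lengths, so under
a noise-free congruent null every repartition yields *exactly* the observed
sum and $p = 1$: the test is maximally conservative when there is no
homoplasy for character assortment to redistribute.  Size calibration is
therefore meaningful only in a regime with appreciable homoplasy, and the
package's calibration checks run the congruent null at short loci and long
branches (120 sites, 0.2 expected substitutions per site per branch), where
the permutation distribution is non-degenerate; there the empirical
rejection rate at $\alpha = 0.05$ sits at (slightly below, as the ties
imply) the nominal level within binomial error.
Second, with strong clean signal the test has high power against even a
single deep regraft, which the power check exercises.

## The synthetic-data generator

`simulate_accession()` emulates the data structure of a cloned amplicon
study of an allopolyploid accession:

* sub-genome haplotypes evolve independently from a random common ancestor
  under a two-parameter (transition/transversion, default ratio 2)
  Poisson substitution process, branch length half the configured
  divergence so the expected pairwise divergence matches the setting;
* indels are sub-genome-level deletion events (per-site initiation,
  geometric lengths) shared by all clones of that sub-genome, mirroring
  the species/haplotype-level indels seen in real alignments;
* each sub-genome carries two allelic variants at the configured allelic
  divergence; clones sample an allele uniformly and add per-base miscalls.

Defaults are the study conditions the pipeline targets: three sub-genomes,
12 clones per predicted diploid sub-genome, sub-genome divergence 0.05
substitutions/site (well above the 0.01 threshold), allelic divergence
0.002 and clone error 0.001 (well below it), 1 kb loci.  The published
record contains no empirical within-accession allelic distance
distribution, so the allelic and error defaults are stated working values,
not biological claims.  One seeded stream drives each accession
(ancestor → haplotypes → indels → alleles → clones, in that order), so
identical configurations reproduce byte-identical output without
disturbing the caller's RNG.

`simulate_marker_panel()` generates multi-locus alignments on a shared
random tree via `phangorn::simSeq()`; incongruent mode regrafts one
subtree (an SPR move) for the second marker.  The generator does **not**
emulate chromatogram noise, PCR recombination (chimeras), recombination
within loci, or concerted evolution of rDNA arrays — passing tests
therefore demonstrate correctness of the algorithms under the stated
model, not robustness to those real-data phenomena.

`simulate_flow_readings()` draws fluorescence readings with a configured
coefficient of variation (default 3%) around the true relative size.

## Numerical choices and degenerate inputs

* Distances are `NA` (with a warning) when no site is comparable or a
  TN93/JC69 logarithm argument is non-positive; `separate_haplotypes()`
  refuses to cluster with undefined pairs and names them.
* Composite pooling falls back to per-pair TN93 with a message when a
  purine or pyrimidine frequency class is empty.
* A zero-length search (`L = 0`) defines $CI = 1$; an $RI$ with zero
  denominator is `NA`.
* Stepwise addition and TBR tie-breaks are seeded; every search, bootstrap
  and permutation is deterministic given its seed, and pipeline stage seeds
  derive deterministically from the master seed.

## Problem sizes used in the checks

The bundled verification uses desk-scale problem sizes chosen to exercise
every code path: exhaustive-vs-heuristic comparisons on 5–7 taxa (105–945
topologies, 100 random matrices), haplotype recovery on 50 seeded
hexaploid accessions (36 clones × 1 kb each), ILD size calibration on 200
seeded congruent panels with 99 permutations, and power on 20 incongruent
panels.  All of these settings are arguments, and scale up unchanged; the
published analyses used 1000 addition replicates and 1000
bootstrap/permutation replicates, which the same functions accept.

## Known limitations

* Exact numeric agreement with MEGA4's composite-likelihood distances and
  PAUP*'s tie handling is out of reach by design; thresholds and fit
  indices are robust to both, tree counts are not.
* NEXUS support is read-mostly (DATA/CHARACTERS matrices, both interleaved
  dialects); SETS/ASSUMPTIONS blocks are ignored with a warning, tree
  blocks are not parsed.
* The ILD implementation covers two partitions, matching its use here.
* The haplotype stage does not detect PCR chimeras and does not phase
  haplotypes across loci.
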