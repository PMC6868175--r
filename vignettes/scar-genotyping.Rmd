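---
title: "Genomic scar genotyping: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic scar genotyping: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

scarscape extracts per-sample "genomic scar" features from somatic
variant catalogs of metastatic castration-resistant prostate cancer
(mCRPC) — or any tumor cohort with comparable inputs — and clusters
samples into genotypes such as microsatellite instability (MSI), the
CDK12-associated tandem-duplication phenotype, BRCAness, and
chromothripsis.  This vignette explains each model, its tunable
parameters, and the design decisions taken where the procedure was
genuinely open; it shows small illustrative computations only.

```{r setup}
library(scarscape)
```

## Inputs and filtering

A sample is a triple of catalogs: small somatic variants (SNV / MNV /
InDel with read support, population allele frequencies, trinucleotide
context and tandem-repeat annotation), absolute copy-number segments,
and structural variants (SVs) with junction B-allele fraction (BAF).
Coordinates are 1-based inclusive internally (the VCF convention);
BEDPE input is converted from half-open 0-based starts on read.
Inversions are split into head-to-head and tail-to-tail orientation
classes at read time because the chromothripsis equal-type test needs
four intrachromosomal classes; they are merged back into a single
"inversion" category for clustering.

The heuristic post-filters remove a small variant when its supporting
read count is at most 3, or its gnomAD exome (ALL) allele frequency is
at least 0.001, or its gnomAD genome (ALL) frequency is at least 0.005;
SVs are kept at BAF at least 0.1.  Comparisons are at-equality removals,
exactly as the thresholds are stated.  Missing annotations never remove
a variant: absence of population evidence is not evidence of a germline
origin, and an InDel of at most 50 bp is the largest event the catalog
admits.

## Tumor mutational burden and the MSI rule

Genomic TMB divides the genome-wide SNV + MNV + InDel count by the
callable (ACTG) genome length, 2,858,674,662 bp for hg19; coding TMB
divides the coding counts by 28,711,682 bp of distinct non-overlapping
coding sequence.  Both denominators are plain constants of the
`genome_spec()` object and are overridable, which the reduced test
genome uses.

```{r}
tmb(mutation_counts(snv_g = 6621, indel_g = 1008, mnv_g = 55))
```

The MSI classifier counts genomic InDels of at most 50 bp lying in a
tandem repeat with unit length 2–4 bp repeated at least four times, or
in a homopolymer repeated at least five times; a sample with more than
11,436 qualifying InDels is MSI.  The repeat-criterion sentence in the
underlying pipeline documentation is ambiguous; it is implemented as
this two-branch rule, which mirrors the MSIseq-style rule that pipeline
cites.  When repeat annotations are absent they can be computed from a
reference by maximal perfect tandem extension of the inserted/deleted
unit to both sides of the event (`annotate_repeats()`).  The threshold
applies after heuristic filtering by default; both the threshold and
its position in the pipeline are configurable.

## Kataegis

Regional hypermutation is detected per chromosome by fitting a
piecewise-constant profile to the log10 inter-mutation distances of the
sample's SNVs.  The fit is a layered dynamic program over (point index,
segment count) minimizing the within-segment sum of squares; it is
globally optimal for the requested segment count.  The segment budget
is one segment per five consecutive SNVs, capped at 5000 per
chromosome.  A segment qualifies when its raw-scale mean inter-mutation
distance is at most 2000 bp; maximal runs of adjacent qualifying
segments are merged and the merged candidate must contain at least five
SNVs.  Merging before the count criterion matters in a degenerate but
real situation: when the background distances are (nearly) constant,
many segmentations tie at the same cost and the optimizer may split a
tight focus across zero-cost singleton segments; merging first makes
the call invariant to that tie-breaking.  A sample with more than 200
events genome-wide is treated as globally hypermutated, not locally:
its event list is reset to zero with a flag.

Two implementation notes.  First, the within-segment SSE cost on an
*unsorted* series does not satisfy the quadrangle inequality, so
fast DP shortcuts (divide-and-conquer, SMAWK) are not applicable —
a 6-point counterexample is easy to construct; the implementation is
the exact dense scan, written so the compiler vectorizes it and cloned
for newer vector instruction sets with runtime dispatch.  Second, the
segment count is fixed at the maximum allowed by the budget rather than
selected by a model-selection criterion: the calling criteria, not the
fit, define events.  Both the budget and the criteria are arguments.

## Chromothripsis

Chromothripsis-like events are called from rounded copy-number states
(ties to even; chromosome Y excluded) and BAF-filtered SVs.  The
candidate region on a chromosome is the breakpoint footprint of its
intrachromosomal SVs; full interleaving-graph clustering is
deliberately out of scope, keeping region finding simple and
documented.  Five criteria are evaluated, all reported without
short-circuiting so each can be inspected at its boundary:

* at least 25 intrachromosomal SVs in the event;
* a run of at least 7 segments oscillating between two copy-number
  states, or at least 14 between at most three;
* an event span of at least 20 Mbp (read as the SV footprint span, not
  the summed oscillating length — the alternative reading of "total
  size");
* a chi-square goodness-of-fit of the DEL / DUP / head-to-head /
  tail-to-tail counts against equal proportions with p > 0.05
  (Monte-Carlo p with 1e5 draws when expected counts drop below 5);
* a one-sample Kolmogorov–Smirnov test of breakpoint positions against
  the uniform distribution over the chromosome with p ≤ 0.05.  The
  criterion names non-randomness but not the statistic; KS against
  chromosome-wide uniform is the choice here, chromosome rather than
  region because a footprint-relative test cannot reject for a cluster
  that *is* the footprint.

## Mutational signatures

SNVs are tabulated into the 96 pyrimidine-normalized trinucleotide
classes (purine-reference SNVs are reverse-complemented).  Refitting
solves a non-negative least squares problem against a signature catalog
by the active-set (Lawson–Hanson) method — deterministic, exact at
convergence — and reports relative contributions that sum to one.
De novo extraction is Kullback–Leibler multiplicative-update NMF with
random restarts; per candidate rank the sample-to-signature assignments
across restarts build a consensus matrix from which the cophenetic
correlation and mean silhouette are computed, with the residual sum of
squares from the best restart.  Defaults are 50 restarts (raise to the
order of 1000 for production use) and candidate ranks 2–15; the
returned factorization defaults to rank 5.  The packaged signature
catalog is synthetic — five well-separated shapes labelled by the
etiologies they imitate (aging, MSI, HRD, APOBEC, smoking) plus a flat
column — so no external download is needed; any COSMIC-format TSV can
be supplied instead.  The signature-to-etiology grouping used for
summaries is an editable data file, not code.

## The feature vector and clustering

The per-sample feature vector has 12 entries: genome-wide SNV, InDel
and MNV burden per Mbp (three separate features, matching the per-class
display the analysis uses, with a combined mode available), the
length-weighted mean ploidy (Y excluded), the total SV count, and the
relative frequencies of seven SV categories — translocations,
inversions, insertions, and tandem duplications and deletions split at
100 kbp (ties at exactly 100 kbp go to "small"; the split is printed
only as strictly larger/smaller).  SV counts enter raw, not
log-transformed; the scaling step handles magnitude.

Clustering scales each feature by its root mean square without
centering, forms the Pearson dissimilarity d = 1 − r between sample
rows — the common R idiom `hclust(as.dist(1 - cor(t(x))), "ward.D")`;
the alternative reading of "Euclidean distance of the correlation
coefficient" is available behind a flag — and applies Ward linkage in
its classic unsquared (`ward.D`) form.  Leaves are reordered by an
exact optimal-leaf-ordering dynamic program minimizing adjacent-leaf
dissimilarity.  The cluster count comes from the elbow of the
within-cluster sum-of-squares curve over tree cuts k = 1..15, automated
as the point of maximum perpendicular distance to the chord between the
curve's endpoints (both axes normalized to [0, 1] so the rule is
scale-free); a weak-curvature warning fires when no clear elbow exists.
Automating the elbow is a deliberate simplification of a visual
procedure, and it has a known failure mode documented below.  Node
stability is an ordinary bootstrap probability — features resampled
with replacement, the pipeline re-run, nodes scored by identical leaf
sets; the multiscale AU approximation of pvclust is intentionally not
reproduced.  Cluster–trait enrichment uses two-sided Fisher's exact
tests with Benjamini–Hochberg correction applied jointly across all
(cluster, trait) tests.

## Enhancer versus gene copy ratio

For a locus pair (gene body, upstream enhancer — AR with its ~66.13 Mb
chromosome X enhancer, MYC with PCAT1, shipped as editable approximate
GRCh37 intervals), the copy number of each region is the maximum over
overlapping segments.  The per-sample log2 enhancer-to-gene ratio is
tested against a strict 1:1 null with *no* fitted parameters; each
ratio is studentized externally, dividing by the root mean square of
the *other* samples' ratios, and |t| > 1 flags enhancer- or
gene-enrichment.  Internal versus external studentization was not
specified for this zero-parameter model; leave-one-out scale
normalization is the choice because it keeps a single aberrant sample
from masking itself.

## The synthetic cohort generator

The generator exists so that every stage is testable without
controlled-access patient data.  Eight genotype profiles plant the
cohort structure the analysis assumes: per-class burden rates, SV count
distributions (negative binomial, dispersion 60) and category mixtures
(Dirichlet-perturbed, concentration 150), truncated-normal ploidy
(sd 0.08), kataegis focus probabilities (foci of 5–30 SNVs at
100–1500 bp spacing), chromothripsis probabilities (an oscillating
two-state block of 21–31 segments spanning up to 40 Mbp with 25+
balanced clustered SVs), signature mixtures, driver-gene and ETS-fusion
flags, and per-sample purity.  Default sizes scale the cluster
proportions 13:13:15:22:55:20:34:25 to the requested cohort size by
largest remainder.  The default genome is a miniature three-chromosome
genome (150/120/100 Mbp) with TMB denominators scaled accordingly, so
per-sample catalogs stay small; per-sample seeds derive from the master
seed by a fixed counter scheme, making whole cohorts byte-reproducible.

Choices worth flagging:

* **MSI burden is planted at count level.**  The MSI rule is an
  absolute count (> 11,436 qualifying InDels) while the genotype tables
  give per-Mbp rates; on a compact genome a rate-faithful MSI sample
  could never cross the absolute threshold.  The MSI genotype therefore
  draws its InDel *count* (mean 14,000, floored so the expected
  qualifying subset clears the threshold by 10%), accepting a per-Mbp
  burden above the full-genome value.
* **Two "no dominant category" genotypes get distinct mixtures.**  The
  source clusters E and G have near-identical printed burden, SV count
  and ploidy and no printed SV-category enrichment, yet they separate
  in the source dendrogram — so they must differ in features that were
  not printed.  The generator emulates that by giving E a
  translocation-leaning and G an inversion-leaning baseline mixture.
* **Chromothripsis samples route baseline intrachromosomal SVs away
  from the shattered chromosome**, whose junction catalog the event
  dominates; without this the footprint-based region would mix
  scattered junctions into the equal-type test.
* **Deletion-phenotype emphasis.**  The deletion-rich (BRCAness)
  genotype enriches deletions of both size classes with emphasis below
  100 kbp; the two source statements of this phenotype's size class
  disagree, and the emphasis is configurable.

What the generator does **not** emulate: purity-driven detection bias
(counts are independent of the drawn purity), germline contamination,
subclonal copy-number states, sequence-context realism of InDels, and
chromosome-level covariance of SV rates.  Tests that pass on this
cohort therefore demonstrate that the *methods* recover planted
structure, not that real mCRPC data would cluster identically.

## Numerical notes and known limitations

* The segmentation DP is exact; its cost is checked against exhaustive
  enumeration for small series in the test suite.  Fast-math
  compilation changes results only at the reassociation level
  (~1e-12 relative); ties between equal-cost segmentations break to
  the earliest breakpoint.
* Copy-number states round ties to even (R's `round()`), so 2.5 → 2
  and 3.5 → 4.
* The elbow rule reliably finds the planted count when clusters are
  comparably tight, but on the default cohort the MSI genotype is such
  an extreme burden outlier that the first split dominates the
  curve and the automated rule picks 5–6 clusters where 8 are planted
  (cutting the tree at 8 still recovers the genotypes essentially
  perfectly, adjusted Rand index ≳ 0.9).  This mirrors why the source
  analysis chose its cluster count by visual inspection of the same
  curve.  Supplying `k` explicitly bypasses the rule.
* Problem sizes used in the shipped tests: cohorts of 200 samples on
  the miniature genome for recovery checks, 10–24 samples for
  integration tests, NMF with 6 restarts at ranks 2–4 on 20 samples;
  these sizes were chosen so the whole suite exercises every stage in
  a few minutes on one core.
* `compare_cohorts()` expects aberration tables already collapsed to
  one event per gene and sample; choosing which aberration types enter
  the table (all versus coding-only) is the caller's responsibility
  and replaces a mode flag.
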