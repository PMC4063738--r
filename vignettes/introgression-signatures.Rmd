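---
title: "Detecting recent adaptive introgression from haplotype signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting recent adaptive introgression from haplotype signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(introsig)
```

## The problem

When a species acquires a haplotype from a related species by hybridization
and backcrossing, the recipient genome carries a recognizable scar: a single
divergent haplotype block around the introgressed locus. The motivating
system is the MHC *DRB* gene of Alpine ibex, a strongly bottlenecked species
in which one of the two *DRB* exon-2 alleles is identical to a domestic-goat
allele. The competing explanation — ancient trans-species polymorphism
maintained by balancing selection — predicts that the *coding* alleles may
be shared but the surrounding non-coding sequence and linked chromosomal
region should have diverged long ago. Recent introgression instead predicts:

1. near-identity between recipient carriers and a donor breed across coding
   *and* non-coding sequence at the locus;
2. no recombinant mosaics between the two divergent recipient haplotypes
   (they have not coexisted long);
3. a block of elevated expected heterozygosity in carriers around the locus;
4. strong linkage disequilibrium spanning the block, with slow LD decay in
   populations where the introgressed allele is common;
5. long, homogeneous extended haplotypes around the diagnostic allele
   (high EHH/iHH); and
6. tight clustering of carrier haplotypes in networks built from the block
   region, but not elsewhere on the chromosome.

`introsig` implements each signature as a small, testable operation, plus a
seeded generator that produces synthetic datasets with exactly this
structure so the whole battery can be validated end to end without any
external data.

## Statistics implemented

**Raw p-distance and identity.** All sequence comparisons use the
uncorrected proportion of differing sites. Under the default
`pairwise_deletion` policy a site is dropped from numerator and denominator
when either sequence carries a gap or an IUPAC ambiguity code; directly
sequenced diploid donors are often reported with heterozygous ambiguity
codes, and counting those as differences would inflate distances. Percent
identity is `100 * (1 - p)` under the same mask, reported half-up to one
decimal at the reporting layer only. The divergence summary's default
interval is the empirical 2.5/97.5 percentile range of the pairwise
distances using inverse-ECDF quantiles (small allele sets then report their
min/max); a percentile bootstrap of the mean is available as an option.

**Recombination (pairwise homoplasy, Phi).** An alignment column is
*informative* if, ignoring gaps/ambiguity, it has at least two states each
carried by at least two sequences. For a pair of sites, the refined
incompatibility score is the minimum number of extra mutations any
genealogy must invoke to explain both characters jointly, computed exactly
on the partition-intersection graph as `|E| - |V| + components`; for binary
sites this is the four-gamete test, and the implementation is checked
against exhaustive minimum-homoplasy search over all topologies for small
cases. The windowed statistic averages scores (each normalized by its
maximum `min(k_i, k_j) - 1`) over informative-site pairs within 100 bp of
each other (the conventional window). Recombination makes *nearby* sites
more compatible than the alignment-wide mixture, so the test rejects when
the observed windowed mean is small relative to a null built by permuting
the assignment of informative sites to positions:
`p = (1 + #{perm <= obs}) / (n_perm + 1)`. Ties count toward the null, so a
fully compatible (e.g. two-haplotype) alignment gives p = 1 by
construction. Direction and calibration are pinned by two generators:
tree-evolved finite-sites alignments (homoplasy, no recombination) give
uniform p-values, and mosaic panels force rejection.

**Linkage disequilibrium.** With phased haplotypes, `D = p_AB - p_A p_B`
and `r2 = D^2 / (p_A q_A p_B q_B)` by direct counting; with unphased
genotypes, two-locus haplotype frequencies are estimated by EM (double
heterozygotes split between cis and trans each iteration) and r2 follows.
Every result records which estimation mode produced it. LD strength
classes use the conventional cutoffs (strong r2 > 0.8, moderate 0.5–0.8,
weak 0.2–0.5); a class's *span* is the longest contiguous genomic run
obtained by merging the `[pos_i, pos_j]` intervals of its pairs. LD decay
is summarized by fitting the sample-size-corrected expectation

$$E[r^2] = \frac{10+C}{(2+C)(11+C)}
  \left[1 + \frac{(3+C)(12+12C+C^2)}{n(2+C)(11+C)}\right],
  \qquad C = \rho\,d,\ \rho = 4N_e r,$$

to the observed (distance, r2) pairs by ordinary least squares with
`rho >= 0`, initialized at `2 / median(d)`. The curve's limits pin the
implementation: `(10/22)(1 + 18/(11n))` at `C -> 0` and `1/n` at
`C -> infinity`. VIF pruning (`VIF = 1/(1 - R^2)` of each marker regressed
on the other markers in a sliding window; threshold 2 is the `R^2 > 0.5`
rule) is provided for analyses that assume near-equilibrium markers.

**EHH, iHH and bifurcation trees.** Among the `n_a` haplotypes carrying a
core allele, EHH at a flanking marker is the probability that two randomly
drawn carriers are identical at every marker from the core to that
position, `sum_h C(n_h,2) / C(n_a,2)` over prefix classes — 1 at the core
and non-increasing outward. Physical distance only; no statistical test is
attached. iHH is the per-side trapezoidal integral of the curve (bp).
Curves stop at the first marker below `stop_threshold` (default 0.05, a
conventional choice; the stopping marker is included and the threshold is
configurable). Fewer than two carriers yields an explicit not-computable
result rather than a number. Bifurcation trees record the prefix-partition
splits marker by marker, children ordered by allele code.

**Trees and networks.** Neighbor joining minimizes the standard Q
criterion with deterministic lowest-index tie-breaks; negative branch
estimates are clamped to zero and the clamped total recorded. NeighborNet
agglomerates clusters of one or two chain-ends using the NJ criterion on
cluster-averaged distances, selects the linking ends with a node-level
criterion, and reduces each three-node chain with the standard (2/3, 1/3)
distance updates; backtracking yields a circular taxon ordering, and all
`n(n-1)/2` circular splits are weighted by non-negative least squares
(Lawson–Hanson active set) against the input distances, dropping
zero-weight splits. On additive metrics both reduce to the generating
tree — checked to 1e-6. Ordinary unweighted NNLS is used; no variance
model is assumed. The cluster-cohesion score
`1 - mean(within) / mean(between)` quantifies what a split network shows
qualitatively, with a label-permutation p-value; it is invariant to
distance rescaling.

**Windows.** Expected heterozygosity is `2p(1-p)` on called alleles within
a group (the `2n/(2n-1)` correction is available, off by default, matching
the common chip-analysis convention). Sliding windows are half-open
`[start, start + window)`, 500 kb by default; the window-size-only
convention in published scans leaves the step open, so the default step is
window/5 for smooth tracks and is configurable. SNP density counts
group-polymorphic markers (MAF at or above a threshold) per bin anchored
at the region start.

## The synthetic-data generator

`generate_introgression_dataset()` encodes the study conditions the
battery is designed for. Defaults: four demes of 25 diploids with
donor-haplotype frequencies 0.31, 0.20, 0.20, 0.02 (the observed range of
the introgressed-allele frequency across reintroduced populations, whose
chip panel was of comparable per-population size); a 6 Mb chromosome
carrying 400 SNPs (RAD-like density of ~67/Mb) with the focal/diagnostic
SNP at 3 Mb; recipient per-site allele frequencies drawn Beta(0.8, 4)
(low-diversity, many near-fixed sites, as expected after a strong
bottleneck); and a single donor haplotype carrying, at 50% of sites, an
allele absent from the recipient pool (`donor_divergence`), fixed-different
at the diagnostic SNP. Each carrier haplotype receives the donor sequence
over an interval around the focal position with independent one-sided
Exponential lengths of mean `block_halflife = donor_block_target / 2`
(default target 750 kb, the width of the observed elevated-heterozygosity
region): the first-order expectation for block erosion `g` generations
after a single hybridization event, with `g` and the local recombination
rate entering only through the halflife. Diploids are formed by random
pairing within deme, so target frequencies hold in expectation and the
realized values are reported in the truth object. Everything is a pure
function of (parameters, seed), and the truth object carries per-haplotype
block intervals for oracle-style tests.

What the generator deliberately does **not** emulate: coalescent ancestry
and background LD in the recipient (sites are independent given their
frequencies), mutation after introgression, selection dynamics, genotyping
error, and shared descent among carrier blocks (each carrier erodes
independently). Passing the battery on this generator therefore shows the
statistics respond correctly to a planted block structure — not that the
pipeline is robust to every feature of real data. For the LD-decay
calibration specifically, background LD is essential, so that check uses
neutral coalescent simulations with recombination (msprime through the
system `python`) in which the true `rho = 4 N_e r` is known exactly.

`generate_alignment_set()` and `synthesize_drb_panel()` build sequence
panels with the structure of the sequenced *DRB* gene study set: two
internally fixed recipient haplotype groups (7 + 7) differing at 116 of
2253 sites (5.1%), one donor goat at exactly 5 differences from the
carrier haplotype (99.8% identity), and a 5-goat panel with 64 informative
sites arranged in contiguous blocks of alternating bipartitions — the
footprint of historical recombination among goat haplotypes. The panel is
synthetic (the original sequences are not redistributed); its headline
numbers are design constants mirroring the published study design, and all
statistics are recomputed from the sequences at run time.

## Numerical choices and edge cases

- Coordinates are 1-based inclusive bp everywhere (VCF convention);
  distances are physical bp.
- Missing genotypes are a single NA sentinel, preserved through I/O; MAF
  and call rates always use called alleles only. Phased haplotype input
  must be complete (phasing happens upstream or in the generator).
- QC order is fixed and logged: sample call rate, then marker call rate,
  then MAF, then the all-heterozygous exclusion (a marker at observed
  heterozygosity 1 in every called sample is treated as a collapsed
  duplication artifact). Filters are idempotent.
- PLINK text and TSV dialects carry no ref/alt designation; alleles are
  coded alphabetically on read, and the round-trip guarantee is byte
  identity of write–read–write. VCF preserves allele codes exactly.
- The EM r2 estimator flags non-convergence rather than failing; its
  fixed point equals direct counting when no double heterozygotes exist,
  and it matches a direct numerical maximum-likelihood fit to 1e-6.
- The decay fit optimizes `log(rho)` with a wide bracket plus a grid
  polish; a flat surface returns the best point flagged unconverged.
- NJ and NeighborNet break ties by the smallest index pair — determinism
  is preferred over fidelity to any particular existing implementation's
  tie behavior.
- Permutation p-values use the add-one convention and count ties toward
  the null, so they are never anti-conservative by discreteness.

## Validation design and known limitations

The test suite validates every operation against an independent oracle
(brute-force enumeration, closed forms, or an established implementation
used only as a cross-check), and then runs the battery at these problem
sizes, chosen to exercise the statistics well inside a desktop budget:
Phi type-I error over 500 tree-evolved alignments (12 taxa x 300 bp,
199 permutations) with power over 100 mosaic panels; LD-decay recovery
over 20 coalescent simulations (50 haplotypes, 200 markers, 1 Mb,
rho = 1e-4/bp, MAF >= 0.05 screen as in chip-style LD protocols); and the
signature battery over 25–100 generator seeds per signature.

Two quantitative behaviors are worth knowing about:

- **The OLS decay fit overestimates rho on coalescent data.** Fitting the
  Hill expectation to raw pairwise r2 (the standard `nls` protocol this
  package reproduces) recovers a planted rho to within 1% on noiseless
  curve data, but on coalescent haplotypes the median recovery ratio is
  about 1.3: realized E[r2] at small C lies below the ratio-of-expectations
  curve, so the fitted decay is steeper than the truth. Without a MAF
  screen the bias reaches ~3x. Fitted rho values should therefore be read
  as comparative decay summaries (population A vs population B), not as
  calibrated estimates of 4Ner — which is exactly how the motivating
  analysis uses them.
- **Strong-LD spans undershoot the planted block under independent
  erosion.** With each carrier eroding its block independently
  (Exponential one-sided lengths, mean 375 kb), the r2 between two
  donor-divergent sites is governed by carrier-coverage ratios; pairs
  further apart than ~0.2 block-halflives rarely exceed r2 = 0.8, and the
  merged strong-pair span has median ~0.3-0.4 of the 750 kb target at the
  default deme sizes. Observed data showing strong LD across megabases
  (r2 = 0.85 over 2.1 Mb) correspond to essentially unbroken blocks —
  very recent introgression and/or shared descent among carrier blocks,
  which the independence assumption deliberately leaves out. The span
  statistic still separates high-frequency demes from the negative
  control by an order of magnitude.

Other limitations: no genetic-map distances (physical bp only), no D'
or haplotype-block algorithms, no model-corrected sequence distances, no
iHS/XP-EHH standardization, and network layout is left to SplitsTree-
compatible NEXUS export. The pipeline accepts phased input but does not
phase; imputation and genotype calling are out of scope.
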