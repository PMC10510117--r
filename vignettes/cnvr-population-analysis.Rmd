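---
title: "CNVR construction and breed differentiation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CNVR construction and breed differentiation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvrpop)
```

`cnvrpop` analyses copy number variation between two related populations
from per-individual read-depth CNV calls. This vignette documents the
statistical model, the conventions and tunable parameters, the design of
the synthetic landscape generator that the test suite runs against, and the
numerical decisions made where the procedure admitted more than one
reasonable choice.

## From calls to CNV regions

Read-depth callers emit, per individual, deletion and duplication intervals
with quality fields: a call p-value, the fraction `q0` of reads with zero
mapping quality, and the interval size. The pipeline's call filter retains
calls with `pval < 0.01`, `q0 < 0.5` and `size > 1000` bp. All three
inequalities are strict, exactly as the rules are conventionally printed;
in particular a 1,000 bp call is removed. Caller output carries four
e-value columns and conventions differ on which one is "the" p-value, so
`read_cnv_calls()` exposes `pval_column` (default the first).

Internally every interval is 0-based half-open, making lengths
subtraction-exact (`size = end − start`); the caller dialect (1-based
inclusive) and GFF3 are converted exactly once, at the I/O boundary, and
the round-trip identity of every reader/writer pair is property-tested.

CNV regions (CNVRs) are the union of transitively overlapping calls across
individuals: within a chromosome — and within an svtype stratum, since
deletion and duplication regions are reported separately — every maximal
set of calls connected by at least 1 bp of overlap becomes one region
spanning their union, carrying the set of contributing samples. Two
conventions deserve note:

* **Overlap criterion.** Any positive overlap merges; no reciprocal
  fraction is required. Abutting intervals that share no base do *not*
  merge (this is why the interval reduction runs with a zero gap width).
* **Carrier filter.** "At least three individuals per breed" is ambiguous
  between *some* breed and *every* breed. The default is
  `mode = "any_breed"`: requiring every breed would make breed-specific
  regions impossible by construction, yet breed-specific region counts are
  a standard output of this analysis. `"each_breed"` is available.

Cross-type merging (`same_type_only = FALSE`) labels regions built from
both call types `MIXED`; it is off by default because deletion and
duplication region counts are conventionally reported separately.

## The V_ST differentiation scan

For each region the copy-number vector over all samples is split by
population and

$$V_{ST} = \frac{V_T - V_S}{V_T},$$

with $V_T$ the variance of the pooled vector and $V_S$ the unweighted mean
of the within-population variances. Three conventions are fixed here:

* **Variance estimator.** Both $V_T$ and the within-group variances use the
  unbiased $n-1$ estimator, and $V_S$ averages the group variances without
  weighting by group size. With integer copy-number configurations of
  10 vs 10 samples this convention produces exact small-denominator
  rationals — e.g. $8/27 = 0.296296$ for ten diploids against five diploids
  plus five triploids, and $25/63 = 0.396825$ for ten diploids against four
  diploids plus six haploids — which population-variance conventions do
  not. These two configurations are the package's frozen reference values.
* **Undefined and negative values.** $V_T = 0$ (all samples identical)
  flags the record undefined rather than raising; undefined records are
  excluded from thresholding. $V_S > V_T$ yields a negative value which is
  reported as-is — clipping would hide estimator behaviour.
* **Threshold.** Candidates are values at or above the 98th percentile,
  computed as nearest rank (sort ascending, take the element at rank
  $\lceil 0.98\,n\rceil$, no interpolation): reproducible and exact under
  ties.

V_ST is affine-invariant in the copy-number vector, so for two-point data
(carriers at one integer copy number, non-carriers diploid) it depends only
on the carrier-count split between the populations — a property the test
suite exploits.

Gene-level values assign each gene the maximum V_ST over regions
overlapping it by at least 1 bp; thresholding is conventionally applied at
gene level, and both region- and gene-level paths are exposed since
reports differ on which was used. Candidates are confirmed by one-way
fixed-effects ANOVA ($F = \mathrm{MSB}/\mathrm{MSE}$, df $(k-1, N-k)$) with
Tukey's HSD post hoc from the studentized range distribution, at
significance level 0.01. The ANOVA and Tukey computations delegate to
`stats::aov()`/`stats::TukeyHSD()`; tests verify the closed form
($F = 9$ on the 10-vs-5/5 fixture), the $k = 2$ identity
$p_{\mathrm{Tukey}} = p_{\mathrm{ANOVA}}$ (equivalently
$q = \sqrt2\,|t|$), and a direct studentized-range computation at $k = 3$.
Degenerate inputs are explicit: zero within-group variance with differing
means reports $F = \infty$, $p = 0$; all-identical values are flagged
undefined.

## Presence/absence clustering with AU/BP support

Samples are clustered on the 0/1 CNVR carriage matrix: Jaccard distance
between sample columns (1 minus shared over present-in-either; 0 for two
all-zero samples) and UPGMA (average linkage, via `stats::hclust`).
Euclidean and correlation distances are available for sensitivity
analysis; the metric is a convention, not part of the statistic.

Cluster support is estimated by multiscale bootstrap, re-implemented here:

1. For each scale $r$ in a grid (default $0.5, 0.6, \dots, 1.4$), draw
   `nboot` resamples of $\mathrm{round}(r\,n)$ rows (regions) with
   replacement, recluster the samples, and record $BP_r$ — the fraction of
   resampled trees containing each observed cluster, matched by member-set
   equality (the standard bootstrap-support semantics, independent of
   internal topology).
2. Transform to probit scale, $z_r = \Phi^{-1}(1 - BP_r)$, and fit
   $z_r = v\sqrt r + c/\sqrt r$ by weighted least squares, the weight of
   each scale being the inverse delta-method variance of $z_r$
   (proportional to the binomial variance of $BP_r$). Saturated $BP_r$ of
   0 or 1 is clamped $1/(2\,\mathrm{nboot})$ from the boundary before the
   transform, bounding the bias symmetrically.
3. Report $AU = 1 - \Phi(v - c)$ and $BP = 1 - \Phi(v + c)$.

A cluster observed at fewer than two non-saturated scales cannot support
the two-parameter fit; it is flagged degenerate and reports the clamped
counted BP at the scale nearest 1. This makes the single-scale grid
`r_grid = 1` reduce exactly to ordinary bootstrap probabilities, which the
tests assert. The all-samples root is in every tree and gets support 1 by
convention. Resampling is seeded: the same seed reproduces every support
value to the last digit.

## Annotation

CNVRs are intersected with gene and QTL intervals (after case-insensitive
"chr"-prefix normalization of chromosome names). The overlap rule is a
single strict inequality `overlap_bp > min_overlap` with defaults 0 for
genes (any shared base) and 1000 for QTLs (the "more than 1 kb" rule, so a
1,000 bp overlap is excluded). Over-representation of hit genes in
user-supplied gene sets uses the one-sided hypergeometric tail
$P(X \ge k)$ with a 0.05 flag and no multiple-testing correction by
default, mirroring the raw-p convention of enrichment reports in this
literature; a Benjamini–Hochberg column is optional. Live GO/KEGG database
queries are out of scope — gene sets are inputs.

## The synthetic landscape generator

The generator produces a ground-truth landscape emulating a two-breed
resequencing study *after* variant calling: two populations of 10
individuals, 26 autosomes on a linearly decreasing length ladder
(275 → 45 Mb), ~5,000 regions with 69% deletions, 92.5% of regions
polymorphic in both breeds, 50 regions strongly frequency-differentiated
(gap ≥ 0.7), caller-bin resolution of 300 bp, and Gaussian read-depth
noise of 0.25 copy-number units. Carriers of a region share one integer
copy number (deletions 0–1, duplications 3–6); this keeps truth simple and
is what makes the exact rational V_ST reference values reachable.

Choices the defaults encode where no standard value exists:

* **Region sizes** are drawn log-scale over [1.2, 400] kb with a
  Beta(1, 1.6) exponent, skewing small so the median is just under 10 kb —
  matching the empirical observation that most deletion regions are below
  10 kb. (A flat log-uniform draw over that range would put the median at
  20 kb.)
* **Carrier frequencies.** Shared regions draw one frequency from
  $0.1 + 0.8\,\mathrm{Beta}(1.2, 2.5)$ — L-shaped as empirical CNVR
  frequency spectra are, bounded away from 0 so "shared" regions genuinely
  segregate in both breeds. Breed-specific regions draw U(0.15, 0.35) in
  one breed (breed-restricted polymorphisms at modest frequency) and 0 in
  the other. Differentiated regions are near fixation in one breed
  (U(max(0.85, gap), 1)) with the other at least the configured gap lower.
  These distributions were fixed once, from the above rationale, before
  the recovery tests existed.
* **Boundary jitter** is Gaussian (sd 300 bp, one caller bin) snapped to
  bin multiples: read-depth callers resolve breakpoints only to bins.
* **Call quality fields** are drawn so 5% of calls violate each of the
  p-value and q0 filters, and 5% decoy calls under 1 kb are added, so every
  branch of the filter is exercised on simulated data.

What the generator does **not** emulate: within-breed relatedness
(individuals are exchangeable), linkage between regions, GC or mappability
bias, per-bin read-depth tracks, sex chromosomes, and caller artefacts
beyond symmetric boundary jitter. Passing recovery tests therefore show the
pipeline's correctness on an idealized landscape with known truth — not
calling accuracy on real reads, which is the caller's responsibility
upstream.

Everything is seeded and deterministic: `simulate_truth()`,
`draw_carriers()`, `emit_calls()` and `emit_copy_numbers()` derive
independent streams from offsets of the config seed, and the carrier
assignment is shared between the call tables and the copy-number matrix.

## Problem sizes and verification

The test suite verifies each stage against an independent oracle at sizes
chosen to keep a full run around a minute: CNVR merging against a per-base
sweep oracle on a 1 Mb toy genome (100 random instances), V_ST against a
two-pass variance oracle (10,000 random vectors, agreement to 1e−12),
interval intersection against a quadratic all-pairs oracle, hypergeometric
p-values against big-integer tail sums, and cluster support on a
two-block 200 × 20 presence matrix with 1,000 resamples per scale, where
the two breed blocks must reach AU and BP ≥ 0.95. The full-scale recovery
check runs the default 5,000-region simulation once (fixed seed): at least
80% of truth-differentiated regions must exceed the 98th-percentile V_ST
threshold, and at least 95% of truth regions with expected carrier counts
≥ 5 per breed must be recovered as CNVRs passing the carrier filter with
≥ 50% reciprocal overlap.

## Known limitations

* V_ST significance is by percentile rank plus ANOVA confirmation; no
  permutation null is provided.
* Carrier copy numbers are constant within a region in the simulator;
  per-carrier mixtures (e.g. segregating 1- and 0-copy deletions) occur in
  real data and would lower V_ST for a given frequency split.
* The QTL annotation assumes coordinates already on the analysis assembly;
  no liftover is performed.
* Only average linkage is implemented for clustering, matching the UPGMA
  convention of this analysis; alternative linkages are out of scope.
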