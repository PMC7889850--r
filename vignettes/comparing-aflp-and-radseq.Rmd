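---
title: "Comparing AFLP fingerprints with RADseq SNPs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing AFLP fingerprints with RADseq SNPs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Phylogeographic studies delimit evolutionary entities from multi-locus
genetic data. Two marker systems dominate the comparative literature:
AFLP fingerprinting, which scores a few hundred dominant presence/absence
bands per individual across several selective primer combinations, and
RADseq, which yields thousands of SNP genotypes. `aflprad` implements the
analysis layer needed to compare the two on the same individuals: AFLP
quality control driven by blind technical replicates, the dissimilarity
coefficients appropriate to each data type (Jaccard for dominant bands,
Gower for dosages with missing calls), rank-based ANOSIM and the Mantel
matrix-correlation test with permutation inference, non-metric
multidimensional scaling, and a locus-rarefaction engine that asks how
many SNP loci are needed to recover the full dataset's regional signal.
A paired synthetic-data generator makes every stage testable without any
external download.

# Models and procedures

## Replicate-guided AFLP locus filtering

Blind replicates are the same DNA run twice through the whole AFLP
workflow; ideally their scored profiles are identical, and every
mismatch is scoring noise. The filter minimizes the sum of p-distances
(proportion of differing loci) over all replicate pairs by a single
greedy sweep: each locus in stored order is tentatively removed, the sum
is recomputed on the remaining loci, and the removal is kept only when
the sum strictly decreases. Three numerical choices matter:

* the p-distance denominator is the *current* locus count, so removing a
  locus on which replicates agree increases the sum — without this the
  procedure would strip every matching locus too;
* ties keep the locus (strict inequality), and the accept test is done in
  integer arithmetic (`mismatches_new * L_old < mismatches_old * L_new`),
  so floating-point rounding can never decide a tie;
* one sweep by default. The procedure is order-dependent in principle;
  the per-decision trajectory is recorded in the `qc_log`, and
  `iterate = TRUE` repeats sweeps to a fixed point for users who prefer
  convergence over fidelity to the one-sweep description.

If accepting every removal would empty the matrix the filter aborts:
that pattern means the replicates disagree pervasively and the input
needs inspection, not automated cleaning.

## Ordination-based outlier screening

Per primer combination the package computes Jaccard distances, a 2-D
NMDS, and a 90% quantile ellipse per region, i.e. Mahalanobis distance
against `qchisq(0.9, df = 2)` on the sample covariance of the region's
ordination coordinates. An individual outside its own region's ellipse
in more than 50% of combinations, or a combination with more than 10% of
individuals outside, is flagged. Defaults (coverage 0.90, thresholds 0.5
and 0.1) follow the screening rule the package reimplements; all three
are arguments. Two open points were decided here: ellipses are
*per region* by default (the regions are the units whose coherence is
being tested; a global-ellipse mode exists behind `per_region = FALSE`),
and individual flags are assigned before combination flags, with
individual fractions recomputed once over retained combinations (no
fixpoint iteration). Note a small-sample fact: a region with `n` members
can never place a point outside the 90% ellipse when
`(n-1)^2/n < qchisq(0.9, 2) ≈ 4.6`, i.e. for `n <= 5`; with the
three-individuals-per-region design the screen is therefore effectively
conservative, which mirrors how such rules behave on small real designs.
Regions with fewer than 3 members have no defined ellipse; their samples
are marked unassessable and never counted as outside.

## Dissimilarities

* **p-distance**: proportion of differing positions of two equal-length
  binary profiles.
* **Jaccard**: `1 - shared / union` over bands present in at least one of
  the two samples; shared absences are ignored, which is the standard
  choice for dominant markers. A pair of all-zero profiles is an
  undefined 0/0 case; it is reported as distance 0 with a warning, the
  convention common in ecology software, so a valid matrix is always
  produced.
* **Gower**: mean over jointly scored loci of `|x_i - x_j| / range`,
  with per-locus range scaling, pairwise deletion of missing values and
  no imputation. Dosages are treated as interval-scaled (they are
  ordered allele counts), not categorical. Zero-range (monomorphic) loci
  contribute nothing and are excluded from the mean; a pair whose shared
  loci are all monomorphic has distance 0, and a pair sharing no scored
  locus at all is an error naming the pair — silent guesses here would
  corrupt downstream permutation tests. Gower distances are invariant to
  per-locus polarity flips (`x -> 2 - x`), which is why the reference
  allele convention of the STRUCTURE reader cannot affect results.

## Permutation statistics

**ANOSIM** ranks all `n(n-1)/2` distances (average ranks on ties) and
computes `R = (mean between-group rank - mean within-group rank) /
(n(n-1)/4)`; being rank-based it is invariant under monotone transforms
of the distances. **Mantel** correlates the two lower triangles with
Pearson's r and permutes objects of the second matrix jointly over rows
and columns; the test is one-sided (`r_perm >= r_obs`). Both use the
add-one convention `p = (#{stat_perm >= stat_obs} + 1) / (n_perm + 1)`,
so the observed labelling counts as one permutation and p is never 0.
Defaults are 9999 permutations; the rarefaction engine uses 999 inside
each replicate because its read-out is the statistic trajectory, not the
per-replicate p-value (both are arguments). Significance stars in
reports are `*` at 0.05 and `**` at 0.01.

**NMDS** minimizes Kruskal stress-1 by alternating isotonic regression
(pool-adjacent-violators, via `stats::isoreg`, on the configuration
distances taken in dissimilarity order) with a Guttman-transform update
(non-metric SMACOF). The first restart starts from the classical-scaling
solution, the remaining restarts from uniform random configurations;
the best of `restarts` (default 50) solutions is returned. A restart
stops when the stress improvement falls below `tol` (default 1e-6) or
after `maxit` iterations, and an update that increases stress is rolled
back, so the reported stress trajectory is non-increasing. Coincident
input points are embedded at the origin with stress 0 rather than
erroring, because the outlier screen must tolerate degenerate
primer-combination matrices.

## Locus rarefaction

Subsets of `s` loci are drawn uniformly without replacement — no locus
twice *within* a replicate, loci free to recur *across* replicates — for
`s = step, 2*step, ...` (default step 50, 50 replicates per step), plus
any extra step such as the AFLP-matched locus count, which is included
even when it is not a multiple of the step. Per subset the package
computes Gower distances, ANOSIM Global R against the region grouping,
and the Mantel correlation with the full-matrix Gower distances.
Degenerate subsets (a sample pair with no jointly scored locus, or a
grouping that collapses) become explicit not-applicable records with the
reason attached — at low locus counts and heavy missingness this is an
expected outcome, not an exception. Every (step, replicate) record runs
under a seed substream derived deterministically from the master seed,
so the whole sweep is reproducible and any single record can be
recomputed in isolation. Subsampling provably never alters per-locus
missingness, and the test suite asserts it.

# The synthetic generator: what it emulates, and what not

`simulate_structure()` draws ancestral frequencies
`p ~ Uniform(0.05, 0.95)` and, for differentiation `fst > 0`, regional
frequencies from the Balding–Nichols Beta distribution
`Beta(p(1-fst)/fst, (1-p)(1-fst)/fst)`, giving `E[f] = p` and
`Var(f) = fst * p(1-p)`. `simulate_aflp()` converts regional frequencies
to dominant band probabilities `1 - (1-f)^2` — a heterozygote shows the
band, which is exactly the information loss that makes AFLP weaker per
locus than codominant SNPs — applies independent scoring noise
(flip probability `epsilon`) to every scored profile including blind
replicate copies (expected replicate p-distance `2*epsilon*(1-epsilon)`),
and assigns loci round-robin to 8 primer-combination tags.
`simulate_snp()` draws dosages `Binomial(2, f)` and masks entries
missing-completely-at-random at rate `missing_rate`.

Defaults state the emulated study design once: 5 regions x 3
individuals, 3 blind replicates, 500 AFLP loci vs 5000 SNPs, `fst = 0.3`,
`epsilon = 0.05`, `missing_rate = 0.2`. The AFLP and SNP sides share the
latent regional structure but not physical loci (two frequency blocks
from one draw), which is what makes their distance matrices correlate —
as in a real organism, where the two marker types sample different parts
of the same genome history.

What the generator deliberately does **not** model: linkage and
coalescent genealogies (loci are exchangeable and independent),
selection, isolation-by-distance within regions, non-random missingness,
band-size homoplasy between unrelated AFLP fragments, and per-individual
quality differences. A green test on synthetic data therefore
establishes that the algorithms are implemented correctly and respond to
regional structure as designed — not that any particular real dataset
will show the same effect sizes.

# Design choices on open questions

* **Greedy filter, one pass vs convergence**: one pass is the default
  (matching the procedure's published description); `iterate = TRUE` is
  available.
* **STRUCTURE reference allele**: the numerically lowest code observed
  per locus. Allele polarity is not defined by the format, and Gower
  distances are polarity-invariant, so the choice is observable only in
  the dosage labels. Consequence: a locus monomorphic for dosage 0
  round-trips through the two-row dialect polarity-flipped; the dosage
  CSV dialect is bit-exact.
* **Region labels** come from the metadata file, never parsed out of
  sample names.
* **ANOSIM permutation count** for published-style summaries: 9999, the
  count documented for the Mantel tests, since no separate count is
  documented for ANOSIM.
* **Rarefaction internal permutations**: 999 by default for
  tractability; exposed as `n_perm`.
* **The "no shared signal" null**: testing that unrelated AFLP and SNP
  datasets give Mantel r near 0 requires the two datasets' *regional
  structures* to be independent. Simply drawing two independent sets of
  latent frequencies is not enough: if both simulations keep the same
  sample-to-region partition, both distance matrices carry the same
  within/between-region block pattern and their expected Mantel
  correlation is substantially positive. The null simulations in the
  test suite therefore assign individuals to regions independently on
  one side (a random relabeling), which is the faithful formalization of
  "independent structures".

# Known limitations

* The outlier screen's NMDS is stochastic; results are deterministic
  only under a fixed `seed` (all entry points take one).
* ANOSIM saturates at exactly `R = 1` once between-group ranks dominate
  completely; with thousands of strongly differentiated loci the
  statistic cannot distinguish `fst = 0.15` from `fst = 0.3` (both give
  `R = 1`). Tests of monotonicity in `fst` are therefore weak at the top
  of the range.
* Jaccard on a pair of all-zero profiles and Gower on all-monomorphic
  shared loci are conventions (distance 0), not measurements; both emit
  warnings or are documented above so users can exclude such samples.
* The package does not process raw reads or electropherograms, run
  Bayesian clustering, or build phylogenetic networks; it starts from
  scored 0/1 tables and exported SNP matrices.
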