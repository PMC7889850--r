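# aflprad

Comparative phylogeographic analysis of AFLP fingerprints and RADseq
SNPs in R.

## The problem

Do a few hundred cheap, dominant AFLP presence/absence markers recover
the same phylogeographic structure as thousands of RADseq SNPs — and how
many SNP loci are actually needed to match the full dataset's signal?
`aflprad` implements the analysis layer for answering these questions on
paired datasets over the same individuals:

* **AFLP quality control** — the blind-replicate greedy locus filter
  (remove a locus iff it strictly lowers the summed replicate
  p-distance, recomputed on the reduced matrix) and an NMDS-based
  outlier screen with per-region 90% quantile ellipses that flags
  individuals (outside in > 50% of primer combinations) and primer
  combinations (> 10% of individuals outside).
* **Dissimilarities** — p-distance for replicates, Jaccard
  (`d = 1 − shared/union`) for dominant bands, Gower
  (`d = mean |x_i − x_j| / range` over jointly scored loci, pairwise
  deletion) for SNP dosages with missing data.
* **Inference** — ANOSIM
  (`R = (mean rank between − mean rank within) / (n(n−1)/4)`), the
  Mantel matrix-correlation test (Pearson r, joint row/column
  permutation), and non-metric multidimensional scaling minimizing
  Kruskal stress-1 — all implemented from first principles with
  permutation p-values under the add-one convention.
* **Locus rarefaction** — repeated random locus subsets in fixed steps
  (default 50 loci × 50 replicates), per subset Global R and the Mantel
  correlation with the full matrix, with an AFLP reference overlay at
  the AFLP locus count.
* **Synthetic paired data** — a Balding–Nichols F-model generator of
  regional allele frequencies feeding a dominant-band AFLP simulator
  (scoring noise, blind replicates, 8 primer combinations) and a diploid
  SNP dosage simulator with random missingness, so the whole pipeline is
  testable offline.

File formats: delimited 0/1 marker tables (optional `combo:locus`
headers), SNP dosage CSVs and STRUCTURE-style two-row exports (`-9`
missing), metadata CSVs (`sample, region, replicate_of, match_key`) and
square distance-matrix CSVs.

## Worked example

```r
library(aflprad)

params <- sim_params(n_loci_aflp = 300, n_loci_snp = 3000, fst = 0.3,
                     epsilon = 0.05, missing_rate = 0.2, seed = 42)
sim <- simulate_paired(params)

qc <- greedy_replicate_filter(sim$aflp$matrix, replicate_pairs(sim$aflp$meta))
print(qc$log)
#> Replicate-guided locus filter: 73 locus/loci removed in 1 pass(es)
#>   replicate p-distance sum: 0.25667 -> 0.00000

keep <- sim$aflp$meta$sample[is.na(sim$aflp$meta$replicate_of)]
dj <- jaccard_matrix(qc$matrix[keep, ])      # AFLP distances
dg <- gower_matrix(sim$snp$matrix)           # SNP distances
groups <- region_groups(sim$snp$meta)

anosim(dj, groups, n_perm = 999, seed = 1)
#> ANOSIM: Global R = 0.9778**  (p = 0.001, 999 permutations)
anosim(dg, groups, n_perm = 999, seed = 2)
#> ANOSIM: Global R = 1.0000**  (p = 0.001, 999 permutations)
mantel(dj, dg, n_perm = 999, seed = 3)
#> Mantel: r = 0.7538**  (p = 0.001, 999 permutations)

rarefaction_curves(sim$snp$matrix, groups, step = 500, reps = 10,
                   n_perm = 99, seed = 4)
#> Locus rarefaction: 6 steps x 10 replicates on 3000 loci (full Global R = 1.000)
#>   step n_applicable n_not_applicable mean_global_R sd_global_R mean_mantel_r
#> 1  500           10                0             1           0     0.9266735
#> 2 1000           10                0             1           0     0.9709836
#> ...
```

Reading: the replicate filter strips the 73 noise-affected loci and
drives the replicate mismatch sum to zero; with strong differentiation
(`fst = 0.3`) both marker types separate the five regions (Global R near
1), the AFLP and SNP distance matrices agree (Mantel r = 0.75,
p = 0.001), and already 500-locus random SNP subsets carry most of the
full matrix's information (mean Mantel r vs full = 0.93, rising towards
1 as loci are added). `**` marks p ≤ 0.01, `*` p ≤ 0.05.

An end-to-end run from files is available via `run_compare(config)` (see
`?run_compare`) or the CLI at `inst/cli/aflprad.R`
(`simulate | qc | distance | anosim | mantel | nmds | rarefy | compare`).

## Scope

The package starts from scored 0/1 AFLP tables and exported SNP
matrices. Raw-read processing (Stacks etc.), electropherogram peak
scoring, Bayesian clustering and phylogenetic-network construction are
out of scope.
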