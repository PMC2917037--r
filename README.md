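# CNAsubtypes

Copy-number aberration (CNA) analysis and genomic subtyping for tumor
cohorts profiled by array-CGH.

Breast tumors (and many other cancers) carry characteristic patterns of
DNA copy-number gains, losses, and high-level amplifications. Given
per-probe log2 ratios for a cohort, this package reconstructs the full
analysis chain used to define copy-number–based molecular subtypes:

1. **Segmentation** — circular binary segmentation (CBS) of each probe-
   ordered log2 profile: the maximal circular-arc statistic
   |S_j − S_i|·√(n/(k(n−k))) is tested against a within-segment
   permutation null, splitting recursively at α = 0.01.
2. **Calling** — sample-adaptive thresholds τ± = median ± max(2.5·s,
   0.1), with s the MAD of positionally smoothed data; segments of < 4
   probes are neutralized; high-level amplification means a called gain
   with segment log2 ≥ 1. Per-sample fraction of the genome altered
   (FGA) summarizes the burden.
3. **Recurrent-region scoring** (GISTIC-style) — per-probe score
   G(m) = Σ_aberrant samples min(|seg log2|, 2), a cyclic-shift
   permutation null preserving within-sample segment structure,
   Benjamini–Hochberg q-values (regions kept at q < 0.25), and
   iterative peel-off peak extraction.
4. **Amplicon analysis** — recurrent high-level amplicons (> 1% of the
   cohort) and a directed coamplification matrix: entry (A,B) is the
   fraction of A-carriers also carrying B.
5. **Expression integration** — Pearson correlation of each gene's
   expression with its region's dosage, thresholded at the 95% quantile
   of a pooled null from 100 copy-number label permutations.
6. **Genomic subtyping** — hierarchical clustering (1 − Pearson,
   complete linkage, k = 6) of samples on average scaled region log2
   values; supervised Welch/Bonferroni region tests; per-subtype
   expression centroids and nearest-centroid classification.
7. **Survival** — Kaplan–Meier, log-rank, and Cox proportional-hazards
   comparison of subtypes (wrapping the survival package).

A synthetic-cohort generator (`generateCohort`) emulates a BAC-array
cohort with six breast-cancer copy-number archetypes (luminal-simple,
luminal-complex, basal-complex, 17q12, amplifier, mixed), including
high-level amplicons with conditional coamplification, dosage-driven cis
gene expression, clinical covariates, and subtype-dependent survival —
so every stage is testable end to end without downloads.

## Tests

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "CNAsubtypes", load_package = "installed")'
```

## Worked example

```r
library(CNAsubtypes)

coh <- generateCohort(nSamples = 60, seed = 3)   # synthetic cohort
cn  <- segmentCohort(coh$cn, seed = 3)           # CBS per sample
cn  <- callCohort(cn)                            # adaptive gain/loss calls
cn
#> CopyNumberExperiment: 4999 probes x 60 samples
#>   assays: lr, seg, calls
#>   chromosomes: 22

gistic <- runGistic(cn, seed = 3)
gistic
#> GisticResults: 16 regions ( 7 gain, 9 loss ) at q < 0.25

head(fga(cn), 3)
#>             fga   fga_gain   fga_loss
#> S001 0.16723345 0.08741748 0.07981596
#> S002 0.07441488 0.05501100 0.01940388
#> S003 0.16203241 0.04700940 0.11502300

rm6 <- buildRegionMatrix(gistic, cn)             # regions x samples, scaled
as6 <- clusterSubtypes(rm6, k = 6)               # genomic subtypes
table(subtypeLabels(as6), coh$truth$subtype)
#>      17q12 amplifier basal-complex luminal-complex luminal-simple mixed
#>   C1     0         0             0              23              0     0
#>   C2     0        11             0               0              6     0
#>   C3     0         0             9               0              0     0
#>   C4     2         0             0               0              0     4
#>   C5     0         0             0               0              3     0
#>   C6     1         0             1               0              0     0

surv <- compareSurvival(SummarizedExperiment::colData(cn),
                        coh$truth$subtype, endpoint = "os")
surv$logrank
#> $chisq
#> [1] 40.44359
#>
#> $df
#> [1] 5
#>
#> $p
#> [1] 1.21529e-07
```

At this small example size (n = 60, only 3 planted 17q12 tumors) the
clustering resolves the major archetypes while the amplifier and
luminal-simple groups share one cluster; at the default n = 200 the
six-way partition recovers the planted subtypes with adjusted Rand
index ~0.8 and a pure 17q12 cluster. The clusters most enriched for
each truth label (C1 = luminal-complex, C3 = basal-complex, ...) show
the subtype structure directly. The log-rank test detects the planted
hazard ordering (p = 1.2e-07).

The segment means land in a `"seg"` assay and the −1/0/1 calls in a
`"calls"` assay of the `CopyNumberExperiment`; `gisticRegions(gistic)`
returns the retained regions as a `GRanges` with peak bounds, G-scores,
q-values and cohort frequencies. `runPipeline(list(seed = 3, out_dir =
"out"))` executes all seven stages and writes flat files (BED/SEG/TSV/
Newick) plus a checksum manifest.

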