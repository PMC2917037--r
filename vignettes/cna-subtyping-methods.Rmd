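---
title: "Copy-number aberration analysis and genomic subtyping: models and methods"
author: "CNAsubtypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Copy-number aberration analysis and genomic subtyping: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

CNAsubtypes implements an end-to-end analysis of array-CGH copy-number
profiles for tumor cohorts: segmentation of per-probe log2 ratios,
sample-adaptive discrete calling, permutation-based scoring of recurrent
aberrations with peak extraction, amplicon co-occurrence statistics,
copy-number/expression dosage integration, hierarchical genomic subtyping
with centroid export, and survival comparison. A synthetic-cohort
generator emulating breast-cancer copy-number archetypes makes the full
pipeline testable end to end without external data. This vignette records
the models, the tunable parameters, and the design decisions taken where
the methods literature leaves choices open.

# Segmentation: circular binary segmentation

Each sample's probe-ordered log2 profile is segmented per chromosome by
recursive circular binary splits. For a candidate stretch of $n$ probes,
the statistic is the maximal two-sample $t$ numerator over all circular
arcs: with centered values and partial sums $S_i$, arcs $(i, j]$ of length
$k \in [2, n-2]$ are scored $|S_j - S_i|\sqrt{n/(k(n-k))}$; the pooled
variance term is constant over arcs and permutations and cancels. The
observed maximum is referred to a within-segment permutation distribution
(default 1,000 draws, seeded); a split is accepted at $p < \alpha$
(default $\alpha = 0.01$) and the resulting pieces are re-tested
recursively. Restricting $k$ keeps any change-point from creating a
segment of fewer than 2 probes. The permutation loop stops early once
significance is impossible (the exceedance count exceeds
$\alpha(B{+}1){-}1$), and a prefix-sum range bound prunes permutations
that cannot reach the observed statistic, which keeps strongly
significant splits cheap.

Missing probes are excluded from the statistics and retain missing
segment means; an all-missing chromosome is skipped with a notice.

# Discrete calls and the fraction of the genome altered

Gain/loss thresholds are derived per sample from positionally smoothed
data: each probe is replaced by the mean of probes whose midpoints lie
within a window (the classical choice on ~100-kb-spacing BAC tiling
arrays is 250 kb, i.e. roughly a 5-probe neighborhood), and the
thresholds are
$$\tau_{\pm} = \mathrm{median} \pm \max(k \cdot s,\ \tau_{\min}),$$
with $s$ the Gaussian-consistent MAD of the smoothed values, $k = 2.5$
and floor $\tau_{\min} = 0.1$ by default. The exact derivation used with
the original two-channel pipeline is not published in reusable form; this
robust-scale rule reproduces its intent — noise-adaptive thresholds that
resist inflation by the aberration load — with auditable behavior
(`adaptiveThresholds`). Because the package's simulated cohorts tile
5,000 probes over the genome (~620-kb spacing), `callCohort`'s default
window is resolution-aware: $\max(250\,\mathrm{kb},\ 5\times$ median
probe spacing$)$, which equals 250 kb at real BAC density and preserves
the intended ~5-probe averaging at desk scale. A fixed 250-kb window at
desk density would smooth nothing and place the MAD on raw noise, which
in our experiments pushed thresholds onto the event amplitudes and
destroyed call sensitivity.

States are assigned per probe from its segment mean (gain at
$\ge \tau_+$, loss at $\le \tau_-$), segments of fewer than 4 probes are
forced neutral, and high-level amplification is flagged where a called
gain's segment mean reaches 1.0 in log2 (~4 copies against a diploid
reference). The fraction of the genome altered (FGA) is probe-count
weighted by default — the simplest auditable convention on evenly tiled
arrays — with a flag for bp weighting.

# Recurrent-aberration scoring

Gains and losses are scored separately. The per-probe score is
$$G(m) = \sum_{s\,:\,\mathrm{called}} \min(|\bar y_{ms}|, c),$$
the sum of called samples' segment-mean amplitudes, capped at $c = 2.0$
so a single extreme sample cannot dominate. The null model cyclically
shifts each sample's per-probe contribution profile by an independent
uniform offset: this preserves within-sample segment-length structure and
total aberration load — the properties that make marker-level nulls
honest — while destroying cross-sample positional alignment. Per-probe
$p$-values use the standard permutation estimator
$p(m) = (1 + \#\{G^{\mathrm{perm}}(m) \ge G(m)\})/(B+1)$ and are
converted to Benjamini–Hochberg $q$-values; regions are retained at
$q < 0.25$.

Peaks are extracted by iterative peel-off: the maximal-$G$ probe defines
a peak (the contiguous run within 95% of the local maximum) and a wide
region (the surrounding contiguous run below the $q$ threshold); the
driving samples' aberrations are removed on that chromosome only, scores
are recomputed, and the loop continues until nothing clears the
threshold. Two numerical choices matter here. First, the $p \to q$
mapping is frozen from the initial genome-wide scan and re-scored probes
are passed through it: recomputing the BH adjustment after each peel-off
would shrink the set of small $p$-values and spuriously inflate the $q$
of still-unextracted peaks (we observed clearly significant secondary
regions vanish this way). Second, removal is per chromosome rather than
genome-wide so that one amplicon cannot erase unrelated ones. Peaks of
the same kind closer than 5 probes are merged. Both permutation streams
(gain and loss) restart from the same seed, which makes the two analyses
exact mirrors under negation of the input — a property the test suite
asserts.

# Amplicons and coamplification

Per sample, maximal probe runs with segment mean $\ge 1.0$ become
amplified intervals; intervals are clustered across samples by
single-linkage overlap (one shared probe suffices) into loci, and loci
amplified in more than 1% of the cohort are retained. How per-sample
amplicons were merged into loci in the original analyses is not stated;
overlap-union is the minimal declared rule, and each locus is annotated
with the significant gain region containing its most frequently amplified
probe. The coamplification matrix is directed: entry $(A, B)$ is the
fraction of $A$-carriers also carrying $B$, so rows need not be
symmetric, but $(A,B)\cdot|A| = (B,A)\cdot|B| = |A \cap B|$ always. Loci
with fewer than 3 carriers are excluded; the display copy masks fractions
below 20%, and the raw matrix is always emitted alongside because that
cut is presentational.

# Expression–dosage integration

Genes are assigned to significant regions after expanding each region's
probe span by one probe per side to admit borderline genes. The region's
per-sample value is the mean segment log2 over its peak probes. For each
mapped gene, the Pearson correlation $r$ with its region value is
compared against $r^\ast$, the upper 5% quantile of the pooled null
distribution obtained from 100 permutations of the copy-number sample
labels. The null is pooled across genes rather than per gene: with 100
permutations a per-gene cutoff is unstable, and a single cohort-level
cutoff matches the one-cutoff convention. The pass rule is one-sided
(dosage drives expression in the direction of the aberration); a
two-sided flag exists. Genes or regions with zero variance are skipped
with a notice. A probe-level variant (`globalProbeCorrelation`)
correlates each gene with its covering probe's segment value, and
`signatureScore` supports arbitrary user-supplied gene lists, scoring by
centroid correlation when a centroid is given and by mean expression
otherwise.

# Genomic subtyping

Samples are clustered on the region-by-sample matrix of average scaled
log2 ratios: per region the mean segment value over peak probes, scaled
across samples. The default scaling divides by the region's standard
deviation *without centering*. This is a deliberate choice: with
mean-centering (z-scores), every unaberrated sample inherits the same
frequency-dependent nonzero baseline across regions, and that shared
component alone produces correlations near 0.45 between genomically quiet
tumors of entirely different subtypes — we observed single-aberration
samples of one subtype absorbed into another subtype's cluster through
exactly this artifact. Keeping neutral at zero removes the coupling while
preserving per-region comparability; z-score and raw modes remain
available (`buildRegionMatrix(scale =)`). Clustering is agglomerative
with distance $1 - $ Pearson correlation and complete linkage, cut at
$k = 6$ by default ($k$ is exposed; no cut criterion is claimed).

Cluster names are assigned post hoc by template matching: each
archetype's expected per-probe profile (event probability × amplitude,
marginalizing conditional events) is summarized over the regions and
greedily matched to cluster mean profiles by correlation, with the
mapping reported. Supervised comparisons between groups use a Welch
two-sample $t$-test per region on the scaled values (the pooled-variance
form is a flag), Bonferroni-adjusted across regions, reporting regions
with adjusted $P < 0.05$ and aberration frequency $\ge 20\%$ in at least
one group. Subtype expression centroids are per-gene means over member
samples restricted to a supplied gene list, and nearest-centroid
classification assigns the maximal-correlation label, with an optional
minimum correlation below which samples are unclassified and ties
resolved by declared centroid order.

# Survival

Kaplan–Meier estimation, the $k$-group log-rank test, and Cox
proportional-hazards regression (Efron ties by default, Breslow
available; Wald intervals) are provided as thin, validated wrappers over
the survival package — the same engine the original analyses used — with
the package's own precondition checks (positive times, 0/1 events, at
least two groups, no constant covariates, separation and convergence
guards). The conventional multivariate model uses nodal status, ER
status, tumor size, and grade 3 versus 1/2 as covariates alongside the
subtype label.

# The synthetic cohort generator

`generateCohort` emulates a BAC-array-like breast-tumor cohort at desk
scale: 22 autosomes with realistic relative lengths tiled by 5,000
evenly spaced probes (~620-kb spacing, 100-kb footprints). Six archetypes
mirror the published genomic subtypes; cohort proportions
(67/51/105/46/52/38 of 359), hormone-receptor, grade, nodal and
BRCA-status compositions, and the hazard ordering (worst for the 17q12
archetype, best for luminal-simple) follow the published subtype
characterizations. Each sample plants its archetype's catalog events
(Bernoulli per event; the amplifier archetype draws 11q13.3 amplification
with probability 0.7 conditional on 8p12, its signature
coamplification), adds per-arm background aberrations, and i.i.d.
Gaussian probe noise (default sd 0.15). High-level amplicons draw
amplitudes with mean $\ge 1.4$ truncated at 1.1 so planted carriers are
detectable at the log2 $\ge 1$ definition. Survival times are
exponential with per-subtype hazards, censored administratively at 10
years (median follow-up in the motivating cohort was ~8 years) plus
uniform dropout. Expression is simulated as
$a \cdot (\text{local planted log2}) + \mathcal N(0, 0.2)$ for ten cis
genes per catalog region ($a = 1$) plus 200 unlinked noise genes.

Desk-scale choices worth knowing:

* **Focal amplicons span ~5 Mb** (17q12, 8p12, 11q13.3, 11q13.5, 8q24)
  so each covers at least 4 probes at the default resolution and
  survives the minimum-segment filter; on a real 32,000-clone array the
  same loci span dozens of clones.
* **Event probabilities are within-subtype frequencies of the defining
  events** (0.6–0.9), at the "frequent / predominantly characterized"
  level the subtype descriptions use. Archetypes must be recoverable by
  the pipeline's own clustering for end-to-end testing to mean anything;
  with markedly lower probabilities the planted partition is not
  recoverable even from noise-free truth, so failures would say nothing
  about the code.
* **Absolute FGA levels are not matched.** The catalog reproduces the
  *ordering* (basal-complex > luminal-complex > luminal-simple) and the
  qualitative architecture, not the published FGA percentages, which
  arise from full-genome aberration loads at 32k-probe resolution.
* **What passing tests do not show:** the generator draws events
  independently given the archetype, uses uniform per-event amplitudes,
  and has no intra-tumor heterogeneity, ploidy shifts, GC waves, or
  cell-type admixture. Recovery results on it validate the machinery,
  not performance on real arrays.

# Evaluation problem sizes

The test suite exercises: 50 noise-free profiles of 200 probes
(segmentation oracle); 50-sample × 2,000-probe pure-noise cohorts
(call specificity, and 20 replicates for type-I control of region
scoring); 60-sample cohorts with planted 15–35% events (power); 1,000
null genes at n = 100 with 100 permutations (dosage-correlation
calibration); one default 200-sample cohort run end to end (subtype
recovery, cis-gene pass rate, survival ordering); 200 replicates of
n = 500 (Cox interval coverage); and a 500-sample amplifier-only cohort
(coamplification convergence). These sizes were chosen as the smallest
at which the binomial/permutation tolerances in the checks are
meaningful.

# Known limitations

* The adaptive-threshold rule is a declared substitute for an
  unpublished derivation, not a reimplementation of it.
* Complete linkage is brittle to within-subtype outliers: because the
  published archetype definitions genuinely overlap (the amplifier's
  frequent +1q/+16p/−16q contains the whole luminal-simple signature;
  the mixed subtype's losses are close to a subset of
  luminal-complex's), the k = 6 cut occasionally merges such a pair on
  some cohort draws, and the adjusted Rand index fluctuates accordingly
  while the 17q12 cluster stays pure.
* Arm-level versus focal significance is not decomposed; later
  refinements of recurrent-aberration scoring (broad/focal separation,
  gene-level GISTIC2 statistics) are out of scope.
* Peel-off removes driver aberrations chromosome-wide, so secondary
  events on the same chromosome carried by the same samples are absorbed
  into the primary peak's extraction rather than reported separately.
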