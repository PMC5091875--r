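---
title: "Survival-guided cluster-of-clusters integration: methods and design"
author: "SurvCOCA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Survival-guided cluster-of-clusters integration: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Molecular subtyping of a heterogeneous tumour cohort — hepatocellular
carcinoma being the motivating case — asks for a partition of samples that
is supported jointly by several molecular platforms (copy-number variation,
DNA methylation, mRNA and miRNA expression) and that separates clinically
meaningful outcomes, above all survival. The cluster-of-clusters (COCA)
strategy integrates platforms at the level of *cluster memberships* rather
than raw features: each platform's features are grouped into sub-clusters,
each sub-cluster splits the samples into two groups, the binary membership
codes are stacked into one matrix, and the samples are clustered on that
matrix. The number of sub-clusters per platform controls how much each
platform contributes. SurvCOCA implements the survival-guided variant: the
per-platform sub-cluster counts are chosen by searching for combinations
whose integrated subgroups separate survival, and taking the most recurrent
counts among the significant combinations.

# The pipeline

## Per-platform preprocessing

Each platform is reduced to a feature-by-sample matrix of comparable,
variance-filtered features:

* **CNV** (`geneLevelCNV`): per gene and sample, the average of the log2
  segment means of all segments overlapping the gene interval, weighted by
  the number of bases each segment contributes (an unweighted mean over
  overlapping segments is available via `cnv_weighting = "unweighted"`;
  length weighting is the standard reading of "average score over the gene
  interval" and is robust to fragmented segmentation). Scores are clipped
  to [−2, 2] to blunt extreme values; genes lacking segment coverage in
  any sample are dropped; genes with across-sample SD ≤ 0.2 are removed.
* **Methylation** (`prepMethylation`): CpG sites with a missing beta value
  in any sample are removed; the 10000 sites with the highest SD are kept.
* **mRNA** (`prepExpression`): genes detected in every sample are log2
  transformed; values below −26 (including log2 of zero) are floored at
  −26; the 6000 highest-SD genes are kept.
* **miRNA** (`prepMirna`): log2 of reads-per-million, floored at 0; the 80
  highest-SD miRNAs are kept.

Numerical conventions: SD always uses the n−1 denominator; top-N selection
orders by descending SD with ties broken lexicographically by feature ID,
so repeated runs are bit-reproducible; the expression floors are applied as
replacements (a zero estimate maps directly to the floor, since log2(0) is
undefined). Coordinates are 1-based inclusive internally; BED gene models
are converted from 0-based half-open on read and chromosome names are
normalised by stripping a leading `chr`, so segment tables and gene models
from different sources join without off-by-one shifts.

## Sub-clustering and binarisation

`subclusterFeatures` groups a platform's features into k sub-clusters by
hierarchical clustering with correlation distance (1 − Pearson across
samples) and average linkage — the standard construction for co-varying
feature blocks; k-means is available as an option, with empty clusters
repaired by moving the farthest member of the largest cluster.

`indicatorFromSubcluster` splits the samples in two by Ward clustering
(Euclidean distance) on the member-feature submatrix. If either side has
fewer than `minGroupSize = 10` samples, the whole row becomes NA: such a
split is considered too unreliable to contribute. Otherwise the group with
the higher mean member-feature value is labelled 1. The orientation is
immaterial to downstream clustering (which is label-symmetric) but a fixed
deterministic rule is needed for reproducibility. The split is invariant
to sample order and to positive rescaling of the features.

`assembleCOCMatrix` stacks the rows in platform order (CNV, mRNA, miRNA,
methylation) and sub-cluster index. All-NA rows are retained: they carry
no information, but keep the row count equal to the sum of the
per-platform sub-cluster counts.

## Consensus clustering

`consensusCluster` resamples a fraction (default 0.8) of the samples
(default 1000 repetitions; desk-scale analyses in this package's tests use
25–100), clusters each subsample into k groups by average-linkage
hierarchical clustering on an NA-tolerant binary distance — the fraction of
mismatching indicator rows among rows observed for both samples — and
accumulates co-clustering frequencies. With `sampleFraction = 1` the
procedure degenerates to a single deterministic partition and the
consensus matrix is exactly its 0/1 co-membership matrix, which the test
suite exploits as an oracle. Sample pairs never co-sampled get consensus 0
with a warning (a sign that `reps` is too low); pairs sharing no observed
indicator row get the uninformative midpoint distance 0.5. Final labels
come from average-linkage clustering of 1 − consensus.

## Choosing the number of subgroups

For each candidate k the area A(k) under the empirical CDF of the
off-diagonal consensus entries is computed; A(k) grows as entries move
away from 1. `selectKDeltaArea` forms the delta-area curve
Δ(2) = A(2), Δ(k) = (A(k) − A(k−1)) / A(2) and returns the largest k with
Δ(k) above the stability threshold (default 0.05), provided the curve has
flattened by the end of the candidate range.

Two design points deserve emphasis:

* **Fixed-reference normalisation.** The conventional delta-area plot
  divides by A(k−1). Because A grows towards its ceiling as k increases,
  that normalisation shrinks late gains mechanically: separating the two
  smallest of five unequal subgroups adds only a few percent *relative to
  the grown denominator*, indistinguishable from the spurious gains
  produced by re-splitting clean clusters. Dividing by the fixed A(2)
  treats all k comparably; empirically the true-k gains then exceed 0.05
  by a comfortable margin while spurious gains stay an order of magnitude
  below it.
* **The flattening guard.** An elbow is only declared if the final
  delta-area is itself below the threshold. For structureless data the
  area curve climbs throughout the range — every extra cluster keeps
  reshuffling samples — and no elbow exists; the minimum k is returned
  with an instability warning rather than an arbitrary large k.

The proportion-of-ambiguous-clustering statistic was considered as an
alternative selector and rejected: over-splitting a large homogeneous
cluster tends to shave off near-deterministic singletons, which looks
"stable" to an ambiguity measure while inflating k.

## Survival scoring and the grid search

`logrankTest` implements the k-sample log-rank chi-square (df = k − 1)
with the standard hypergeometric variance correction for tied event
times; it agrees with the classical two-sample statistic on two groups
and with an independent risk-table enumeration on arbitrary inputs, and
`kmEstimate` wraps the product-limit estimator. `survivalGuidedGridSearch`
evaluates combinations of per-platform sub-cluster counts (defaults: 2–15
for CNV, mRNA and methylation, 2–7 for miRNA, subgroup counts 2–7),
either exhaustively or over a seeded random subsample of the grid
(`budget`), caching sub-cluster assignments and indicators per
(platform, k) so the grid reuses them. Each combination is
consensus-clustered at every candidate subgroup count and scored by the
log-rank p-value; combinations below the 0.05 threshold are flagged
significant. No multiple-testing correction is applied by default — the
selection step consumes recurrence, not inference — but a
Benjamini–Hochberg flag is available.

Classifications containing a subgroup smaller than `min_group_size` are
recorded as untested (`logrank_p = NA`): a subgroup below the minimum
split size is not a usable subtyping, and near-empty groups invalidate
the chi-square approximation of the log-rank test — under a global null,
degenerate three-sample subgroups otherwise produce spuriously extreme
p-values and a severely inflated false-positive fraction. This extends
the minimum-group-size principle already governing the binarisation step
to the scoring step.

`recurrenceModeSelect` takes, per platform independently, the modal
sub-cluster count among significant grid points (ties resolved toward
the smaller count, and reported). Per-platform recurrence — rather than
recurrence of joint 4-tuples — is used because the grid is sparse in
four dimensions and joint recurrence is rarely informative at realistic
budgets. `finalizeSubgroups` then rebuilds the matrix at the selected
counts, consensus-clusters over the subgroup range and applies the
delta-area elbow. `loocvAccuracy` validates the final classification by
leave-one-out nearest-centroid reassignment on the indicator matrix
(NA-tolerant mean absolute difference; singleton subgroups are skipped
with the denominator adjusted): the minimal classifier consistent with
binary indicator features.

## Subgroup characterisation

`associationTest` cross-tabulates subgroup labels against categorical
covariates (Fisher's exact test by default, safer for small cells;
chi-square optional). `subgroupProportions` reports the percentage of a
covariate level within a set of subgroups, keeping both the unrounded
value and the rounded integer used in report displays.
`featureAUCOneVsRest` ranks biomarkers by the ROC AUC of a feature
separating one subgroup from the rest, computed through the Mann–Whitney
identity with ties counting 1/2; the direction-free field
max(AUC, 1 − AUC) covers markers distinguishing a subgroup by low
values. `subgroupSignatureTable` screens features per platform and
subgroup by rank-sum tests with Benjamini–Hochberg adjustment.

# The synthetic study

`simulateMultiomics` generates the conditions the pipeline assumes so
every stage can be exercised without any external download: 250 samples
in five subgroups of unequal proportions (0.12, 0.32, 0.26, 0.18, 0.12,
mirroring the skewed subgroup sizes typical of real cohorts), four
block-structured platforms in which each feature block shifts a subset of
subgroups by 2 total-SD units, subgroup-specific exponential survival
spanning a 4-fold hazard ratio with 30% censoring, two enriched mutation
genes per subgroup, and subgroup-biased clinical covariates (gender,
alcohol, AFP class, tumour stage). The first block of every platform
marks exactly one subgroup, guaranteeing identifiability; later blocks
shift random subsets. CNV is emitted as per-sample segment records over
a bundled gene model (two segments per block region), so the
genomic-overlap averaging path is covered; methylation passes through a
logistic squash to keep beta-value range semantics; mRNA and miRNA are
emitted on the linear scale so the log2/floor rules apply. A small
fraction of cells (2%) is set missing to exercise the NA-handling rules.
Everything is a deterministic function of the configuration seed.

The generator emulates block-correlated features, planted subgroups,
survival contrasts and covariate biases. It does **not** attempt real
marginal distributions (beta-mixture methylation, heavy-tailed
expression), platform-specific noise, batch structure, or realistic
linkage between platforms beyond the shared subgroup labels — so passing
recovery tests demonstrates correctness of the machinery under its
stated assumptions, not performance on any particular real cohort.
Exponential survival was chosen for closed-form hazard control; the
censoring rate is tuned exactly via the exponential-censoring identity.

# Problem sizes and determinism

The test suite and the acceptance script run the full pipeline at
deliberately modest sizes — 60–250 samples, 8–10 blocks per platform,
consensus repetitions 25–100, grid budgets of 6–25 combinations — which
this package treats as its reference desk-scale conditions; all defaults
scale up unchanged. Every stochastic step (grid subsampling, consensus
resampling, the generator) is driven by explicit integer seeds through
`withr::with_seed`, so identical inputs give bit-identical outputs.

# Known limitations

* The two-group split within a sub-cluster is strictly binary; finer
  within-platform structure is only expressible through more
  sub-clusters.
* Consensus clustering with average linkage can produce unbalanced
  groups on weakly structured data; the minimum-group-size rule converts
  such runs into untested grid points rather than repairing them.
* The delta-area elbow cannot certify a k at the very end of the
  candidate range (the flattening guard needs room to observe the
  plateau); widen `subgroup_range` if the expected k is near its edge.
* P-values from the grid search are selection-biased by construction;
  they guide recurrence-based model selection and are not confirmatory
  inference.
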