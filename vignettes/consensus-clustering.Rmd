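---
title: "Cross-dataset consensus clustering of erythroid time courses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-dataset consensus clustering of erythroid time courses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erythroclust)
```

## The problem

Erythroid differentiation can be driven in culture from several progenitor
sources — adult peripheral-blood CD34+ cells, cord-blood CD34+ cells, and
human induced pluripotent stem cells (hiPSC) — and profiled as a time course
of sorted cell populations. The analytical question this package addresses
is: *which genes are co-ordinately regulated in the same way in every
source?* Genes that co-express consistently across all three datasets point
at the core erythroid program; genes that cluster in only one source mark
source-specific (e.g. hiPSC-aberrant) regulation.

The design this package targets has three datasets over a common gene
universe, with 11 population points for adult blood, 3 for cord blood and 3
for hiPSC, each measured in three biological replicates on linear-scale
intensity arrays. Replicates are collapsed to per-population medians before
clustering.

## The pipeline

`run_pipeline()` chains the stages:

1. **Control-gene normalisation.** Each sample is rescaled so the geometric
   mean of two stably expressed control genes (ACTB and PAFAH1B2) equals
   their grand geometric mean across samples. The scheme is symmetric in
   the controls, scale-equivariant, and idempotent. Because the anchor is
   the observed grand mean, rescaling a single corrupted sample is undone
   exactly up to one predictable global factor (the grand mean itself moves
   by the n-th root of the corruption); relative expression is restored
   exactly.
2. **Expression filter.** A gene is kept if it reaches a minimum linear
   intensity (default 100) in *all* replicates of *at least one*
   population. The boundary is inclusive.
3. **Differential expression.** Empirical-Bayes moderated two-group
   statistics on log2 intensities (next section), selected with the joint
   rule p ≤ 0.01, linear fold change ≥ 2, B > 2.945, over every unordered
   pair of populations; the union over pairs defines each dataset's DE
   genes.
4. **SMART × 100.** Each dataset's DE-gene population profiles are
   clustered 100 times with a tunable split-merge algorithm (below), seeds
   `seed_base .. seed_base + 99`.
5. **Bi-CoPaM.** The 100 crisp partitions are label-aligned and averaged
   into a fuzzy consensus partition matrix (CoPaM), then binarised with the
   difference-threshold rule at δ = 0: each gene is assigned to its unique
   maximum-membership cluster, or to none on an exact tie.
6. **Bimax.** The three binary membership matrices are concatenated
   column-wise and all inclusion-maximal all-ones submatrices with at least
   3 columns (= number of datasets) are enumerated exactly. Because δ = 0
   allows at most one 1 per gene per dataset, every such bicluster uses
   exactly one cluster column from each dataset: its genes co-express
   consistently everywhere.
7. **Size filter.** Clusters with more than 30 genes (strictly) are
   reported as the headline result; smaller ones are retained upstream.

## The moderated statistics

For a two-group comparison with `n_a`/`n_b` replicates the per-gene model is
the pooled-variance linear model on log2 intensities: effect `b` (log2 fold
change), residual variance `s²` on `d_g = n_a + n_b − 2` degrees of freedom.
Variances are assumed exchangeable across genes with a scaled
inverse-chi-square prior `(d₀, s₀²)`, estimated by moment-matching of
`log s²` (the excess of its variance over `trigamma(d_g/2)` identifies `d₀`
through the trigamma inverse; when the excess is non-positive `d₀ = ∞` and
`s₀²` is the mean sample variance). The posterior variance

`s̃² = (d₀·s₀² + d_g·s²) / (d₀ + d_g)`

is a convex combination of prior and sample variance; the moderated
`t = b / (s̃·√(1/n_a + 1/n_b))` has `d₀ + d_g` degrees of freedom. The
log-odds statistic B assumes a two-component mixture in which a proportion
`p_de` (default 0.01) of genes are differentially expressed with prior
fold-change variance `v₀`, estimated from the upper tail of the |t|
distribution; B > 2.945 = ln 19 then corresponds to a posterior probability
of differential expression above 0.95. Setting `prior_df = 0` recovers the
classical two-sample t exactly, which the test suite exploits as an oracle;
the full moderated path is cross-checked against an independent
empirical-Bayes implementation (limma) when available. Zero-variance genes
are floored at a small epsilon (`var_floor = 1e-8`) before shrinkage so
degenerate synthetic input cannot produce infinite t. No multiple-testing
correction is applied: the selection rule is a joint raw-p / fold-change /
log-odds filter, and the type-I calibration of the raw p-values is itself
under test.

## The SMART instantiation

SMART is cited in the literature as a tunable split-merge clusterer with
stochastic restarts and no data-dependent parameters; published accounts
leave the split criterion open, so the concrete instantiation here is a
design choice of this package:

* Profiles are log2-transformed and row-standardized, so Euclidean
  geometry on rows equals Pearson-correlation geometry — *shape*, not
  level, defines co-expression.
* Start from one cluster. Repeatedly take the cluster with the largest
  within-cluster dispersion (total squared distance to its centroid; ties
  broken by lowest index), bisect it with a seeded 2-means, and keep the
  split only if the cluster's projection onto the axis joining the two
  child centroids is detectably non-Gaussian (Anderson–Darling test,
  `split_alpha = 1e-3`). This is the Gaussian-projection splitting idea
  familiar from G-means: a well-separated mixture rejects strongly, while
  a homogeneous noise cluster does not, keeping k data-driven without a
  user-set cluster number. Clusters below 8 members are never split (the
  test needs enough points).
* Merge phase: repeatedly join the pair of clusters whose centroids have
  the highest Pearson correlation, while it is ≥ 0.9, capped at 10 merges
  per run.
* Labels are renumbered by smallest member index, so a partition is a
  deterministic function of (profiles, seed).

The per-run stochasticity (k-means initialisation) is exactly what the
consensus stage feeds on: 100 runs differ in their mistakes but agree on
robust structure.

## Bi-CoPaM details

Cluster labels are arbitrary, so before averaging, every partition is
(a) canonically relabelled by smallest member index and (b) mapped onto the
first run's labels by maximum-overlap one-to-one matching, solved exactly
as a linear assignment problem (an in-package O(K³) Hungarian solver;
partitions with fewer clusters are padded with empty ones). The canonical
relabelling makes the result provably invariant to the labels the clusterer
happened to emit even when overlap ties make the assignment non-unique.
The CoPaM is the element-wise mean of the aligned 0/1 matrices: rows sum to
1 and entries are multiples of 1/n_runs. Binarisation at δ = 0 assigns each
gene to its maximum-membership column when the gap to the second-largest
membership exceeds δ (with a 1e-12 comparison tolerance); exact ties
unassign the gene rather than picking arbitrarily, preserving "one cluster
per gene" without a hidden coin flip. Raising δ never assigns a
previously-unassigned gene.

## Bimax details

Maximal all-ones submatrices are in one-to-one correspondence with closed
column sets (a column set C with support R = all rows covering C, such that
no further column is all-ones over R). The implementation enumerates closed
sets depth-first with prefix-preserving closure extension, which visits
each closed set exactly once, then orders output lexicographically by
column set and row set. This is exact — the property suite checks set
equality against brute-force enumeration over all column subsets on
hundreds of random matrices up to 12×8 — and fast at this problem's scale,
where each gene carries at most one 1 per dataset. `min_rows` defaults to 2
(a "cluster" of one gene is not a cluster); the >30-gene filter is applied
afterwards as a separate, visible step. Consensus cluster numbering is
deterministic but arbitrary; it carries no meaning across runs or datasets.

## The synthetic-data generator

`simulate_datasets()` emulates the three-source study design so that every
stage is testable without the original arrays: a common gene universe;
11/3/3 population points; 3 replicates per population; planted
co-expression clusters that are either shared by all datasets or specific
to one; two constant high-intensity control genes; a floor of non-expressed
genes below the expression filter; and additive Gaussian noise on log2
intensities (multiplicative log-normal on the linear scale — the microarray
convention, and it makes the FC ≥ 2 filter analytically controllable).

Cluster templates are smooth shape functions over pseudotime (up, down,
peak, dip, late-up, early-down), sampled at each dataset's population
count, scaled to an amplitude of 2 log2 units (4-fold swings) on a baseline
of 2⁹. The shapes are chosen so that any two standardized templates
correlate below the 0.9 merge threshold even at only 3 population points —
the minimum resolution of the cord/hiPSC designs. Published work gives no
noise magnitudes or cluster sizes; the defaults (500 genes, 4 shared + 2
specific clusters of 40 genes, log2 noise sd 0.25, floor intensity 50) are
calibration choices of this package: 0.25 is a realistic replicate CV for
modern arrays and leaves the planted 4-fold swings comfortably but not
trivially detectable.

What the generator does **not** emulate: probe-level effects, spatial
artifacts, batch effects, correlated noise between genes, heavy-tailed
outliers, or realistic gene-gene correlation outside the planted clusters.
Passing the recovery tests therefore demonstrates that the machinery is
correct and calibrated under the stated model, not that it is robust to
every pathology of real arrays.

## Numerical choices and degenerate inputs

* Membership comparisons use an absolute tolerance of 1e-12; CoPaM row
  sums are exact to 1e-9.
* All-identical profiles cluster to k = 1; zero-variance (flat) genes
  standardize to the zero vector.
* Dispersion ties in the split queue break to the lowest cluster index;
  assignment-problem ties break deterministically by index through the
  Hungarian sweep order, and are made irrelevant to the output by the
  canonical pre-relabelling.
* Cluster indices are 1-based and contiguous with no empty clusters.
* Every stochastic step takes an explicit integer seed; the pipeline
  derives per-run seeds as `seed + (dataset-1)·n_runs + run-1`.

## Problem sizes used in the checks

The validation suite runs the full study-shaped configuration — 500 genes,
three datasets (11/3/3 populations × 3 replicates), 100 SMART runs per
dataset, five independent seeds — which completes in well under a minute
per seed; unit tests use smaller ensembles (25–40 runs, 100–360 genes) to
keep the suite fast. Null-calibration checks use 2000 flat genes. These
sizes are the package's own validation choices and can be scaled up freely.

## Known limitations

* The SMART split criterion is this package's instantiation of an
  under-documented algorithm; other instantiations would give different
  (also valid) ensembles. The consensus stage is deliberately robust to
  such per-run variation.
* Only the difference-threshold (max-membership) binarisation variant is
  implemented; union/intersection variants of Bi-CoPaM are not.
* The moderated model covers two-group contrasts, matching the
  pairwise-stages selection rule; multi-factor designs, array weights and
  FDR control are out of scope.
* Consensus cluster numbers are reproducible under a fixed seed but
  arbitrary as names; they cannot be mapped onto any external cluster
  numbering without the original data.

## A worked micro-example

```{r example}
sim <- simulate_datasets(simulation_config(
  n_genes = 260, n_clusters_shared = 2, n_clusters_specific = 1,
  cluster_size = 40, noise_sd_log2 = 0.25, seed = 1))
res <- run_pipeline(sim$datasets,
                    pipeline_config(smart = smart_config(n_runs = 30),
                                    seed = 1))
lengths(res$consensus_clusters)
res$manifest$counts$de_genes
```

The two planted shared clusters come back as the two large consensus
clusters; the dataset-specific clusters are clustered within their own
dataset but, lacking partners in the other two, cannot form a 3-column
bicluster and are absent from the consensus output.
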