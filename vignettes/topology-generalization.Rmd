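---
title: "Feature-space topology and the generalization of molecular machine learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feature-space topology and the generalization of molecular machine learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(topogen)
```

## The problem

Choosing a molecular representation (a fingerprint, a descriptor table, a
learned embedding) is one of the strongest levers on QSAR model quality,
yet it is usually settled by brute-force benchmarking. `topogen` starts
from a different premise: a representation is a point cloud in
$\mathbb{R}^d$, and the *shape* of that cloud — how its points cluster,
how many cycles its neighborhood graph carries, how many directions its
local neighborhoods occupy — carries information about how well a
regressor will generalize on it. The package computes those shape
summaries, computes classical QSAR activity-landscape baselines, runs a
controlled model benchmark, and fits a meta-model that predicts the
normalized test error of a (dataset, representation, size, split)
configuration from the shape summaries alone.

## Persistent homology of a representation

For a feature matrix $X = \{x_1, \dots, x_N\} \subset \mathbb{R}^d$ and a
metric $\rho$, the Vietoris–Rips complex at scale $\varepsilon$ contains
every simplex whose vertices are pairwise within $\varepsilon$. Growing
$\varepsilon$ yields a filtration; persistent homology tracks when
connected components ($H_0$) and cycles ($H_1$) are born and die, giving
a multiset of intervals $(b, d)$ per homological dimension.

`vr_persistence()` computes these intervals exactly for dimensions 0 and
1 from a dense distance matrix:

* dimension 0 by a union-find pass over the sorted edges — the deaths are
  the minimum-spanning-forest edge weights (`mst_deaths()` exposes this
  directly);
* dimension 1 by the dual (persistent cohomology) reduction with
  clearing: spanning-forest edges are skipped, the remaining edges are
  processed in decreasing filtration order as mod-2 coboundary columns
  over their cofacet triangles, and each reduced column pairs its pivot
  triangle with the edge. This is the standard fast scheme for
  Vietoris–Rips filtrations; the test suite checks it *exactly* (all
  intervals, both metrics) against an independent brute-force
  boundary-matrix reduction over every simplex of dimension $\le 2$.

Conventions: coefficients are mod 2; ties in edge weights break
lexicographically, so diagrams are deterministic; the single infinite
$[0, \infty]$ component of the full filtration is removed, as are
zero-length intervals (they carry no persistence and would break the
normalized-lifetime division). Consequently a duplicate-free cloud yields
exactly $N - 1$ finite $H_0$ bars, which makes the 0-dimensional Betti
number a proxy for sample size — a feature, not a bug, because sample
size is one of the quantities the meta-model must see.

`compute_descriptors()` turns a diagram into the scalar descriptor
vector: per dimension the Betti number and its $n$-normalized variant,
the five aggregates (min, max, mean, population sd, sum) of lifetimes
$\Delta_j = d_j - b_j$, of midlifes $\mu_j = (b_j + d_j)/2$, and of their
sum-normalized variants $p_j$ and $\nu_j$, and the persistence entropy
$E = -\sum_j p_j \log p_j$ (natural log, matching the persistence-entropy
literature). A dimension with no intervals propagates `NA` — "no
topological signal" is information the meta-model handles downstream, not
an error.

## Intrinsic dimension

Three estimators complement the diagram statistics:

* **Persistence dimension** (`ph_dimension()`): subsample $n$ points for
  a grid of sizes (default $100, 150, \dots, 2000$, one seeded draw per
  size), compute the $\alpha$-weighted total persistence
  $E^\alpha = \sum (d - b)^\alpha$ with $\alpha = 1$, and regress
  $\log E^\alpha$ on $\log n$; the estimate is $\alpha / (1 - m)$ for
  slope $m$. A slope $\ge 1$ or an all-zero $E^\alpha$ marks a degenerate
  geometry and returns `NA` with diagnostics rather than a number.
* **TwoNN** (`twonn_dimension()`): the ratio $\mu = r_2 / r_1$ of each
  point's two nearest-neighbor distances follows a Pareto law with shape
  equal to the intrinsic dimension; the estimate is the origin-anchored
  least-squares slope of $-\log(1 - F(\mu))$ on $\log \mu$, after
  discarding the top 10% of ratios (the standard prescription — the tail
  is noise-dominated). Duplicate rows make $r_1 = 0$ and are rejected by
  id, because the ratio is undefined there.
* **Local PCA** (`lpca_dimension()`): for each point, count the
  covariance eigenvalues of its $k$ nearest neighbors (default
  $k = 100$, capped at $n - 1$) exceeding 5% of the leading eigenvalue,
  and average the counts. The per-neighborhood (rather than global)
  reading follows the local-region eigenvalue construction; it is exact
  on noiseless embedded flats.

## Activity-landscape baselines

For a labelled dataset $(X, y)$ the package computes the classical
roughness/modelability indices, each behind its own function:

* **SALI**: $\mathrm{SALI}_{ij} = |y_i - y_j| / (1 - \mathrm{sim}(i,j))$.
  Pairs at similarity 1 are masked and counted rather than propagating
  `NaN`; summaries are over unmasked pairs. The default similarity is
  Tanimoto for binary fingerprints and $1/(1+\text{euclidean})$
  otherwise.
* **SARI**: continuity (potency-weighted mean similarity below the 0.65
  similarity threshold) and discontinuity (mean $|\Delta y|$ at or above
  it) combined as $(\mathrm{cont} + (1 - \mathrm{disc}))/2 \in [0, 1]$.
  For a single dataset the discontinuity score is scaled by the label
  range; `sari_batch()` instead min–max normalizes the raw scores within
  a batch of datasets, replacing the original reference-panel z-scoring,
  which needs a reference panel this package does not assume.
* **RMODI**: the fraction of molecules whose nearest neighbor is
  label-similar, via the rivality-style rule
  $RI_i = |y_i - y_{nn(i)}| / \mathrm{range}(y) - 0.1 < 0$. Constant
  labels give 1 (every neighbor trivially similar) with a warning.
* **ROGI / ROGI-XD**: the dispersion loss
  $\int_0^1 2(\sigma_0 - \sigma_t)\,dt$ under progressive complete-linkage
  coarse-graining, with labels replaced by cluster means and $\sigma$ the
  population sd of the coarse-grained vector. The classic variant
  normalizes distances by their maximum and cuts at threshold $t$; the XD
  variant traverses the merge sequence by cluster count with
  $t = 1 - (k-1)/(n-1)$, removing the distance-scale and dimensionality
  dependence. Clustering is delegated to `stats::hclust`, whose merge
  order is deterministic for a fixed input.

## The benchmark and error normalization

`train_eval()` trains one of two model families per configuration — a
`ranger` random forest (grid: 100/500 trees $\times$ unlimited/depth-10)
and a single-hidden-layer `nnet` network with standardized inputs (grid:
16/64 hidden units $\times$ weight decay $10^{-4}/10^{-3}$) — selecting
hyperparameters by 5-fold cross-validated RMSE on the training side and
reporting held-out RMSE, MAE and $R^2$. The neural grid uses single-layer
widths because that is the family the chosen backend supports; it
exercises the same selection machinery. `make_split()` provides seeded
random and group (scaffold-style) holdouts, the latter guaranteeing that
no group spans both sides. `normalize_errors()` maps each error within a
batch to $[0,1]$ by min–max; batches default to datasets, and the planted
benchmark normalizes within (dataset $\times$ split scheme) because each
splitting strategy constitutes its own benchmark table.

## The planted meta-benchmark

Real corpora and pretrained embeddings are out of scope, so
`make_meta_benchmark()` builds the entire study as a seeded synthetic
object whose ground truth is known:

* **Datasets** (default 8) cycle through geometries (unit squares/cubes,
  Gaussian blobs, a 4-cube) and a roughness ladder of planted cliff
  fractions $0, \dots, 0.24$. Labels are a smooth radial sinusoid
  $\cos(\pi r / r_{\max})$ (Lipschitz constant $\pi / r_{\max}$) plus
  Gaussian noise (sd 0.05), with a *spatially clustered* cliff region
  whose labels are offset by three times the base range. Clustered (not
  scattered) cliffs are deliberate: independently scattered cliffs are
  irreducible noise for every regressor, so representation quality would
  not modulate their error — empirically, distorted representations then
  smooth over them and the planted quality ladder cancels. A coherent
  cliff region, like real scaffold-driven activity cliffs, is learnable
  exactly to the extent that the representation is faithful, which is the
  association the meta-model exists to detect. `make_landscape()` keeps
  scattered cliffs as its default mode for the modelability fixtures,
  where unpredictability is the point.
* **Representations** (default 6 per dataset) re-encode the same
  molecules under a convex distortion ladder — Gaussian coordinate noise
  with sd $0.7\,t^{1.3}$ ($t \in [0,1]$) of the coordinate scale, plus
  $3(j-1)$ pure-noise dimensions — so within every dataset the realized
  error rises with distortion while lifetimes, Betti statistics and
  dimension estimates shift with it.
* **Evaluation** holds out one fixed 20% test set per (dataset, split
  scheme) and grows only the training pool across the two sample sizes
  (150, 300). A fixed holdout keeps the quality ladder visible: resampling
  the test set at every size would inject cliff-sampling noise larger
  than the representation effect itself.

Descriptor vectors (`representation_descriptors()`) are computed per
(dataset, representation, size) on the same subsample the models see,
with the persistence-dimension size grid scaled to 40–100% of $n$.

## TopoLearn-style meta-modelling

`assemble_meta()` joins run records with descriptor vectors into
$(X_t, y_t)$ with $y_t$ the normalized RMSE; the `PH` feature set carries
only topological descriptors and dimension estimates, while `C` adds
controls (sample size, dimensionality, one-hot split scheme, model
family, hyperparameters) for analysis. Missing descriptor values are
encoded as a sentinel below the observed minimum plus a per-feature
indicator column — an explicit mechanism for the forest rather than an
assumption of native missing-value support. `fit_meta()` trains a random
forest (300 trees; depth and leaf-size grid by internal 5-fold CV) and
clips all predictions to $[0, 1]$, since the target lives there by
construction. `leave_one_out_cv()` implements LODO-CV (hold out each
dataset) and LORO-CV (hold out each representation), reporting per-fold
Pearson $r$, their mean and sd ($r_{cv}$), the correlation over pooled
holdout predictions ($r_a$), impurity-based feature importances averaged
over folds, and the exact fold index partition for leakage audits.
`correlation_screen()` gives the univariate Pearson/Spearman view with
two-tailed p-values, uncorrected, as a screening table.

## Problem sizes and what the tests show

The shipped test-suite and acceptance script run the pipeline at desk
scale, chosen so each stage still has a known ground truth: persistence
is verified exactly against the brute-force oracle at $n \le 25$;
topology recovery uses a noisy circle at $n = 100$; dimension recovery
uses $n = 2000$ clouds; the meta-benchmark uses 8 datasets $\times$ 6
representations at $n = 300$ with 3 seeds, roughly 190 meta-rows. On
that benchmark, LODO $r_{cv}$ lands around 0.7–0.85 while the same
pipeline on permutation-shuffled targets gives $|r_a| < 0.15$ — the
planted topology–error association, not the pipeline, carries the
signal. Two caveats delimit what this shows: the generators produce
low-dimensional manifolds plus noise, not the heavy-tailed, highly
anisotropic clouds of real fingerprints and embeddings; and the
representation ladder varies a single distortion axis, whereas real
representations differ in many coupled ways. Passing here demonstrates
correctness of the machinery and recoverability of a planted signal, not
transfer to any particular chemical corpus.

## Numerical and degenerate-input conventions

* Distances: Jaccard requires strictly binary matrices; all-zero bit
  row pairs are defined as distance 0 with a warning; cosine pairs with a
  zero-norm row get distance 1 (0 for two zero rows) with a warning.
* Diagrams: `threshold = NULL` means the full filtration; with a finite
  threshold, essential classes become infinite bars and are dropped at
  finalization.
* `ph_dimension` needs at least 4 usable sizes; degenerate geometry
  (slope $\ge 1$, all-zero persistence) yields `NA` plus a flag.
* Constant labels: RMODI is 1 with a warning, ROGI is 0, SALI summaries
  are 0; constant training labels make $R^2$ `NA` with a warning.
* Tied raw errors in a normalization batch map to 0 with a warning.
* Every stochastic step (generators, subsampling, splits, model fits)
  derives its stream from an explicit integer seed; regeneration equality
  is asserted in the tests.

## Known limitations

* Homology stops at dimension 1; no sparse or approximate filtrations,
  landscapes, or persistence images.
* The dense reduction targets clouds up to a few hundred points per
  diagram (the benchmark's scale); thousands of points per diagram would
  need an approximate backend.
* SARI's reference-panel normalization is replaced by single-dataset or
  within-batch normalization; only orderings across representations
  should be interpreted.
* The rivality index is a behavioral reconstruction with one explicit
  tolerance, not a reimplementation of the original algorithm.
* LORO-CV on the planted benchmark is structurally easy (representations
  share the distortion ladder); its honest use is the leakage audit and
  fold accounting, not a transfer claim.
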