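---
title: "Pattern recognition in binary cytogenetic LGF matrices: methods and design"
author: "cytopattern"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pattern recognition in binary cytogenetic LGF matrices: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytopattern)
```

## The problem

A patient karyotype can be encoded as a binary vector over cytogenetic
bands: for each band, three indicator features record whether the band is
involved in a Loss, a Gain, or a Fusion (the LGF model). A cohort becomes
a sparse samples-by-features 0/1 matrix. Whole-chromosome and whole-arm
events switch dozens of adjacent band features on together, so the
columns are heavily redundant; most cells are zero because any one tumor
carries few aberrations relative to the full band catalogue.

`cytopattern` finds and characterizes the recurrent aberration patterns
in such a matrix: which karyotypes form clusters, how many clusters a
principled dimension argument supports, which features co-occur as
elementary cytogenetic events, and how strongly each event characterizes
each cluster.

## Distances on binary profiles

Every metric is a function of the 2x2 contingency counts
$(N_{11}, N_{10}, N_{01}, N_{00})$ of a pair of 0/1 vectors. The primary
metric is the Jaccard distance

$$d_J = 1 - \frac{N_{11}}{N_{11} + N_{10} + N_{01}},$$

which ignores 0-0 matches -- two karyotypes are similar because of the
aberrations they share, not because of the thousands of bands both leave
untouched. Nine companion metrics (Sokal-Michener, Hamming, Russell-Rao,
Pearson, Goodman-Kruskal, Manhattan, Canberra, Binary, Euclidean) follow
the standard binary-similarity survey conventions and are available
through the same `metric` argument everywhere, so the sensitivity of any
result to the metric is one function call away (`compareMetrics()`).

Degenerate denominators are pinned explicitly: two all-zero vectors are
at Jaccard/Binary distance 0; the Pearson distance with a zero marginal
is 0 for equal vectors and 1 otherwise; Goodman-Kruskal with
$2n = \sigma'$ is 0. One deliberate asymmetry: the Russell-Rao formula
$1 - N_{11}/n$ is kept as printed, so it is nonzero even on identical
vectors unless they are all ones; the pairwise-matrix layer forces the
diagonal to zero, which is the invariant downstream methods rely on.

## Feature reduction

`dropEmpty()` removes all-zero features; `collapseDuplicates()` merges
features whose columns are identical across the whole cohort, keeping
the first header as representative and a `DedupMap` for provenance.
Reports show a representative as e.g. `1p1.L.x8` so a collapsed
whole-arm event remains visible. Distances downstream are computed on
the reduced, unweighted matrix; an expanded report can always recover
the full band list through the map.

`thresherFilter()` then removes uninformative "outlier" features: on the
correlation-scaled matrix, feature $j$ is scored by the length of its
loading vector on the top $q$ principal components,
$\sqrt{\sum_{k \le q} l_k v_{jk}^2} \in [0, 1]$, and features below
`delta = 0.3` are dropped. Both the cutoff and the standardization are
configurable; standardization is the default because prevalence
differences between rare and common aberrations would otherwise dominate
the loadings.

## How many components, how many clusters

The cluster count is tied to the number of significant principal
components of the (column-mean-centered) matrix, computed through the
singular values for stability; eigenvalues below $10^{-12} l_1$ are
treated as zero.

Two rules are implemented:

* **Broken stick**: keep the largest $q$ such that each of the first $q$
  variance proportions exceeds the expected ordered fragment lengths
  $b_k = \frac1d \sum_{i=k}^d 1/i$ of a randomly broken unit stick.
* **Auer-Gervini**: place an exponential prior with rate $\theta$ on the
  component count; the MAP dimension
  $q^*(\theta) = \arg\max_q [L(q) - \theta q]$, with $L$ the profile
  log-likelihood under an isotropic residual, is a non-increasing step
  function of $\theta$. It is computed exactly from the upper convex hull
  of $\{(q, L(q))\}$ -- the breakpoints are the chord slopes -- rather
  than by grid search; a dense-grid evaluation is retained as an oracle
  in the tests. "Long" steps, wider than twice the mean step length, mark
  dimensions that stay optimal over a wide prior range.

When several long steps exist the default picks the **smallest** such
candidate. This is a genuine design choice: the step function typically
shows one long step near the between-cluster dimension and another near
the finer within-cluster event structure, and published analyses of this
kind have chosen among long steps by hand. Parsimony is the defensible
automatic default, and `criterion = "manual"` reproduces any pinned
choice exactly.

The **feature axis** asks a different question -- how many distinct
co-occurrence directions rise above random variance fragmentation -- and
there the broken-stick rule on the correlation-scaled transposed matrix
is the default (`clusterFeatures()`). On synthetic cohorts the
twice-mean rule on the feature axis locks onto the sample-cluster
structure (a handful of dominant eigenvalues) and under-counts the
planted events, while the broken stick counts them stably; this is
documented behavior, not an accident, and both criteria remain
selectable.

## Clustering

`pamCluster()` is a deterministic BUILD+SWAP partitioning around
medoids: BUILD seeds with the object minimizing total distance and
greedily adds the best cost reducer; SWAP repeatedly applies the single
best-improving medoid/non-medoid exchange. All ties break toward the
lowest object index, so runs are bit-reproducible with no random
restarts. Silhouette widths use the usual $(b-a)/\max(a,b)$ with
singletons scored 0.

A known limitation, measured rather than hidden: best-improvement
BUILD+SWAP is a local search over the 1-swap neighborhood. On a few
percent of small random instances it terminates in a swap-local optimum
that is not the global medoid optimum, and the canonical reference
implementation of PAM returns the identical configuration on such
instances. The tests therefore assert swap-local optimality exhaustively
(no single exchange can improve the final cost) plus global-optimum
attainment on the large majority of small instances, not on all of them.

Cluster ids from different runs or algorithms are arbitrary;
`alignLabels()` matches two partitions by Hungarian assignment on their
contingency table (greedy matching above 500 clusters), and
`makePalette()`/`recolor()` route one shared color scheme through that
alignment so the same biological cluster keeps its color in every view.

## Views

* `adjacencyGraph()` connects karyotypes at distance below `tau`
  (default 0.6 on Jaccard, i.e. sharing more than 40% of aberrations).
  The threshold is a parameter; the package does not re-derive it.
* `densityDownsample()` keeps object $i$ with probability
  $\min(1, TD/LD_i)$, where $LD_i$ counts neighbors within a radius
  (default: 5th percentile of off-diagonal distances) and the target
  density $TD$ is calibrated by bisection so the expected kept count
  equals the target. Dense regions are thinned; rare clusters survive
  far better than under uniform thinning, which is the point.
* `classicalMDS()` is Torgerson double-centering (via `cmdscale`), with
  zero-padding and a warning when the positive spectrum is smaller than
  the requested dimension.
* `hclustWard()` uses the Ward.D2 convention. Jaccard distances are not
  Euclidean, so the dendrogram (and the MDS view) are heuristic
  projections, useful for orientation rather than inference.
* t-SNE or any other non-linear embedding can be plugged into
  `embedCoords()` as a user-supplied function; the package does not
  re-implement one.

## Characterization

Feature clusters become event groups: `eventSignature()` expands each
group through the `DedupMap`, parses the band and event type of every
member, and classifies the group (loss-only, gain-only, fusion-only,
fusion+loss, fusion+gain, mixed; "mixed" also flags loss+gain groups
without a fusion, which the classical taxonomy does not enumerate -- a
message is emitted when it occurs). A sample *exhibits* a group if any
member feature is 1; with exact duplicate columns this is equivalent on
representatives, and it matches the union semantics of band lists.
`eventFrequency()` counts carriers exactly (integer arithmetic; rounding
only in rendered reports), `coverageSummary()` reports how many clusters
have at least one event above each threshold of the conventional
99/95/90/80/70/60% ladder, `topEvents()` lists qualifying events per
cluster (cutoff compared on unrounded values; ties by group id), and
`heatmapOrder()` orders both axes by Ward clustering of
1 - Pearson-correlation distances, treating zero-variance profiles as
correlation 0.

## The synthetic cohort generator

`simulateCohort()` is first-class, tested code and the package's study
bench. It emulates exactly the features of real LGF data the pipeline
exploits:

* **block-duplicated columns** -- each elementary event sets a block of
  `blockSize` band features together;
* **planted sample clusters** with disjoint event signatures and
  per-event `penetrance`;
* **one-way noise** -- background 0 to 1 flips (false aberration calls)
  at rate `noise`, keeping event blocks internally consistent the way
  real whole-arm events are (a symmetric mode exists for robustness
  checks);
* **uninformative outlier features** -- iid Bernoulli columns.

The reference conditions (`defaultSimSpec()`): 600 samples, 5 equally
likely clusters, 12 events of 8 bands (2-3 events per cluster),
penetrance 0.9, noise 0.01, 40 outlier features at rate 0.02, seed 42.
These sizes keep every property measurable in seconds while leaving the
structure non-trivial: roughly 14% 1-density, noise-unique columns (so
deduplication is only exercised separately in noiseless tests), and a
step function with competing long steps at the cluster and event
dimensions.

What the generator does **not** emulate: ISCN-level structure, clonal
heterogeneity, correlated (non-independent) noise, co-occurring
signatures shared between clusters, and disease-label noise. Passing the
recovery tests therefore shows the machinery is correct on data with
planted block/cluster/penetrance structure; it does not certify
performance on any particular real cohort.

Two measurement conventions in the recovery benchmark
(`recoveryStudy()`) are worth stating. Penetrance recovery is scored on
the planted signature entries (cluster/event pairs with positive planted
penetrance): a non-signature pair has no planted penetrance to recover,
and its observed frequency is the known noise floor
$1 - (1-\varepsilon)^B$ rather than zero. And feature-group recovery is
scored at the true event count, separating "can the clustering recover
the planted groups" from "does the dimension rule count them", which is
scored on its own.

## Numerical and degenerate-input choices

* Eigenvalues below $10^{-12} l_1$ are clipped to zero; spectra with
  fewer than two positive eigenvalues yield a single unit step at q = 1.
* The profile likelihood is evaluated only where the residual variance
  is strictly positive.
* Distance matrices are symmetrized as $(D + D^T)/2$ after vectorized
  computation to remove floating-point jitter, and results are
  independent of evaluation order by construction.
* Down-sampling bisection runs 60 halvings, giving expected-count
  calibration to well below one object.
* `pamCluster` accepts K = 1 (the BUILD seed is already the global
  optimum) and K = n (every object its own medoid, cost 0).
* All RNG consumption is wrapped in `withSeed()`, which restores the
  caller's RNG state, so library calls never perturb a user's stream.

## Problem sizes in the shipped checks

The test suite and the acceptance script regenerate everything they
measure: 1000 random pairs for the metric oracles, 100 random spectra
for the step-function oracle, 200 small instances for the PAM/exhaustive
comparison, 25 seeds of the default cohort for recovery, and 100 seeds
of a 1000-sample two-cluster cohort (90/10 mixture) for down-sampling
calibration. These sizes were chosen so the whole battery runs in about
a minute on one core while keeping Monte-Carlo noise far from the
decision boundaries.
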