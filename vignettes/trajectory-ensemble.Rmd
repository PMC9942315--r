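---
title: "Ensemble pseudotime and fine-tuned cluster trees: methods"
author: "TrajEnsemble authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble pseudotime and fine-tuned cluster trees: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Single-cell RNA-seq profiles a developmental process as a static snapshot:
each cell is one point along (or near) an unobserved trajectory of cell
states. Trajectory inference reconstructs two things from the expression
matrix: a **pseudotime** — a per-cell scalar ordering cells along the
process — and a **trajectory** — the branching structure connecting cell
states. Most cluster-level methods first build a graph (typically a minimum
spanning tree over cluster centers) and then read pseudotime off the graph
as a geodesic distance, which makes the pseudotime inherit every error in
the graph. TrajEnsemble inverts that order: it infers a robust pseudotime
first, by averaging over clusterings at several resolutions, and then uses
that pseudotime to *correct* the cluster-level tree.

# The pipeline

Given a cells × genes count matrix, a GMT collection of pathway gene sets,
and one or more user-supplied start cells, the pipeline runs four stages.

## 1. Preprocessing

* **Iterated log rescale** (`logRescale`): every entry is replaced by
  `log2(x + 1)` repeatedly until the *global* range (max − min over the
  whole matrix) is below 100. The loop reading of the threshold means a
  matrix that already sits in range is untouched, and the transform is
  idempotent. Zeros force a pseudocount; `log2(x + 1)` is used because it
  is the field's standard and maps 0 to 0. The range is deliberately
  global rather than per-gene: the criterion describes the expression
  scale of the matrix as a whole. A cap of 30 iterations guards against
  pathological (non-finite) input; it is mathematically unreachable for
  finite matrices.
* **Gene quality control** (`filterGenes`): a gene is kept iff it is
  expressed (value > 0) in at least 20% of cells. The boundary is kept —
  removal applies to genes expressed in *less than* 20%. Rescaling is
  applied before filtering (the order in which the two steps are
  described); since `log2(x+1)` preserves zeros, the order does not change
  which genes pass.

## 2. Pathway factorization

Genes act in concert, and only part of the transcriptome tracks the
developmental process. Instead of feeding all genes to the embedding, the
matrix is intersected with each pathway gene set; pathways matching fewer
than 10 genes are dropped (threshold inclusive: exactly 10 survives). Each
surviving pathway submatrix is summarized by **two factor-analysis score
columns**, which equalizes the influence of small and large pathways; the
scores are concatenated, giving `2 × P` columns for `P` surviving
pathways, and clipped to `[-5, 5]` to cut outliers.

Numerical choices:

* Columns are standardized before extraction (factor analysis operates on
  the correlation matrix), so gene scale differences inside a pathway
  cannot dominate. This standardization is this package's choice.
* Extraction is maximum-likelihood factor analysis (`stats::factanal`),
  rotation "none", regression scores — base R's canonical routine for the
  task, and deterministic.
* Factor signs are indeterminate; each factor is flipped so its
  largest-magnitude loading is positive, making results reproducible
  across platforms.
* Degenerate pathways: if the likelihood fit fails (Heywood cases,
  singular correlation matrices — common in near-noise-free data), the
  first two principal-component scores of the standardized submatrix are
  used, with a warning. If fewer than two non-constant genes remain, zero
  columns are emitted so pathway bookkeeping stays consistent.

## 3. Shared embedding and the clustering backend

The factor matrix is embedded once into a `d = 15`-dimensional latent
space (truncated, sign-fixed PCA in the default backend) and that single
latent space serves both the ensemble and the final clustering. Clustering
at fixed `k` is k-means with 10 restarts under a fixed seed; the final
partition picks `k` in `[2, 15]` by maximal mean silhouette width (ties to
the smallest `k`).

The backend is a deliberately narrow contract (`backendEmbed`,
`backendCluster` on an `EmbedClusterBackend` object): the architecture is
agnostic to which dimension-reduction/clustering engine stands behind it,
and heavier engines (e.g. autoencoder-based ones) can be swapped in
without touching anything downstream. The test suite verifies the contract
with a mock backend.

One design point deserves emphasis: all per-resolution clusterings run in
the **same** latent space. The ensemble averages raw, unnormalized
distances across resolutions, and a shared space keeps those distances on
a common scale, which is what makes the plain element-wise average
well-posed.

## 4. Ensemble pseudotime

For each `k` from 5 to 10 (six resolutions, from coarse to fine):

1. The **start cluster** is the mode of the clusters containing the
   user-supplied start cells (ties: smallest cluster index).
2. Cells in the start cluster get pseudotime **exactly 0**; every other
   cell inherits the Euclidean distance from its cluster's center (mean of
   member latent coordinates) to the start cluster's center.

The final pseudotime is the element-wise mean of the six per-resolution
vectors. Per-run vectors are averaged *without* normalization (an optional
`normalizeRuns` flag rescales each run to maximum 1 first, default off).
Per-run seeds are derived as `seed + k`, so runs differ but the ensemble
is deterministic. Raising the maximum resolution beyond 10 refines the
ordering slightly at the cost of extra clustering runs; both bounds are
exposed (`kMin`, `kMax`).

Note the consequence of the mode rule: a start cell that some resolution
assigns *outside* the mode start cluster inherits that cluster's distance
in that run, so only cells that land in the start cluster at every
resolution are guaranteed an ensemble value of exactly 0.

## 5. Trajectory construction and fine-tuning

The final partition's cluster centers become vertices of a complete graph
weighted by Euclidean distance; its **minimum spanning tree**, directed
away from the start cluster, is the initial trajectory. The MST is
computed by Kruskal's algorithm with a deterministic lexicographic
(weight, smaller index, larger index) tie-break, so symmetric center
configurations cannot produce platform-dependent trees; tests cross-check
the total weight against igraph's MST.

The MST knows nothing about direction or vertex attributes, so its vertex
order can disagree with the developmental order. The **fine-tune** step
repairs this using mean cluster pseudotime as a weak label. Starting at
the root position, it considers the payloads at all strict descendants,
finds the one with minimum mean pseudotime (`v_min`, ties broken by
smallest cluster index), and if the current payload's pseudotime exceeds
it, *swaps the two payloads between their positions*, recomputing the
weights of all edges incident to either position from the new endpoint
centers; it then recurses into each child position using the post-swap
assignment. The tree's shape is never modified — only which payload sits
where.

Two properties follow and are verified exhaustively in the tests:

* **Min-heap postcondition.** Every position ends with mean pseudotime ≤
  all of its strict descendants': each visited position receives the
  minimum over its entire descendant set before the recursion descends,
  so no later swap below it can raise a smaller value above it. The same
  argument shows the procedure is idempotent, and that a root carrying
  ensemble pseudotime (start cluster = 0) is never swapped away.
* **Weight consistency.** Every final edge weight equals the Euclidean
  distance of its endpoints' centers, checked globally by the class
  validity method.

The per-cell pseudotime the pipeline reports is the ensemble pseudotime,
not a geodesic re-derivation from the fine-tuned tree: the tree is the
trajectory output, the ensemble is the pseudotime output.

# Evaluation

`stageCorrelation` scores inferred pseudotime against ground-truth
developmental stages, encoded by ordinal index. Spearman is the default —
a cluster-level pseudotime is monotone but far from linear in stage, and
midranks handle the heavy ties a cluster-level pseudotime produces —
Pearson is available by flag, and the CLI's `evaluate` subcommand reports
both.

# The synthetic generator

`simulateTrajectory` emulates the structure the pipeline assumes:

* A rooted milestone topology (linear chain, two-armed bifurcation, or a
  small tree) is laid out in a 5-dimensional latent space so adjacent
  milestones are unit distance apart and non-adjacent ones farther (each
  new branch takes a fresh orthogonal axis).
* Each cell is its milestone center plus isotropic Gaussian noise
  (`noiseSd`, in units of the inter-milestone spacing).
* Expression is the softplus of a fixed random linear map of latent
  position, scaled by 50 so the raw range exceeds 100 and the log-rescale
  loop actually engages; an optional Poisson option adds count noise.
* Start cells are 5 cells sampled from the root stage — a sample rather
  than the whole stage, so the mode rule in start-cluster selection is
  genuinely exercised.
* `simulateGeneSets` draws gene sets (default 15 sets of 10–40 genes)
  from the simulated gene universe, so the pathway-intersection step sees
  realistic partial overlaps.

Default study conditions used in the property tests and the acceptance
script: 5 stages × 200 cells for the linear recovery check at latent noise
0.15, and the 5-milestone bifurcation × 200 cells at noise 0.1 for
topology recovery, each over 10 simulation seeds; the fine-tune procedure
is checked against an independent naive transcription on *all* rooted tree
shapes with up to 6 positions (50 random payload assignments each) and on
200 random trees with up to 12 positions. These sizes keep the whole suite
in the minutes range on a single core while leaving every property
nontrivially exercised.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: dropout and technical zero inflation, library
size variation, batch effects, genes outside any pathway dominating
variance, overlapping or cyclic trajectories, and the cluster-number
regime of atlas-scale datasets. The generator's linear-map-plus-softplus
readout is intentionally simple: the pipeline's first acts are a log
transform and factor analysis, which this readout exercises directly.

# Limitations

* The trajectory is a single connected rooted tree: cycles and
  disconnected processes are out of scope.
* Cells inherit their cluster's pseudotime wholesale; there is no
  within-cluster ordering and no principal-curve smoothing.
* The default backend is linear (PCA); strongly nonlinear manifolds will
  benefit from plugging a nonlinear backend into the contract.
* Identifier matching between the expression matrix and the GMT is the
  user's responsibility; no organism-specific gene-ID mapping is bundled.
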