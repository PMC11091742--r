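---
title: "Co-expression-assisted clustering: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-expression-assisted clustering: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Graph-based clustering of scRNA-seq data treats every highly variable gene
equally when it builds its neighbor graph, so the partition it returns is
shaped as much by technical noise as by the co-regulated marker programs
that actually distinguish cell populations. `cascc` turns this around: it
first finds the *gene co-expression signatures* present in the data with an
attractor algorithm, and then lets those signatures decide the features,
the number of clusters K, and where K-means starts.

The pipeline has five stages, all behind the single fitting function
`cascc()`:

1. **QC and normalization.** Genes detected in fewer than
   `min_cells_per_gene` (3) cells and cells expressing fewer than
   `min_genes_per_cell` (200) genes are dropped; counts are scaled to
   `norm_scale` (10^4) per cell and `log1p`-transformed.
2. **Initial graph clustering.** PCA (50 components on the 2000 most
   variable genes), a shared-nearest-neighbor graph (k = 20, Jaccard edge
   weights), and Louvain modularity optimization at resolution 1. This
   partition is *scaffolding only*: its one-vs-rest Wilcoxon markers (top
   10 per cluster, BH-adjusted) become candidate attractor seeds.
3. **Adaptive attractor search** from every candidate seed (details
   below), followed by signature deduplication.
4. **K = number of surviving signatures.** Each genuine co-expression
   signature marks one dominant population. If fewer than two signatures
   survive, the initial partition's K is used instead, with a warning.
5. **Seeded K-means.** Cells are points in the feature space spanned by
   the attractor genes plus the initial markers; center *i* starts at the
   cell that maximally expresses signature *i*; Lloyd iterations run to a
   1e-4 center-shift tolerance, with no random restarts. The result is
   fully deterministic.

## The attractor iteration

A *metagene* is a per-cell score vector; the iteration starts it at a seed
gene's expression row. Each step computes the association `J_g` of every
gene with the current metagene and replaces the metagene with the convex
combination of gene rows weighted by `J_g^a / sum(J^a)`. A fixed point of
this map is a ranked gene list — the attractor signature — whose top genes
are the core of one co-expression program. Convergence is declared when
the top-`top_n` (20) set is stable between consecutive iterations and no
association moves by more than `tol` (1e-7); a state revisited with period
2 is flagged oscillating and discarded.

**Association estimator.** `J` is normalized mutual information estimated
with B-spline soft binning (6 bins, order 3) on rank-transformed values.
Rank binning makes `J` exactly invariant under strictly increasing
transformations and keeps the zero-inflation mass of sparse counts in the
lowest bin, where value-based bins would degenerate. The marginal
information used for normalization is the estimator's own self-MI — the MI
of a vector with itself under the same soft binning — so that
`J(x, x) = 1` holds exactly; with hard bins this reduces to the ordinary
Shannon marginal entropy. The estimator is symmetric and clipped to
`[0, 1]`.

**Signed association.** Mutual information cannot tell co-expression from
mutual exclusion: with two cell types, the markers of one type are
perfectly informative about the markers of the other. Inside the attractor
the association is therefore multiplied by the sign of the Spearman
correlation with the metagene; anti-correlated genes get weight zero and
cannot enter a signature. Without this, mutually exclusive marker programs
fuse into mixed signatures and K is over-estimated.

**Seed release.** At initialization the seed's self-association is 1 by
construction while its partners' associations are far smaller, so the raw
update would lock the metagene onto the seed row forever. The first update
therefore excludes the seed's own weight, letting the seed's co-expression
partners define the first metagene; from the second iteration on the seed
competes like any other gene.

**Adaptive exponent.** The weighting exponent starts at `a_min` (2). If
the converged signature is *generic* — more than `breadth_cap` (100) genes
within `breadth_level` (0.5) of its top association, the profile of a
housekeeping or depth-driven program — the exponent is raised by `a_step`
(1) and the iteration re-converged from the seed, up to `a_max` (10). A
sharper exponent keeps the iterate inside the seed's own co-expression
instead of drifting into the generic one. The breadth count is relative to
the signature's top association because the absolute association scale
depends strongly on data sparsity.

**Strength and deduplication.** Two filters decide which converged
signatures count:

* *Strength.* A genuine signature has deep support: its rank-10
  (`strength_rank`) association must stand at least `strength_ratio` (5)
  times above the signature's association noise floor (the median |J|
  over all genes). This is read at rank 10, not rank 1, because a noise
  seed can be its own one-gene fixed point with a top association near 1
  while everything below it sits at the floor. An optional absolute floor
  (`strength_min`, default 0) is available. The same criterion, applied
  to the seed's first association profile, screens hopeless seeds before
  any iteration is spent on them.
* *Deduplication.* Any seed inside a co-expression converges to the same
  signature, so surviving signatures are grouped by single-link clustering
  on the Jaccard overlap of their top-20 sets (threshold `jaccard_min` =
  0.5) and each group keeps its member with the highest mean top-20
  association. Single-link grouping is a transitive closure and therefore
  independent of input order.

The seed scan runs in two phases — the leading marker of each initial
cluster (parallelizable over `threads`), then the remaining seeds
sequentially, skipping any seed already ranked in the top 10 of an
accepted signature. Both economies are outcome-neutral: a screened seed
cannot found a signature and a covered seed would converge to the
signature that covers it, so serial and parallel runs are byte-identical.

## Feature scaling for K-means

Features are the union of the top `n_attr` (20) genes of each signature
and the top `n_deg` (10) markers of each initial cluster. For the K-means
step the cells are represented by clipped analytic negative-binomial
Pearson residuals of the counts (null model: gene mean times cell size
factor, variance `mu + mu^2/theta` with `theta = 100`, clipped at
±sqrt(n_cells)). We chose residuals over z-scored log values deliberately:
`log1p` compresses exactly the strongly elevated counts that distinguish a
population, and on data where types differ in a few tens of genes that
compression is the accuracy bottleneck — an exact-likelihood classifier
separates such cells perfectly while equal-weight log-scale scoring does
not. Pearson residuals keep that magnitude evidence on a comparable scale
across genes and are the current standard for count-based feature scaling.
The log-normalized layer is still what the attractor, the marker tests and
the center-picking scores consume.

The optional 2D embedding is an exact t-SNE (perplexity capped at
`(n-1)/3`, PCA initialization plus seeded jitter, early exaggeration 12
for 100 iterations, 500 iterations total) computed on the same residual
feature matrix, so the embedding reflects the method's own feature
selection. UMAP is not implemented; requesting it raises a capability
error and the pipeline continues without an embedding.

## Evaluation metrics

`ari()` implements the Hubert–Arabie adjusted Rand index from the
contingency table; pair counts are integers represented exactly in double
precision for any realistic cell count, and a degenerate denominator
returns 0 (or 1 for two identical trivial partitions). `nmi()` normalizes
mutual information by the arithmetic mean of the partition entropies by
default (geometric, min and max are available); `ami()` subtracts the
exact hypergeometric expected MI for n ≤ 5000 and a Monte-Carlo estimate
above. `log_modulus_k()` is `|sign(d) log10(|d|+1)|` of the K gap,
`deviation_k()` the signed relative deviation `(K_est - K_true)/K_true`;
both formulas are isolated behind their functions so either convention can
be swapped. `asw()` is the mean silhouette width in an embedding, with
singleton clusters contributing 0.

## The synthetic generator

`generate_synthetic()` draws a genes x cells count matrix with `C` planted
types. Each type owns a disjoint module of `module_size` genes; within a
cell of that type the module genes share a latent factor
`f ~ N(1, sd = 0.1)` and are NB-distributed with mean
`baseline_mean * exp(module_strength * f)`; all other entries are
NB(`baseline_mean`, `dispersion`); independent Bernoulli dropout zeroes
each entry with probability `dropout_rate`. The reference ("strong")
preset is 3 types, 600 cells, 1000 genes, 20-gene modules at loading 1.5
and 30% dropout; "weak" lowers the loading to 0.6 (deliberately at the
detection limit of the seed screen) and "null" to 0. `baseline_mean = 3`
and `dispersion = 10` were fixed once as a moderately expressed,
moderately overdispersed gene panel; at these values the pairwise
correlation of same-module genes exceeds background correlation by ≈0.35
on the counts scale, the co-expression structure the attractor is built to
exploit.

What the generator deliberately omits: batch effects, ambient
contamination, doublets, library-size gradients correlated with type, and
transitioning populations that interpolate between programs. Passing the
end-to-end tests therefore shows the machinery is correct under clean
planted structure, not that real tissues will be recovered with the same
accuracy.

## Numerical choices and degenerate inputs

* Ties everywhere resolve deterministically: equal associations by gene
  id, equal distances by cell index, duplicate ids get a numeric suffix
  with a warning.
* A constant vector has zero information: its association is 0 by
  convention, a constant seed is rejected, a constant metagene raises a
  degenerate-convergence condition that the scan records and discards.
* An edgeless neighbor graph yields the singleton partition with a
  warning; an empty cluster during Lloyd iteration is re-seeded at the
  point farthest from its previous center; when K exceeds the number of
  signatures the remaining centers are placed by farthest-first traversal.
* All-zero cells stay all-zero through normalization; an MTX triplet
  outside its declared dimensions, negative or non-finite entries, and
  missing sidecar files are rejected with stage-named errors.

## Problem sizes used in validation

The shipped tests validate the full pipeline on the reference 600 x 1000
conditions (20 generator seeds for recovery, 10 per type count for the K
study) and use 200-500-cell toys for the per-operation oracles; these
sizes give tight Monte-Carlo margins while keeping the whole suite
comfortably interactive. `scripts/acceptance.R` re-runs the same
computations from scratch at the same sizes.

## Known limitations

* K equals the number of surviving signatures; a population without a
  coherent co-expression module (or two populations sharing one) will be
  under-counted. `k_override` exists for exactly that case.
* The attractor scan is quadratic in cells for the association cache and
  linear in scanned genes per iteration; atlas-scale inputs (10^5+ cells)
  need subsampling, which the package does not automate.
* The seed screen and strength filter are calibrated for sparse count
  data; on dense, strongly correlated data (e.g. bulk profiles) they are
  conservative and `strength_ratio` may need lowering.
* `embed_2d()` is exact t-SNE, O(n^2) per iteration: fine to a few
  thousand cells, slow beyond.
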