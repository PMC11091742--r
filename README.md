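# cascc — co-expression-assisted single-cell clustering

`cascc` clusters single-cell RNA-seq data by first discovering the gene
co-expression signatures present in the expression matrix and then letting
those signatures drive the clustering: they select the features, determine
the number of clusters K, and place the initial K-means centers. It is
aimed at analysts who want a partition anchored in co-regulated marker
programs rather than in the geometry of a noisy neighbor graph, together
with the standard metrics to evaluate it.

## Method in brief

The core object is the **attractor signature**. Starting from a seed gene
*g*, a per-cell metagene *m* is initialized at *g*'s expression row and
iterated:

    J_h   = sMI(x_h, m)                 for every gene h
    w_h   = max(J_h, 0)^a / Σ max(J, 0)^a
    m'    = Σ_h w_h · x_h

where `sMI` is normalized mutual information (B-spline soft binning on
ranks, normalized so `sMI(x, x) = 1`) multiplied by the sign of the
Spearman correlation, and `a` is an exponent adapted upward if the
signature converges onto a generic, housekeeping-like profile. The fixed
point is a ranked gene list identifying the core of one co-expression
program; any seed inside the program converges to the same list.

The pipeline runs: QC → log-normalization → SNN-Louvain initial
clustering → attractor search seeded at each initial cluster's top
Wilcoxon markers → signature deduplication → **K = number of surviving
signatures** → K-means on NB Pearson-residual features, centers seeded at
the cells maximally expressing each signature. Every stage is
deterministic given a seed, and the attractor scan parallelizes without
changing its output.

Evaluation helpers implement the Hubert–Arabie adjusted Rand index,
adjusted and normalized mutual information, the absolute log-modulus
`|sign(d)·log10(|d|+1)|` and signed relative deviation of an estimated
cluster number, and average silhouette width of a 2D embedding. A
negative-binomial generator with planted cell types and co-expression
modules provides ground truth for end-to-end validation.

## Worked example

```r
library(cascc)

# a synthetic dataset with 3 planted cell types (600 cells x 1000 genes)
d   <- generate_synthetic(synth_preset("strong", seed = 7))
fit <- cascc(d$matrix, seed = 1)
fit
#> Co-expression-assisted clustering (cascc 0.1.0)
#>   600 cells in K = 3 clusters (estimated K = 3)
#>   3 attractor signature(s), 120 selected features

evaluate_clustering(labels(fit), d$truth$type_label,
                    embedding = fit$embedding_2d)[c("ari", "ami", "k_est")]
#> $ari
#> [1] 1
#> $ami
#> [1] 1
#> $k_est
#> [1] 3
```

The three attractor signatures recover the three planted 20-gene modules
(`summary(fit)` lists their top genes), the estimated K equals the planted
type count, and the final labels agree perfectly with the ground truth —
ARI and AMI of 1 mean no cell is misassigned. `plot(fit)` shows the cells
in the t-SNE embedding of the selected feature space, colored by cluster.

File-based workflows use `cascc_run(input, out_dir)` (10x-style MTX
triplet or dense CSV/TSV in; labels, summary JSON, signature table and
embedding out) and `cascc_eval(pred, truth)`; a thin command-line wrapper
with `simulate` / `run` / `eval` subcommands is in `inst/cli/cascc.R`.

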