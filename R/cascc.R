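#' Pipeline configuration
#'
#' All tunable parameters of the pipeline as a flat named list. Unknown
#' keys are rejected. The effective configuration is echoed into every
#' fitted object and summary file.
#'
#' @param ... Key = value overrides of the defaults listed below.
#' @return Named list of class `"cascc_config"`.
#'
#' @details Defaults:
#' \describe{
#'   \item{QC}{`min_cells_per_gene = 3`, `min_genes_per_cell = 200`,
#'     `norm_scale = 1e4`.}
#'   \item{Initial clustering}{`hvg = TRUE`, `n_hvg = 2000`,
#'     `n_components = 50`, `knn_k = 20`, `resolution = 1`,
#'     `n_seed_candidates = 10` (marker seeds per initial cluster).}
#'   \item{Attractor}{`bins = 6`, `spline_order = 3`, `a_min = 2`,
#'     `a_max = 10`, `a_step = 1`, `breadth_cap = 100`,
#'     `breadth_level = 0.5`, `top_n = 20`, `tol = 1e-7`,
#'     `max_iter = 100`, `jaccard_min = 0.5`, `strength_min = 0`,
#'     `strength_rank = 10`, `strength_ratio = 5`,
#'     `scan_all_genes = FALSE` (scan restricted to HVG plus seed
#'     candidates).}
#'   \item{Final clustering}{`n_deg = 10`, `n_attr = 20`, `zclip = 10`,
#'     `residual_theta = 100` (NB shape of the Pearson-residual feature
#'     scaling), `kmeans_tol = 1e-4`, `kmeans_max_iter = 300`.}
#'   \item{Embedding}{`embed_method = "tsne"`, `embed_iter = 500`,
#'     `perplexity = 30`.}
#' }
#' @export
cascc_config <- function(...) {
  defaults <- list(
    min_cells_per_gene = 3L, min_genes_per_cell = 200L, norm_scale = 1e4,
    hvg = TRUE, n_hvg = 2000L, n_components = 50L, knn_k = 20L,
    resolution = 1, n_seed_candidates = 10L,
    bins = 6L, spline_order = 3L, a_min = 2, a_max = 10, a_step = 1,
    breadth_cap = 100L, breadth_level = 0.5, top_n = 20L, tol = 1e-7,
    max_iter = 100L, jaccard_min = 0.5, strength_min = 0,
    strength_rank = 10L, strength_ratio = 5, scan_all_genes = FALSE,
    n_deg = 10L, n_attr = 20L, zclip = 10, residual_theta = 100,
    kmeans_tol = 1e-4, kmeans_max_iter = 300L,
    embed_method = "tsne", embed_iter = 500L, perplexity = 30)
  over <- list(...)
  if (length(over) == 1L && is.list(over[[1L]]) && is.null(names(over))) {
    over <- over[[1L]]
  }
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  defaults[names(over)] <- over
  structure(defaults, class = "cascc_config")
}

#' Co-expression-assisted clustering of single-cell expression data
#'
#' Fits the full five-step pipeline: (1) QC filtering, log-normalization
#' and an initial shared-nearest-neighbor Louvain clustering of the cells;
#' (2) adaptive attractor search seeded at each initial cluster's top
#' marker genes, yielding deduplicated co-expression signatures; (3)
#' feature selection as the union of attractor genes and initial markers;
#' (4) the number of clusters K set to the number of surviving signatures;
#' (5) K-means on the feature-selected z-scored matrix, initialized at the
#' cells that maximally express each signature. Every stage is
#' deterministic given `seed`; the attractor scan parallelizes over
#' `threads` without changing the result.
#'
#' @param x A counts-layer [expression_matrix()], or a path accepted by
#'   [load_matrix()].
#' @param config A [cascc_config()].
#' @param k_override Optional integer forcing K, bypassing the
#'   attractor-based estimate (reported in the summary).
#' @param embedding Compute the 2D t-SNE embedding of the feature space
#'   (default TRUE).
#' @param threads Parallel workers for the attractor scan (default 1).
#' @param seed Integer seed for the stochastic stages (graph clustering,
#'   embedding initialization).
#' @param verbose Print per-stage progress to stderr (default FALSE).
#' @return Object of class `"cascc"`: list with `assignment` (a
#'   [cluster_assignment()]), `K`, `k_estimated`, `features`, `attractors`,
#'   `centers_cell_ids`, `embedding_2d` (or NULL), `initial` (the step-1
#'   assignment), `seed_candidates`, `filter_report`, `config`, `seed`,
#'   `version`.
#' @seealso [labels.cascc()], [summary.cascc()], [plot.cascc()],
#'   [evaluate_clustering()]
#' @export
cascc <- function(x, config = cascc_config(), k_override = NULL,
                  embedding = TRUE, threads = 1L, seed = 0L,
                  verbose = FALSE) {
  cfg <- if (inherits(config, "cascc_config")) config
         else cascc_config(config)
  say <- function(...) if (verbose) message("[cascc] ", ...)
  if (is.character(x)) {
    say("loading ", x)
    x <- load_matrix(x)
  }
  .check_layer(x, "counts")
  if (ncol(x$values) == 0L || nrow(x$values) == 0L) {
    stop("empty expression matrix", call. = FALSE)
  }

  say("QC filtering ", nrow(x$values), " genes x ", ncol(x$values), " cells")
  mf <- filter_matrix(x, cfg$min_cells_per_gene, cfg$min_genes_per_cell)
  report <- attr(mf, "filter_report")
  ln <- log_normalize(mf, cfg$norm_scale)

  say("initial graph clustering")
  hvg <- if (cfg$hvg) select_hvg(ln, cfg$n_hvg) else ln$gene_ids
  emb <- pca_embed(.subset_genes(ln, hvg), cfg$n_components, seed = seed)
  g <- knn_graph(emb, k = min(cfg$knn_k, ncol(ln$values) - 1L))
  init <- graph_cluster(g, resolution = cfg$resolution, seed = seed)

  seeds_tab <- if (init$K >= 2L) {
    rank_degs(ln, init, n_top = cfg$n_seed_candidates)
  } else {
    NULL
  }
  seed_genes <- if (!is.null(seeds_tab)) {
    lapply(seeds_tab, `[[`, "gene_id")     # per-cluster, marker-rank order
  } else {
    # single initial cluster: fall back to top-variance genes as seeds
    list(hvg[seq_len(min(cfg$n_seed_candidates, length(hvg)))])
  }

  say("attractor scan over ", length(unlist(seed_genes)), " seeds")
  scan_genes <- if (cfg$scan_all_genes) ln$gene_ids
                else union(hvg, unlist(seed_genes))
  mscan <- .subset_genes(ln, intersect(ln$gene_ids, scan_genes))
  attractors <- find_attractors(
    mscan, seed_genes, a_min = cfg$a_min, a_max = cfg$a_max,
    a_step = cfg$a_step, breadth_cap = cfg$breadth_cap,
    breadth_level = cfg$breadth_level, max_iter = cfg$max_iter,
    top_n = cfg$top_n, tol = cfg$tol, bins = cfg$bins,
    spline_order = cfg$spline_order, jaccard_min = cfg$jaccard_min,
    strength_min = cfg$strength_min, strength_rank = cfg$strength_rank,
    strength_ratio = cfg$strength_ratio, threads = threads)
  say(length(attractors), " attractor signature(s) survive deduplication")

  k_estimated <- estimate_k(attractors, fallback = init)
  K <- if (!is.null(k_override)) {
    say("K forced to ", k_override, " by k_override (estimate was ",
        k_estimated, ")")
    as.integer(k_override)
  } else {
    k_estimated
  }

  features <- build_feature_set(seeds_tab, attractors,
                                n_deg = cfg$n_deg, n_attr = cfg$n_attr)
  say(nrow(features), " features; K = ", K)

  # cells as points in clipped NB Pearson-residual space of the features
  Xfeat <- t(pearson_residuals(mf, theta = cfg$residual_theta)[
    features$gene_id, , drop = FALSE])
  km <- kmeans_seeded(ln, features, attractors, K, n_top = cfg$n_attr,
                      clip = cfg$zclip, tol = cfg$kmeans_tol,
                      max_iter = cfg$kmeans_max_iter, X = Xfeat)

  emb2 <- NULL
  if (embedding) {
    say("2D embedding (", cfg$embed_method, ")")
    emb2 <- tryCatch(
      embed_2d(Xfeat, method = cfg$embed_method, seed = seed,
               perplexity = cfg$perplexity, max_iter = cfg$embed_iter),
      error = function(e) {
        warning("embedding skipped: ", conditionMessage(e), call. = FALSE)
        NULL
      })
  }

  structure(list(assignment = km$assignment, K = km$assignment$K,
                 k_estimated = k_estimated, features = features,
                 attractors = attractors,
                 centers_cell_ids = km$centers_cell_ids,
                 sse_trace = km$sse_trace, embedding_2d = emb2,
                 initial = init, seed_candidates = seeds_tab,
                 filter_report = report, config = cfg, seed = seed,
                 version = tryCatch(
                   as.character(utils::packageVersion("cascc")),
                   error = function(e) "dev")),
            class = "cascc")
}

#' @export
print.cascc <- function(x, ...) {
  cat(sprintf("Co-expression-assisted clustering (cascc %s)\n", x$version))
  cat(sprintf("  %d cells in K = %d clusters (estimated K = %d)\n",
              length(x$assignment$labels), x$K, x$k_estimated))
  cat(sprintf("  %d attractor signature(s), %d selected features\n",
              length(x$attractors), nrow(x$features)))
  invisible(x)
}

#' Summarize a fitted clustering
#'
#' @param object A `"cascc"` fit.
#' @param ... Unused.
#' @return The fit, invisibly; prints cluster sizes, attractor exponents
#'   and top genes, and feature provenance counts.
#' @export
summary.cascc <- function(object, ...) {
  print(object)
  cat("\nCluster sizes:\n")
  print(table(label = object$assignment$labels))
  cat("\nAttractor signatures:\n")
  for (i in seq_along(object$attractors)) {
    s <- object$attractors[[i]]
    cat(sprintf("  [%d] seed=%s a=%g top: %s\n", i, s$seed, s$exponent,
                paste(s$ranked_genes[1:min(5, length(s$ranked_genes))],
                      collapse = " ")))
  }
  cat("\nFeature provenance:\n")
  print(table(object$features$provenance))
  invisible(object)
}

#' Cluster labels of a fitted clustering
#'
#' @param object A `"cascc"` fit.
#' @param ... Unused.
#' @return Integer labels (`0..K-1`) named by cell id.
#' @export
labels.cascc <- function(object, ...) {
  stats::setNames(object$assignment$labels, object$assignment$cell_ids)
}

#' Plot a fitted clustering in its 2D embedding
#'
#' @param x A `"cascc"` fit with an embedding.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.cascc <- function(x, ...) {
  if (is.null(x$embedding_2d)) {
    stop("fit has no 2D embedding (run cascc(..., embedding = TRUE))",
         call. = FALSE)
  }
  lab <- x$assignment$labels
  graphics::plot(x$embedding_2d, col = lab + 1L, pch = 19, cex = 0.6,
                 xlab = "dim 1", ylab = "dim 2",
                 main = sprintf("cascc clustering (K = %d)", x$K), ...)
  invisible(x)
}

#' Run the pipeline on a dataset and write its output files
#'
#' Wraps [cascc()] with the on-disk interface: writes `cascc_labels.csv`
#' (`cell_id,label`), `cascc_summary.json` (K, feature count, attractor
#' seeds and exponents, the effective configuration and package version),
#' `attractors.tsv`, `initial_clusters.tsv`, `seed_candidates.tsv` and,
#' when an embedding was computed, `embedding.tsv`.
#'
#' @inheritParams cascc
#' @param input Path to the input matrix (directory or file).
#' @param out_dir Output directory, created if needed.
#' @param format Input format passed to [load_matrix()].
#' @return The `"cascc"` fit, invisibly.
#' @export
cascc_run <- function(input, out_dir, format = "auto",
                      config = cascc_config(), k_override = NULL,
                      embedding = TRUE, threads = 1L, seed = 0L,
                      verbose = FALSE) {
  m <- load_matrix(input, format = format)
  fit <- cascc(m, config = config, k_override = k_override,
               embedding = embedding, threads = threads, seed = seed,
               verbose = verbose)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(data.frame(cell_id = fit$assignment$cell_ids,
                              label = fit$assignment$labels),
                   file.path(out_dir, "cascc_labels.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.table(
    data.frame(cell_id = fit$initial$cell_ids, label = fit$initial$labels),
    file.path(out_dir, "initial_clusters.tsv"), sep = "\t",
    row.names = FALSE, quote = FALSE)
  if (!is.null(fit$seed_candidates)) {
    sc <- do.call(rbind, lapply(names(fit$seed_candidates), function(cl) {
      df <- fit$seed_candidates[[cl]]
      if (nrow(df) == 0L) return(NULL)
      cbind(cluster = cl, rank = seq_len(nrow(df)), df)
    }))
    utils::write.table(sc, file.path(out_dir, "seed_candidates.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  at <- do.call(rbind, lapply(seq_along(fit$attractors), function(i) {
    s <- fit$attractors[[i]]
    k <- min(fit$config$top_n, length(s$ranked_genes))
    data.frame(attractor_id = i, rank = seq_len(k),
               gene_id = s$ranked_genes[seq_len(k)],
               J = s$associations[seq_len(k)], seed = s$seed,
               exponent = s$exponent, status = s$status)
  }))
  if (!is.null(at)) {
    utils::write.table(at, file.path(out_dir, "attractors.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  if (!is.null(fit$embedding_2d)) {
    utils::write.table(
      data.frame(cell_id = fit$assignment$cell_ids, fit$embedding_2d),
      file.path(out_dir, "embedding.tsv"), sep = "\t", row.names = FALSE,
      quote = FALSE)
  }
  summary_json <- list(
    K = fit$K, k_estimated = fit$k_estimated,
    k_override = if (is.null(k_override)) NULL else k_override,
    n_features = nrow(fit$features),
    attractor_seeds = vapply(fit$attractors, `[[`, "", "seed"),
    attractor_exponents = vapply(fit$attractors, `[[`, 0, "exponent"),
    config = unclass(fit$config), seed = seed, version = fit$version)
  jsonlite::write_json(summary_json,
                       file.path(out_dir, "cascc_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(fit)
}

#' Evaluate predicted labels against ground truth from files
#'
#' File-level counterpart of [evaluate_clustering()]: reads two
#' `cell_id,label` CSVs (aligning cells by id) and optionally an
#' `embedding.tsv` for the silhouette.
#'
#' @param pred_path,truth_path Label CSV paths.
#' @param embedding_path Optional `cell_id,dim1,dim2` TSV.
#' @param out_path Optional path for a JSON report of the metrics.
#' @return The metric list from [evaluate_clustering()].
#' @export
cascc_eval <- function(pred_path, truth_path, embedding_path = NULL,
                       out_path = NULL) {
  pred <- load_labels(pred_path)
  truth <- load_labels(truth_path)
  emb <- NULL
  if (!is.null(embedding_path)) {
    df <- utils::read.delim(embedding_path, colClasses = c("character",
                                                           NA, NA))
    emb <- as.matrix(df[, 2:3])
    rownames(emb) <- df[[1L]]
  }
  res <- evaluate_clustering(pred, truth, embedding = emb)
  if (!is.null(out_path)) {
    jsonlite::write_json(res, out_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  res
}
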