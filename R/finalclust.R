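#' Assemble the feature set for final clustering
#'
#' Union of the top attractor genes (per signature, in signature order) and
#' the top marker genes of each initial cluster, with per-gene provenance.
#' Attractor genes come first, then markers not already present.
#'
#' @param seed_candidates A `"cascc_seeds"` object from [rank_degs()], or
#'   `NULL` when no initial markers are available.
#' @param attractors List of deduplicated `"cascc_attractor"` signatures.
#' @param n_deg Markers kept per initial cluster (default 10).
#' @param n_attr Genes kept per attractor (default 20).
#' @return Object of class `"cascc_features"`: data frame with columns
#'   `gene_id` and `provenance` (`"attractor"`, `"deg"` or `"both"`).
#' @export
build_feature_set <- function(seed_candidates, attractors, n_deg = 10L,
                              n_attr = 20L) {
  attr_genes <- unlist(lapply(attractors, function(s) {
    s$ranked_genes[seq_len(min(n_attr, length(s$ranked_genes)))]
  }), use.names = FALSE)
  attr_genes <- unique(attr_genes)
  deg_genes <- unique(unlist(lapply(seed_candidates, function(df) {
    df$gene_id[seq_len(min(n_deg, nrow(df)))]
  }), use.names = FALSE))
  if (length(attr_genes) == 0L && length(deg_genes) > 0L) {
    warning("no attractor signatures survived; features are initial-cluster",
            " markers only", call. = FALSE)
  }
  gene_ids <- c(attr_genes, setdiff(deg_genes, attr_genes))
  if (length(gene_ids) == 0L) {
    stop("empty feature set: relax the attractor strength/overlap ",
         "thresholds or the marker count", call. = FALSE)
  }
  provenance <- ifelse(gene_ids %in% attr_genes & gene_ids %in% deg_genes,
                       "both",
                       ifelse(gene_ids %in% attr_genes, "attractor", "deg"))
  structure(data.frame(gene_id = gene_ids, provenance = provenance,
                       stringsAsFactors = FALSE),
            class = c("cascc_features", "data.frame"))
}

#' Estimate the number of clusters from the attractor output
#'
#' K is the number of surviving (deduplicated) attractor signatures: each
#' detected co-expression signature marks one dominant population. When
#' fewer than 2 signatures survive the initial graph clustering's K is used
#' instead, with a prominent warning.
#'
#' @param attractors List of deduplicated signatures.
#' @param fallback A [cluster_assignment()] supplying K when the attractor
#'   evidence is insufficient.
#' @return Integer K.
#' @export
estimate_k <- function(attractors, fallback) {
  K <- length(attractors)
  if (K < 2L) {
    warning("only ", K, " attractor signature(s) survived; ",
            "falling back to the initial graph clustering (K = ",
            fallback$K, ")", call. = FALSE)
    return(fallback$K)
  }
  K
}

#' Per-cell expression score of an attractor signature
#'
#' Mean of z-scored log-normalized expression over the signature's top
#' `n_top` genes: the cell-level activity of the co-expression signature,
#' used to pick initial K-means centers.
#'
#' @param m Lognorm-layer [expression_matrix()].
#' @param sig A converged `"cascc_attractor"`.
#' @param n_top Genes averaged (default 20).
#' @return Named numeric vector, one score per cell.
#' @export
attractor_cell_scores <- function(m, sig, n_top = 20L) {
  .check_layer(m, "lognorm")
  if (sig$status != "converged") {
    stop("attractor signature is not converged (status: ", sig$status, ")",
         call. = FALSE)
  }
  top <- sig$ranked_genes[seq_len(min(n_top, length(sig$ranked_genes)))]
  missing <- setdiff(top, m$gene_ids)
  if (length(missing)) {
    stop("attractor gene(s) absent from matrix: ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  z <- .zscore_rows(m$values[top, , drop = FALSE], clip = Inf)
  stats::setNames(colMeans(z), m$cell_ids)
}

#' K-means on the feature-selected matrix, seeded at attractor-peak cells
#'
#' Cells are points in feature space: by default per-gene z-scored
#' (clipped at +/-10) log-normalized expression of the feature genes; the
#' full pipeline passes clipped NB [pearson_residuals()] via `X`, which
#' preserve count-magnitude evidence. Initial center `i` is the feature
#' vector of the cell that maximizes
#' attractor `i`'s [attractor_cell_scores()] (ties broken by lowest cell
#' index; a cell already claimed by an earlier attractor yields to the
#' next-highest cell). If `K` exceeds the number of attractors, remaining
#' centers are placed by deterministic farthest-first traversal. Lloyd
#' iterations with Euclidean distance run until the largest center shift is
#' below `tol` or `max_iter` is reached -- a single deterministic run, no
#' random restarts. A cluster that empties is re-seeded at the point
#' farthest from its previous center.
#'
#' @param m Lognorm-layer [expression_matrix()] (full gene set; it is
#'   subset to `features` internally).
#' @param features A `"cascc_features"` set (or character vector of gene
#'   ids).
#' @param attractors List of converged signatures, one per intended center.
#' @param K Number of clusters, `2 <= K <= n_cells`.
#' @param n_top Genes per attractor used for the center-picking score.
#' @param clip Z-score clipping bound (default 10).
#' @param tol Center-shift convergence threshold (default 1e-4).
#' @param max_iter Lloyd iteration cap (default 300).
#' @param X Optional cells x features matrix overriding the default
#'   feature representation (rows aligned to the cells of `m`).
#' @return List with `assignment` (a [cluster_assignment()]),
#'   `centers_cell_ids` (the seeding cells), and `sse_trace` (total
#'   within-cluster sum of squares after each Lloyd iteration).
#' @export
kmeans_seeded <- function(m, features, attractors, K, n_top = 20L,
                          clip = 10, tol = 1e-4, max_iter = 300L,
                          X = NULL) {
  .check_layer(m, "lognorm")
  gene_ids <- if (inherits(features, "data.frame")) features$gene_id
              else as.character(features)
  n <- ncol(m$values)
  if (K < 1L || K > n) {
    stop("'K' must be between 1 and the number of cells", call. = FALSE)
  }
  if (is.null(X)) {
    mf <- .subset_genes(m, gene_ids)
    X <- t(.zscore_rows(mf$values, clip = clip))  # cells x features
  } else {
    X <- as.matrix(X)
    if (nrow(X) != n) {
      stop("'X' rows must match the cells of 'm'", call. = FALSE)
    }
  }
  # pick one seeding cell per attractor, strongest first
  center_cells <- integer(0L)
  for (sig in attractors) {
    sc <- attractor_cell_scores(m, sig, n_top = n_top)
    ord <- order(-sc, seq_along(sc))             # ties: lowest cell index
    pick <- ord[!(ord %in% center_cells)][1L]
    center_cells <- c(center_cells, pick)
  }
  center_cells <- center_cells[seq_len(min(K, length(center_cells)))]
  # farthest-first traversal fills any centers K has beyond the attractors
  while (length(center_cells) < K) {
    if (length(center_cells) == 0L) {
      center_cells <- 1L
      next
    }
    d2 <- .min_dist2(X, X[center_cells, , drop = FALSE])
    d2[center_cells] <- -Inf
    center_cells <- c(center_cells, which.max(d2))
  }
  centers <- X[center_cells, , drop = FALSE]
  labels <- integer(n)
  sse_trace <- numeric(0L)
  for (it in seq_len(max_iter)) {
    D <- .dist2_matrix(X, centers)               # n x K squared distances
    labels <- max.col(-D, ties.method = "first")
    new_centers <- centers
    for (k in seq_len(K)) {
      idx <- labels == k
      if (!any(idx)) {
        # empty cluster: re-seed at the point farthest from its old center
        far <- which.max(.dist2_to(X, centers[k, ]))
        new_centers[k, ] <- X[far, ]
      } else {
        new_centers[k, ] <- colMeans(X[idx, , drop = FALSE])
      }
    }
    sse_trace <- c(sse_trace,
                   sum((X - new_centers[labels, , drop = FALSE])^2))
    shift <- sqrt(max(rowSums((new_centers - centers)^2)))
    centers <- new_centers
    if (shift < tol) break
  }
  D <- .dist2_matrix(X, centers)
  labels <- max.col(-D, ties.method = "first")
  list(assignment = cluster_assignment(labels - 1L, m$cell_ids),
       centers_cell_ids = m$cell_ids[center_cells],
       sse_trace = sse_trace)
}

.dist2_matrix <- function(X, C) {
  # squared Euclidean distances, n x k
  outer(rowSums(X^2), rep(1, nrow(C))) - 2 * X %*% t(C) +
    outer(rep(1, nrow(X)), rowSums(C^2))
}

.dist2_to <- function(X, v) {
  rowSums(sweep(X, 2L, v)^2)
}

.min_dist2 <- function(X, C) {
  apply(.dist2_matrix(X, C), 1L, min)
}
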