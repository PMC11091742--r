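#' PCA embedding of cells
#'
#' Principal components of the cells computed on per-gene standardized
#' log-normalized expression (genes with zero variance are dropped before
#' standardization). The sign of each component is fixed so that its
#' largest-magnitude gene loading is positive, making the embedding fully
#' reproducible.
#'
#' @param m Lognorm-layer [expression_matrix()].
#' @param n_components Number of components (default 50, capped at
#'   `min(genes, cells) - 1`).
#' @param seed Unused source of randomness kept for interface stability;
#'   the decomposition is deterministic.
#' @return Numeric matrix, cells x n_components, rownames = cell ids.
#' @export
pca_embed <- function(m, n_components = 50L, seed = 0L) {
  .check_layer(m, "lognorm")
  v <- m$values
  keep <- .row_vars(v) > 0
  if (!any(keep)) {
    stop("degenerate input: all genes are constant, PCA undefined",
         call. = FALSE)
  }
  v <- v[keep, , drop = FALSE]
  n_components <- min(n_components, nrow(v) - 1L, ncol(v) - 1L)
  if (n_components < 1L) {
    stop("too few non-constant genes or cells for PCA", call. = FALSE)
  }
  z <- (v - rowMeans(v)) / sqrt(.row_vars(v))
  p <- stats::prcomp(t(z), center = TRUE, scale. = FALSE,
                     rank. = n_components)
  scores <- p$x
  # sign convention: largest-|loading| gene per component has positive sign
  for (j in seq_len(ncol(scores))) {
    l <- p$rotation[, j]
    if (l[which.max(abs(l))] < 0) scores[, j] <- -scores[, j]
  }
  rownames(scores) <- m$cell_ids
  scores
}

#' Shared-nearest-neighbor graph over cells
#'
#' Connects each cell to its `k` nearest Euclidean neighbors in the
#' embedding, symmetrizes edges by union, and weights each edge by the
#' Jaccard overlap of the two endpoints' neighbor sets (shared nearest
#' neighbors). Zero-weight edges are dropped. Distance ties are broken by
#' cell index order.
#'
#' @param embedding Cells x dims numeric matrix (e.g. from [pca_embed()]).
#' @param k Number of neighbors per cell; must satisfy `0 < k < n_cells`.
#' @return An undirected weighted [igraph::graph] whose vertex names are
#'   the embedding rownames (or cell indices).
#' @export
knn_graph <- function(embedding, k = 20L) {
  embedding <- as.matrix(embedding)
  n <- nrow(embedding)
  if (!is.numeric(k) || k <= 0) stop("'k' must be positive", call. = FALSE)
  if (k >= n) stop("'k' must be smaller than the number of cells",
                   call. = FALSE)
  d <- as.matrix(stats::dist(embedding))
  # stable order() breaks distance ties by index
  nbr <- lapply(seq_len(n), function(i) {
    o <- order(d[i, ])
    o <- o[o != i]
    o[seq_len(k)]
  })
  edges <- do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, nbr[[i]])
  }))
  edges <- t(apply(edges, 1L, sort))
  edges <- unique(edges)
  w <- vapply(seq_len(nrow(edges)), function(e) {
    a <- nbr[[edges[e, 1L]]]
    b <- nbr[[edges[e, 2L]]]
    length(intersect(a, b)) / length(union(a, b))
  }, numeric(1L))
  keep <- w > 0
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (any(keep)) {
    g <- igraph::add_edges(g, t(edges[keep, , drop = FALSE]))
    igraph::E(g)$weight <- w[keep]
  }
  nm <- rownames(embedding)
  igraph::V(g)$name <- if (is.null(nm)) as.character(seq_len(n)) else nm
  g
}

#' Graph-based community clustering
#'
#' Louvain modularity optimization on the shared-nearest-neighbor graph at
#' the given resolution. A graph with no edges yields the trivial partition
#' of singletons, with a warning.
#'
#' @param graph Weighted undirected graph from [knn_graph()].
#' @param resolution Modularity resolution (default 1).
#' @param seed Integer seed controlling the (stochastic) node sweep order.
#' @return A cluster assignment: list with `labels` (integer, `0..K-1`,
#'   relabeled by first occurrence), `K`, and `cell_ids`.
#' @export
graph_cluster <- function(graph, resolution = 1, seed = 0L) {
  n <- igraph::vcount(graph)
  if (n == 0L) stop("empty graph", call. = FALSE)
  ids <- igraph::V(graph)$name
  if (igraph::ecount(graph) == 0L) {
    warning("graph has no edges; every cell is its own cluster",
            call. = FALSE)
    return(cluster_assignment(seq_len(n) - 1L, ids))
  }
  set.seed(seed)
  cl <- igraph::cluster_louvain(graph, resolution = resolution)
  memb <- igraph::membership(cl)
  cluster_assignment(match(memb, unique(memb)) - 1L, ids)
}

#' Construct a cluster assignment
#'
#' @param labels Integer labels per cell; relabeled to `0..K-1` by first
#'   occurrence.
#' @param cell_ids Cell identifiers aligned to `labels`.
#' @return Object of class `"cascc_clusters"` with `labels`, `K`,
#'   `cell_ids`.
#' @export
cluster_assignment <- function(labels, cell_ids) {
  if (length(labels) != length(cell_ids)) {
    stop("labels and cell_ids lengths differ", call. = FALSE)
  }
  labels <- as.integer(match(labels, unique(labels)) - 1L)
  structure(list(labels = labels, K = length(unique(labels)),
                 cell_ids = as.character(cell_ids)),
            class = "cascc_clusters")
}

#' @export
print.cascc_clusters <- function(x, ...) {
  cat(sprintf("<cascc_clusters> %d cells in %d clusters\n",
              length(x$labels), x$K))
  print(table(label = x$labels))
  invisible(x)
}

#' Rank per-cluster marker genes
#'
#' One-vs-rest Wilcoxon rank-sum test per gene and cluster (normal
#' approximation with tie correction and continuity correction, the
#' large-sample form of `stats::wilcox.test`), Benjamini-Hochberg adjusted
#' within each cluster. Genes with positive log fold change (difference of
#' mean log-normalized expression, cluster minus rest) are ranked by
#' adjusted p ascending, ties by logFC descending, then gene id.
#'
#' @param m Lognorm-layer [expression_matrix()].
#' @param clusters A [cluster_assignment()] over the same cells, `K >= 2`.
#' @param n_top Markers to keep per cluster (default 10).
#' @return Object of class `"cascc_seeds"`: a list, one data frame per
#'   cluster with columns `gene_id`, `logFC`, `p_adj`.
#' @export
rank_degs <- function(m, clusters, n_top = 10L) {
  .check_layer(m, "lognorm")
  if (!identical(clusters$cell_ids, m$cell_ids)) {
    stop("cluster assignment cells do not match matrix cells",
         call. = FALSE)
  }
  if (clusters$K < 2L) {
    stop("DEG ranking needs at least 2 clusters; with K = 1 use ",
         "top-variance genes as seeds instead", call. = FALSE)
  }
  v <- m$values
  n <- ncol(v)
  r <- t(apply(v, 1L, rank))           # within-gene ranks across all cells
  # tie correction term per gene: sum(t^3 - t) over tie groups
  tie_term <- apply(v, 1L, function(x) {
    tt <- table(x)
    sum(tt^3 - tt)
  })
  out <- vector("list", clusters$K)
  names(out) <- as.character(seq_len(clusters$K) - 1L)
  for (cl in seq_len(clusters$K) - 1L) {
    in_cl <- clusters$labels == cl
    n1 <- sum(in_cl)
    n2 <- n - n1
    U <- rowSums(r[, in_cl, drop = FALSE]) - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    sigma <- sqrt(n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1))))
    z <- U - mu
    z <- ifelse(sigma > 0, (z - sign(z) * 0.5) / sigma, 0)
    p <- 2 * stats::pnorm(-abs(z))
    p[sigma == 0] <- 1                  # constant gene: no evidence
    p_adj <- stats::p.adjust(pmin(p, 1), method = "BH")
    lfc <- rowMeans(v[, in_cl, drop = FALSE]) -
      rowMeans(v[, !in_cl, drop = FALSE])
    keep <- lfc > 0
    ord <- order(p_adj[keep], -lfc[keep], m$gene_ids[keep])
    idx <- which(keep)[ord][seq_len(min(n_top, sum(keep)))]
    out[[as.character(cl)]] <- data.frame(
      gene_id = m$gene_ids[idx], logFC = lfc[idx], p_adj = p_adj[idx],
      stringsAsFactors = FALSE)
  }
  structure(out, class = "cascc_seeds")
}
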