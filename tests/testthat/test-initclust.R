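test_that("pca embedding is exact on low rank and ordered by variance", {
  set.seed(1)
  # rank-2 matrix: two components explain all variance
  base <- matrix(rnorm(2 * 40), 2, 40)
  load <- matrix(rnorm(30 * 2), 30, 2)
  v <- pmax(load %*% base + 5, 0)
  m <- expression_matrix(v, sprintf("g%d", 1:30), sprintf("c%d", 1:40),
                         layer = "lognorm")
  emb <- pca_embed(m, n_components = 5)
  vars <- apply(emb, 2, var)
  expect_lt(sum(vars[3:5]) / sum(vars), 1e-3)
  expect_true(all(diff(vars) <= 1e-8))
  # duplicated cells map to identical embedding rows
  v2 <- cbind(v, v[, 1])
  m2 <- expression_matrix(v2, m$gene_ids, c(m$cell_ids, "dup"),
                          layer = "lognorm")
  emb2 <- pca_embed(m2, n_components = 3)
  expect_equal(emb2["dup", ], emb2["c1", ], tolerance = 1e-8)
  # constant matrix is rejected
  mc <- expression_matrix(matrix(1, 5, 5), sprintf("g%d", 1:5),
                          sprintf("c%d", 1:5), layer = "lognorm")
  expect_error(pca_embed(mc), "degenerate")
  # deterministic including the sign convention
  expect_identical(pca_embed(m, 4), pca_embed(m, 4))
})

test_that("knn graph connects neighbors and separates far groups", {
  # 3 equidistant points, k = 2: complete graph
  tri <- matrix(c(0, 0, 1, 0, 0.5, sqrt(3) / 2), 3, 2, byrow = TRUE)
  g <- knn_graph(tri, k = 2)
  expect_equal(igraph::ecount(g), 3)
  # two tight far-apart groups: no positive-weight cross edges
  set.seed(2)
  pts <- rbind(matrix(rnorm(20, sd = 0.1), 10, 2),
               matrix(rnorm(20, mean = 50, sd = 0.1), 10, 2))
  g2 <- knn_graph(pts, k = 5)
  ends <- igraph::as_edgelist(g2, names = FALSE)
  expect_true(all((ends[, 1] <= 10) == (ends[, 2] <= 10)))
  expect_error(knn_graph(pts, k = 0), "positive")
  expect_error(knn_graph(pts, k = 20), "smaller")
  # duplicate points: deterministic via index-order tie breaking
  dup <- matrix(rep(c(0, 1, 2), each = 4), 6, 2)
  expect_identical(igraph::as_edgelist(knn_graph(dup, 2)),
                   igraph::as_edgelist(knn_graph(dup, 2)))
})

test_that("graph clustering recovers components and planted blocks", {
  # two disconnected cliques
  g <- igraph::make_full_graph(5) + igraph::make_full_graph(5)
  igraph::V(g)$name <- sprintf("c%d", 1:10)
  igraph::E(g)$weight <- 1
  cl <- graph_cluster(g, seed = 1)
  expect_identical(cl$K, 2L)
  expect_identical(cl$labels[1:5], rep(0L, 5))
  # one clique -> one cluster
  g1 <- igraph::make_full_graph(6)
  igraph::V(g1)$name <- sprintf("c%d", 1:6)
  igraph::E(g1)$weight <- 1
  expect_identical(graph_cluster(g1, seed = 1)$K, 1L)
  # edgeless graph: singletons with a warning
  g0 <- igraph::make_empty_graph(4, directed = FALSE)
  igraph::V(g0)$name <- sprintf("c%d", 1:4)
  expect_warning(cl0 <- graph_cluster(g0), "no edges")
  expect_identical(cl0$K, 4L)
})

test_that("planted 3-block graphs are recovered across seeds", {
  blocks <- rep(1:3, each = 30)
  aris <- vapply(1:10, function(s) {
    set.seed(s)
    n <- 90
    p <- ifelse(outer(blocks, blocks, "=="), 0.5, 0.01)
    adj <- matrix(runif(n * n) < p, n, n)
    adj[lower.tri(adj, diag = TRUE)] <- FALSE
    g <- igraph::graph_from_adjacency_matrix(adj | t(adj), "undirected")
    igraph::V(g)$name <- sprintf("c%d", 1:n)
    igraph::E(g)$weight <- 1
    cl <- graph_cluster(g, seed = s)
    ari(cl$labels, blocks)
  }, numeric(1))
  expect_gte(mean(aris >= 0.95), 0.9)
})

test_that("DEG ranking puts planted markers first and is order-invariant", {
  set.seed(6)
  n <- 20
  v <- matrix(rnbinom(30 * n, mu = 5, size = 20), 30, n)
  v[3, 1:10] <- rnbinom(10, mu = 60, size = 20)    # marker of cluster 0
  v[17, 11:20] <- rnbinom(10, mu = 60, size = 20)  # marker of cluster 1
  v[9, ] <- 4                                       # constant gene
  ln <- log_normalize(toy_counts(v))
  cl <- cluster_assignment(rep(0:1, each = 10), ln$cell_ids)
  degs <- rank_degs(ln, cl, n_top = 5)
  expect_identical(degs[["0"]]$gene_id[1], "g3")
  expect_identical(degs[["1"]]$gene_id[1], "g17")
  expect_false("g9" %in% unlist(lapply(degs, `[[`, "gene_id")))
  # p-values match wilcox.test on the same data
  w <- stats::wilcox.test(ln$values[3, 1:10], ln$values[3, 11:20])
  raw_p <- degs[["0"]]$p_adj[1] / 1  # top adjusted p; compare order only
  expect_lt(raw_p, 0.01)
  expect_lt(w$p.value, 0.01)
  # permuting the cells leaves the ranked lists unchanged
  set.seed(1)
  perm <- sample(n)
  ln2 <- expression_matrix(ln$values[, perm], ln$gene_ids,
                           ln$cell_ids[perm], layer = "lognorm")
  cl2 <- cluster_assignment(cl$labels[perm], ln$cell_ids[perm])
  degs2 <- rank_degs(ln2, cl2, n_top = 5)
  expect_identical(lapply(degs, `[[`, "gene_id"),
                   lapply(degs2, `[[`, "gene_id"))
  expect_error(rank_degs(ln, cluster_assignment(rep(0, n), ln$cell_ids)),
               "at least 2")
})

test_that("rank-sum adjusted p-values match a wilcox.test + BH oracle", {
  set.seed(8)
  n <- 60
  v <- matrix(rnbinom(25 * n, mu = 4, size = 5), 25, n)
  v[5, 1:30] <- rnbinom(30, mu = 12, size = 5)
  ln <- log_normalize(toy_counts(v))
  lab <- rep(0:1, each = 30)
  cl <- cluster_assignment(lab, ln$cell_ids)
  degs <- rank_degs(ln, cl, n_top = 25)
  # oracle: per-gene two-sided wilcox.test (normal approximation with
  # continuity correction), BH-adjusted over all genes
  p_ref <- vapply(seq_len(25), function(i) {
    suppressWarnings(stats::wilcox.test(
      ln$values[i, lab == 0], ln$values[i, lab == 1],
      exact = FALSE, correct = TRUE))$p.value
  }, numeric(1))
  p_ref <- stats::setNames(stats::p.adjust(p_ref, "BH"), ln$gene_ids)
  df <- degs[["0"]]
  expect_equal(df$p_adj, unname(p_ref[df$gene_id]), tolerance = 1e-4)
  expect_identical(df$gene_id[1], "g5")
})
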