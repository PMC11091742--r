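make_seeds_tab <- function(lists) {
  structure(lapply(lists, function(g) {
    data.frame(gene_id = g, logFC = seq(2, 1, length.out = length(g)),
               p_adj = seq(1e-8, 1e-4, length.out = length(g)),
               stringsAsFactors = FALSE)
  }), class = "cascc_seeds")
}

test_that("feature set unions attractors and markers with provenance", {
  J <- seq(0.9, 0.5, length.out = 10)
  att <- list(fake_signature(sprintf("a%02d", 1:10), J),
              fake_signature(sprintf("b%02d", 1:10), J))
  degs <- make_seeds_tab(list(`0` = sprintf("d%02d", 1:10),
                              `1` = sprintf("e%02d", 1:10),
                              `2` = sprintf("f%02d", 1:10)))
  fs <- build_feature_set(degs, att, n_deg = 10, n_attr = 10)
  expect_identical(nrow(fs), 50L)                  # disjoint union
  expect_identical(fs$gene_id[1:10], sprintf("a%02d", 1:10))
  # shared gene appears once, flagged "both"
  degs2 <- make_seeds_tab(list(`0` = c("a01", "x01")))
  fs2 <- build_feature_set(degs2, att[1], n_deg = 2, n_attr = 10)
  expect_identical(sum(fs2$gene_id == "a01"), 1L)
  expect_identical(fs2$provenance[fs2$gene_id == "a01"], "both")
  # no attractors: markers only, with a warning
  expect_warning(fs3 <- build_feature_set(degs, list(), n_deg = 5,
                                          n_attr = 10),
                 "markers only")
  expect_identical(nrow(fs3), 15L)
  expect_error(suppressWarnings(build_feature_set(NULL, list())),
               "empty feature set")
})

test_that("K equals the number of surviving attractors, with fallback", {
  J <- seq(0.9, 0.5, length.out = 10)
  att <- lapply(c("a", "b", "c"), function(p) {
    fake_signature(sprintf("%s%02d", p, 1:10), J)
  })
  fb <- cluster_assignment(rep(0:3, each = 5), sprintf("c%d", 1:20))
  expect_identical(estimate_k(att, fb), 3L)
  expect_warning(k0 <- estimate_k(list(), fb), "falling back")
  expect_identical(k0, 4L)
  expect_warning(k1 <- estimate_k(att[1], fb), "falling back")
  expect_identical(k1, 4L)
})

test_that("attractor cell scores peak in the marked population", {
  m <- toy_module_matrix(seed = 42)
  sig <- converge_attractor(m, "mod01", a = 2, top_n = 10)
  sc <- attractor_cell_scores(m, sig, n_top = 10)
  expect_length(sc, 500L)
  # the cell with the largest module expression scores highest
  module_mean <- colMeans(m$values[sprintf("mod%02d", 1:10), ])
  expect_gt(cor(sc, module_mean), 0.95)
  # identical cells score identically
  m2 <- expression_matrix(m$values[, c(1, 1, 2)], m$gene_ids,
                          c("x", "y", "z"), layer = "lognorm")
  sig2 <- sig
  sc2 <- attractor_cell_scores(m2, sig2, n_top = 10)
  expect_identical(sc2[["x"]], sc2[["y"]])
  # non-converged or missing-gene signatures are rejected
  bad <- sig; bad$status <- "oscillating"
  expect_error(attractor_cell_scores(m, bad), "not converged")
  gone <- sig; gone$ranked_genes[1] <- "absent"
  expect_error(attractor_cell_scores(m, gone, n_top = 5), "absent")
})

test_that("seeded kmeans recovers well-separated clouds exactly", {
  set.seed(9)
  n_half <- 30
  v <- cbind(matrix(rnbinom(20 * n_half, mu = 2, size = 10), 20, n_half),
             matrix(rnbinom(20 * n_half, mu = 2, size = 10), 20, n_half))
  v[1:5, seq_len(n_half)] <- rnbinom(5 * n_half, mu = 40, size = 10)
  v[6:10, n_half + seq_len(n_half)] <- rnbinom(5 * n_half, mu = 40,
                                               size = 10)
  ln <- log_normalize(toy_counts(v))
  J <- seq(0.9, 0.6, length.out = 5)
  att <- list(fake_signature(sprintf("g%d", 1:5), J),
              fake_signature(sprintf("g%d", 6:10), J))
  km <- kmeans_seeded(ln, sprintf("g%d", 1:10), att, K = 2)
  truth <- rep(0:1, each = n_half)
  expect_identical(ari(km$assignment$labels, truth), 1)
  expect_length(km$centers_cell_ids, 2L)
  # SSE is non-increasing over Lloyd iterations
  expect_true(all(diff(km$sse_trace) <= 1e-8))
})

test_that("seeded kmeans equals the exhaustive SSE optimum on tiny data", {
  set.seed(4)
  v <- cbind(matrix(rnbinom(8 * 6, mu = 1, size = 10), 8, 6),
             matrix(rnbinom(8 * 6, mu = 1, size = 10), 8, 6))
  v[1:4, 1:6] <- rnbinom(24, mu = 30, size = 10)
  v[5:8, 7:12] <- rnbinom(24, mu = 30, size = 10)
  ln <- log_normalize(toy_counts(v))
  att <- list(fake_signature(sprintf("g%d", 1:4), rep(0.8, 4)),
              fake_signature(sprintf("g%d", 5:8), rep(0.8, 4)))
  km <- kmeans_seeded(ln, sprintf("g%d", 1:8), att, K = 2)
  # brute-force best 2-partition by SSE on the same feature matrix
  X <- t(cascc:::.zscore_rows(ln$values, 10))
  best <- NULL
  best_sse <- Inf
  for (code in 1:(2^11)) {
    lab <- as.integer(intToBits(code))[1:12]
    if (length(unique(lab)) < 2) next
    sse <- sum(vapply(0:1, function(k) {
      xs <- X[lab == k, , drop = FALSE]
      sum(sweep(xs, 2, colMeans(xs))^2)
    }, numeric(1)))
    if (sse < best_sse - 1e-12) {
      best_sse <- sse
      best <- lab
    }
  }
  expect_identical(ari(km$assignment$labels, best), 1)
})

test_that("kmeans edge cases: K = n, duplicates, bad K", {
  set.seed(5)
  v <- matrix(rnbinom(6 * 8, mu = 5, size = 10) + 1, 6, 8)
  ln <- log_normalize(toy_counts(v))
  att <- list(fake_signature(sprintf("g%d", 1:6), rep(0.8, 6)))
  km <- kmeans_seeded(ln, sprintf("g%d", 1:6), att, K = 8)
  expect_identical(km$assignment$K, 8L)            # each cell its own
  expect_lt(max(km$sse_trace), 1e-12)
  expect_error(kmeans_seeded(ln, sprintf("g%d", 1:6), att, K = 9),
               "between 1")
  # duplicated points share a label
  v2 <- cbind(v, v)
  ln2 <- log_normalize(toy_counts(v2))
  km2 <- kmeans_seeded(ln2, sprintf("g%d", 1:6), att, K = 2)
  expect_identical(km2$assignment$labels[1:8], km2$assignment$labels[9:16])
})

test_that("2d embedding separates clouds, is deterministic, allows n=3", {
  set.seed(3)
  x <- rbind(matrix(rnorm(40 * 4), 40, 4),
             matrix(rnorm(40 * 4, mean = 25), 40, 4))
  y <- embed_2d(x, seed = 1, max_iter = 500)
  c1 <- colMeans(y[1:40, ]); c2 <- colMeans(y[41:80, ])
  spread <- max(sqrt(rowSums(sweep(y[1:40, ], 2, c1)^2)),
                sqrt(rowSums(sweep(y[41:80, ], 2, c2)^2)))
  expect_gt(sqrt(sum((c1 - c2)^2)), spread)
  expect_identical(embed_2d(x, seed = 1, max_iter = 500), y)
  expect_identical(dim(embed_2d(matrix(rnorm(9), 3, 3), seed = 1,
                                max_iter = 50)), c(3L, 2L))
  expect_error(embed_2d(x, method = "umap"), "capability")
})
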