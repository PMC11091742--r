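test_that("metagene update concentrates weight as the exponent grows", {
  m <- toy_module_matrix(n_mod = 4, n_bg = 8, n_cells = 120, seed = 7)
  up <- metagene_update(m, m$values["mod01", ], a = 2)
  expect_length(up$J, 12L)
  expect_true(all(up$J[sprintf("mod%02d", 1:4)] > 0))
  # identical rows: new metagene equals the shared row
  shared <- expression_matrix(matrix(rep(seq_len(50), each = 3), 3, 50,
                                     byrow = FALSE),
                              c("a", "b", "c"), sprintf("c%d", 1:50),
                              layer = "lognorm")
  shared$values[] <- rep(log1p(seq_len(50)), each = 3)
  up2 <- metagene_update(shared, shared$values["a", ], a = 2)
  expect_equal(up2$scores, unname(shared$values["a", ]), tolerance = 1e-12)
  # a -> large concentrates all weight on the top-associated gene
  up3 <- metagene_update(m, m$values["mod01", ], a = 50)
  expect_equal(up3$scores, unname(m$values["mod01", ]), tolerance = 1e-6)
})

test_that("metagene update errors on degenerate states", {
  m <- toy_module_matrix(n_mod = 4, n_bg = 8, n_cells = 120, seed = 7)
  expect_error(metagene_update(m, rep(1, 120), a = 2), "unassociated")
  expect_error(metagene_update(m, m$values["mod01", 1:10], a = 2),
               "number of cells")
  expect_error(metagene_update(m, m$values["mod01", ], a = -1),
               "positive")
})

test_that("metagene stays inside the convex hull of gene rows", {
  m <- toy_module_matrix(seed = 19)
  up <- metagene_update(m, m$values["mod03", ], a = 3)
  lo <- apply(m$values, 2, min)
  hi <- apply(m$values, 2, max)
  expect_true(all(up$scores >= lo - 1e-10 & up$scores <= hi + 1e-10))
  expect_equal(sum(up$J^3 / sum(up$J^3)), 1)
})

test_that("attractor converges from any module seed to the module", {
  m <- toy_module_matrix(seed = 42)
  sigs <- lapply(c("mod01", "mod05", "mod09"), function(s) {
    converge_attractor(m, s, a = 2, top_n = 10)
  })
  for (s in sigs) {
    expect_identical(s$status, "converged")
    expect_gte(sum(grepl("^mod", s$ranked_genes[1:10])), 9)
  }
  # seed-independence: any two module seeds share the top set
  expect_gte(length(intersect(sigs[[1]]$ranked_genes[1:10],
                              sigs[[2]]$ranked_genes[1:10])), 9)
  expect_gte(length(intersect(sigs[[1]]$ranked_genes[1:10],
                              sigs[[3]]$ranked_genes[1:10])), 9)
  # associations are ranked non-increasing
  expect_true(all(diff(sigs[[1]]$associations) <= 1e-12))
})

test_that("a converged attractor is a fixed point of the update", {
  m <- toy_module_matrix(seed = 42)
  sig <- converge_attractor(m, "mod02", a = 2, top_n = 10)
  expect_identical(sig$status, "converged")
  up <- metagene_update(m, sig$metagene, a = sig$exponent)
  top_before <- sig$ranked_genes[1:10]
  top_after <- names(sort(-up$J))[1:10]
  expect_setequal(top_after, top_before)
})

test_that("missing or constant seeds are rejected", {
  m <- toy_module_matrix(n_cells = 100, seed = 1)
  expect_error(converge_attractor(m, "nope"), "not in matrix")
  m$values["bg01", ] <- 3
  expect_error(converge_attractor(m, "bg01"), "constant")
})

test_that("exponent adaptation escapes a generic broad signature", {
  m <- toy_global_plus_module(seed = 42)
  lo <- converge_attractor(m, "mod01", a = 2, top_n = 10)
  breadth_lo <- sum(lo$associations >= 0.5 * lo$associations[1])
  expect_gt(breadth_lo, 20)              # generic signature at a_min
  ad <- adapt_exponent(m, "mod01", a_min = 2, breadth_cap = 20, top_n = 10)
  expect_identical(ad$status, "converged")
  expect_gt(ad$exponent, 2)
  expect_identical(sort(ad$ranked_genes[1:10]),
                   sprintf("mod%02d", 1:10))
  # degenerate range behaves exactly like plain convergence
  one <- adapt_exponent(m, "mod01", a_min = 3, a_max = 3, top_n = 10)
  ref <- converge_attractor(m, "mod01", a = 3, top_n = 10)
  expect_identical(one$ranked_genes, ref$ranked_genes)
  expect_identical(one$exponent, 3)
})

test_that("already-narrow signatures keep the minimal exponent", {
  m <- toy_module_matrix(seed = 42)
  ad <- adapt_exponent(m, "mod04", a_min = 2, breadth_cap = 100,
                       top_n = 10)
  expect_identical(ad$exponent, 2)
  expect_identical(ad$status, "converged")
})

test_that("deduplication merges by single-link overlap and strength", {
  g1 <- sprintf("a%02d", 1:10)
  g2 <- sprintf("b%02d", 1:10)
  J <- seq(0.9, 0.5, length.out = 10)
  s_a <- fake_signature(g1, J)
  s_a2 <- fake_signature(g1, J - 0.05, seed = "a02")
  s_b <- fake_signature(g2, J)
  # identical top sets -> one survivor, the stronger one
  out <- dedup_attractors(list(s_a2, s_a), top_n = 10)
  expect_length(out, 1L)
  expect_identical(out[[1]]$seed, "a01")
  # disjoint sets -> both survive, ordered by strength
  out2 <- dedup_attractors(list(fake_signature(g2, J - 0.1), s_a),
                           top_n = 10)
  expect_length(out2, 2L)
  expect_identical(out2[[1]]$seed, "a01")
  # chained overlap A~B~C groups all three even if A~C is weak
  gA <- sprintf("x%02d", 1:10)
  gB <- c(gA[1:8], "y01", "y02")                 # Jaccard(A,B) = 8/12
  gC <- c("y01", "y02", gA[1:5], sprintf("z%02d", 1:3))
  sA <- fake_signature(gA, J)
  sB <- fake_signature(gB, J - 0.01, seed = gB[1])
  sC <- fake_signature(gC, J - 0.02, seed = gC[1])
  jac <- function(u, v) length(intersect(u, v)) / length(union(u, v))
  expect_gte(jac(gA, gB), 0.5)
  expect_gte(jac(gB, gC), 0.5)
  expect_lt(jac(gA, gC), 0.5)                    # chain, not a clique
  out3 <- dedup_attractors(list(sA, sB, sC), top_n = 10,
                           jaccard_min = 0.5)
  expect_length(out3, 1L)
  # order independence of the single-link grouping
  out3b <- dedup_attractors(list(sC, sA, sB), top_n = 10,
                            jaccard_min = 0.5)
  expect_identical(out3[[1]]$ranked_genes, out3b[[1]]$ranked_genes)
})

test_that("deduplication discards weak and non-converged signatures", {
  g1 <- sprintf("a%02d", 1:10)
  J <- seq(0.9, 0.5, length.out = 10)
  weak <- fake_signature(g1, J / 50, noise_floor = 0.01)
  bad <- fake_signature(g1, J, status = "oscillating")
  good <- fake_signature(sprintf("b%02d", 1:10), J)
  out <- dedup_attractors(list(weak, bad, good), top_n = 10)
  expect_length(out, 1L)
  expect_identical(out[[1]]$seed, "b01")
  expect_identical(dedup_attractors(list()), list())
})

test_that("parallel seed scanning equals serial scanning exactly", {
  m <- toy_module_matrix(n_mod = 12, n_bg = 36, n_cells = 200, seed = 31)
  seeds <- list(c("mod01", "mod04"), c("mod06", "bg05"))
  serial <- find_attractors(m, seeds, top_n = 10, threads = 1)
  parallel <- find_attractors(m, seeds, top_n = 10, threads = 4)
  expect_identical(serial, parallel)
  expect_gte(length(serial), 1L)
})
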