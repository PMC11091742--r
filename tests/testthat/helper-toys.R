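# Programmatic fixtures shared across the test files. Everything is built
# in code at test time; no data files.

# dense planted-module toy: `n_mod` correlated genes driven by one latent
# factor plus `n_bg` independent noise genes; values shifted positive so
# they form a valid lognorm layer
toy_module_matrix <- function(n_mod = 10L, n_bg = 90L, n_cells = 500L,
                              noise_sd = 0.5, seed = 42L) {
  set.seed(seed)
  f <- rnorm(n_cells)
  mod <- t(sapply(seq_len(n_mod), function(i) f + rnorm(n_cells, sd = noise_sd)))
  bg <- matrix(rnorm(n_bg * n_cells), n_bg, n_cells)
  v <- pmax(rbind(mod, bg) + 4, 0)
  ids <- c(sprintf("mod%02d", seq_len(n_mod)), sprintf("bg%02d", seq_len(n_bg)))
  expression_matrix(v, ids, sprintf("c%03d", seq_len(n_cells)),
                    layer = "lognorm")
}

# toy with a global factor loading on every gene plus one specific module,
# for exercising the breadth-triggered exponent adaptation
toy_global_plus_module <- function(n_mod = 10L, n_bg = 90L, n_cells = 500L,
                                   seed = 42L) {
  set.seed(seed)
  f <- rnorm(n_cells)
  g <- rnorm(n_cells)
  mod <- t(sapply(seq_len(n_mod), function(i) {
    f + 0.4 * g + rnorm(n_cells, sd = 0.4)
  }))
  bg <- t(sapply(seq_len(n_bg), function(i) g + rnorm(n_cells, sd = 0.4)))
  v <- pmax(rbind(mod, bg) + 4, 0)
  ids <- c(sprintf("mod%02d", seq_len(n_mod)), sprintf("bg%02d", seq_len(n_bg)))
  expression_matrix(v, ids, sprintf("c%03d", seq_len(n_cells)),
                    layer = "lognorm")
}

# tiny counts matrix with explicit values
toy_counts <- function(values, genes = NULL, cells = NULL) {
  values <- as.matrix(values)
  if (is.null(genes)) genes <- sprintf("g%d", seq_len(nrow(values)))
  if (is.null(cells)) cells <- sprintf("c%d", seq_len(ncol(values)))
  expression_matrix(values, genes, cells, layer = "counts")
}

# a hand-built attractor signature object for dedup tests
fake_signature <- function(genes, J, seed = genes[1L], status = "converged",
                           noise_floor = 1e-3, exponent = 2) {
  structure(list(ranked_genes = genes, associations = J, seed = seed,
                 exponent = exponent, n_iterations = 5L, status = status,
                 metagene = NULL, noise_floor = noise_floor),
            class = "cascc_attractor")
}

# Exhaustive pair-enumeration oracle for the adjusted Rand index: count
# agreeing/disagreeing item pairs directly.
ari_pair_oracle <- function(a, b) {
  n <- length(a)
  same_a <- outer(a, a, "==")[upper.tri(diag(n))]
  same_b <- outer(b, b, "==")[upper.tri(diag(n))]
  n11 <- sum(same_a & same_b)
  n00 <- sum(!same_a & !same_b)
  n10 <- sum(same_a & !same_b)
  n01 <- sum(!same_a & same_b)
  tot <- n11 + n00 + n10 + n01
  expected <- (n11 + n10) * (n11 + n01) / tot
  maxind <- ((n11 + n10) + (n11 + n01)) / 2
  if (maxind == expected) return(if (n10 + n01 == 0) 1 else 0)
  (n11 - expected) / (maxind - expected)
}

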