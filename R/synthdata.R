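#' Specify a synthetic scRNA-seq dataset
#'
#' Describes a counts matrix with `n_types` planted cell populations, each
#' marked by a disjoint module of `module_size` co-expressed genes. Within
#' a cell of type `t`, the module genes of `t` share a latent factor
#' `f ~ N(1, sd = 0.1)` and are negative-binomially
#' distributed with mean `baseline_mean * exp(module_strength * f)`; all
#' other genes are background NB(`baseline_mean`, `dispersion`).
#' Independent Bernoulli dropout zeroes each entry with probability
#' `dropout_rate`.
#'
#' @param n_cells,n_genes Matrix dimensions (defaults 600 x 1000).
#' @param n_types Number of planted populations C (default 3).
#' @param module_size Genes per planted module (default 20);
#'   `n_types * module_size <= n_genes`.
#' @param module_strength Latent-factor loading (default 1.5); 0 removes
#'   all population signal.
#' @param baseline_mean Background NB mean (default 3).
#' @param dispersion NB size parameter (default 10; larger is closer to
#'   Poisson).
#' @param dropout_rate Bernoulli zeroing probability in `[0, 1)`
#'   (default 0.3).
#' @param type_proportions Simplex vector of length `n_types` (default
#'   uniform).
#' @param seed RNG seed baked into the spec (default 1).
#' @return Object of class `"cascc_synthspec"`.
#' @export
synth_spec <- function(n_cells = 600L, n_genes = 1000L, n_types = 3L,
                       module_size = 20L, module_strength = 1.5,
                       baseline_mean = 3, dispersion = 10,
                       dropout_rate = 0.3, type_proportions = NULL,
                       seed = 1L) {
  if (is.null(type_proportions)) {
    type_proportions <- rep(1 / n_types, n_types)
  }
  spec <- list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
               n_types = as.integer(n_types),
               module_size = as.integer(module_size),
               module_strength = module_strength,
               baseline_mean = baseline_mean, dispersion = dispersion,
               dropout_rate = dropout_rate,
               type_proportions = type_proportions, seed = as.integer(seed))
  if (spec$n_types * spec$module_size > spec$n_genes) {
    stop("n_types * module_size exceeds n_genes", call. = FALSE)
  }
  if (abs(sum(type_proportions) - 1) > 1e-8 || any(type_proportions <= 0) ||
      length(type_proportions) != spec$n_types) {
    stop("type_proportions must be a positive vector of length n_types ",
         "summing to 1", call. = FALSE)
  }
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop("dropout_rate must be in [0, 1)", call. = FALSE)
  }
  if (baseline_mean <= 0 || dispersion <= 0 || module_strength < 0) {
    stop("baseline_mean and dispersion must be positive, module_strength ",
         "non-negative", call. = FALSE)
  }
  structure(spec, class = "cascc_synthspec")
}

#' Preset synthetic-data conditions
#'
#' `"strong"` is the reference condition for end-to-end validation: 3
#' populations of 600 cells over 1000 genes, 20-gene modules at loading
#' 1.5, 30% dropout. `"weak"` halves the loading to 0.6 (signal near the
#' detection limit); `"null"` sets it to 0 (no structure at all).
#'
#' @param preset One of `"strong"`, `"weak"`, `"null"`.
#' @param ... Overrides passed to [synth_spec()] (e.g. `n_types = 5`,
#'   `seed = 7`).
#' @return A `"cascc_synthspec"`.
#' @export
synth_preset <- function(preset = c("strong", "weak", "null"), ...) {
  preset <- match.arg(preset)
  strength <- switch(preset, strong = 1.5, weak = 0.6, null = 0)
  synth_spec(module_strength = strength, ...)
}

#' Generate a synthetic counts matrix with planted cell types
#'
#' Draws the dataset described by a [synth_spec()]: deterministic given the
#' spec's seed. Gene ids are `module<t>_g<j>` for planted module genes and
#' `bg_g<j>` for background genes; cell ids are `cell<i>`.
#'
#' @param spec A `"cascc_synthspec"`.
#' @return List with `matrix` (counts-layer [expression_matrix()]) and
#'   `truth` (list: `type_label` named per cell, `module_genes` per type,
#'   `spec` echo).
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "cascc_synthspec"))
  set.seed(spec$seed)
  n <- spec$n_cells
  g <- spec$n_genes
  C <- spec$n_types
  ms <- spec$module_size
  types <- sample.int(C, n, replace = TRUE, prob = spec$type_proportions)
  module_genes <- lapply(seq_len(C), function(t) {
    sprintf("module%d_g%02d", t, seq_len(ms))
  })
  gene_ids <- c(unlist(module_genes),
                sprintf("bg_g%04d", seq_len(g - C * ms)))
  mu <- matrix(spec$baseline_mean, g, n)
  f <- stats::rnorm(n, mean = 1, sd = 0.1)   # latent factor per cell
  for (t in seq_len(C)) {
    idx_g <- ((t - 1L) * ms + 1L):(t * ms)
    idx_c <- which(types == t)
    mu[idx_g, idx_c] <- spec$baseline_mean *
      exp(spec$module_strength * rep(f[idx_c], each = ms))
  }
  counts <- matrix(stats::rnbinom(g * n, mu = mu, size = spec$dispersion),
                   g, n)
  if (spec$dropout_rate > 0) {
    counts[stats::runif(g * n) < spec$dropout_rate] <- 0L
  }
  cell_ids <- sprintf("cell%04d", seq_len(n))
  truth <- list(type_label = stats::setNames(types, cell_ids),
                module_genes = stats::setNames(module_genes,
                                               paste0("type", seq_len(C))),
                spec = unclass(spec))
  list(matrix = expression_matrix(counts, gene_ids, cell_ids,
                                  layer = "counts"),
       truth = truth)
}

#' Write a synthetic dataset as an on-disk fixture
#'
#' Emits the 10x-style Matrix Market triplet (via [write_matrix()]) plus
#' `truth_labels.csv` (`cell_id,label`) and `truth_modules.json`. The files
#' round-trip exactly through [load_matrix()] and [load_labels()], and are
#' byte-identical across runs at the same spec seed.
#'
#' @param m Counts-layer [expression_matrix()].
#' @param truth Truth list as returned by [generate_synthetic()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(m, truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix(m, dir, format = "mtx_dir")
  utils::write.csv(data.frame(cell_id = names(truth$type_label),
                              label = unname(truth$type_label)),
                   file.path(dir, "truth_labels.csv"), row.names = FALSE,
                   quote = FALSE)
  jsonlite::write_json(truth$module_genes,
                       file.path(dir, "truth_modules.json"))
  invisible(dir)
}
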