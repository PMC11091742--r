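#' Filter low-information genes and cells
#'
#' Standard single-cell QC applied once, genes first: genes detected
#' (count > 0) in fewer than `min_cells_per_gene` cells are removed, then
#' cells expressing fewer than `min_genes_per_cell` of the remaining genes
#' are removed. The removal report is attached as the `"filter_report"`
#' attribute of the result.
#'
#' @param m Counts-layer [expression_matrix()].
#' @param min_cells_per_gene Minimum cells a gene must be detected in
#'   (default 3).
#' @param min_genes_per_cell Minimum genes a cell must express (default 200).
#' @return Filtered counts matrix with a `filter_report` attribute listing
#'   `genes_removed` and `cells_removed`.
#' @export
filter_matrix <- function(m, min_cells_per_gene = 3L,
                          min_genes_per_cell = 200L) {
  .check_layer(m, "counts")
  detected <- m$values > 0
  keep_g <- rowSums(detected) >= min_cells_per_gene
  if (!any(keep_g)) {
    stop("all genes removed at min_cells_per_gene = ", min_cells_per_gene,
         "; lower the threshold", call. = FALSE)
  }
  genes_removed <- m$gene_ids[!keep_g]
  v <- m$values[keep_g, , drop = FALSE]
  keep_c <- colSums(v > 0) >= min_genes_per_cell
  if (!any(keep_c)) {
    stop("all cells removed at min_genes_per_cell = ", min_genes_per_cell,
         "; lower the threshold", call. = FALSE)
  }
  cells_removed <- m$cell_ids[!keep_c]
  out <- expression_matrix(v[, keep_c, drop = FALSE],
                           m$gene_ids[keep_g], m$cell_ids[keep_c],
                           layer = "counts")
  attr(out, "filter_report") <- list(genes_removed = genes_removed,
                                     cells_removed = cells_removed)
  out
}

#' Log-normalize a counts matrix
#'
#' Each cell's counts are scaled to a common total (`scale`, default 1e4,
#' i.e. counts-per-10k) and transformed with `log1p` (natural log). All-zero
#' cells map to all-zero columns.
#'
#' @param m Counts-layer [expression_matrix()].
#' @param scale Target per-cell total after scaling; must be positive.
#' @return A `lognorm`-layer [expression_matrix()].
#' @export
log_normalize <- function(m, scale = 1e4) {
  .check_layer(m, "counts")
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0) {
    stop("'scale' must be a single positive number", call. = FALSE)
  }
  totals <- colSums(m$values)
  f <- ifelse(totals > 0, scale / totals, 0)
  v <- log1p(sweep(m$values, 2L, f, `*`))
  expression_matrix(v, m$gene_ids, m$cell_ids, layer = "lognorm")
}

#' Select highly variable genes
#'
#' Ranks genes by standardized dispersion: the dispersion (variance over
#' mean) of the normalized counts (`expm1` of the lognorm layer) is
#' z-scored within 20 bins of genes grouped by mean expression, so that
#' variability is compared among genes of similar abundance.
#'
#' @param m Lognorm-layer [expression_matrix()].
#' @param n Number of genes to keep (default 2000; capped at the number of
#'   genes present).
#' @return Character vector of selected gene ids, ordered by decreasing
#'   standardized dispersion.
#' @export
select_hvg <- function(m, n = 2000L) {
  .check_layer(m, "lognorm")
  norm_counts <- expm1(m$values)
  mu <- rowMeans(norm_counts)
  va <- .row_vars(norm_counts)
  disp <- ifelse(mu > 0, va / mu, 0)
  nb <- min(20L, max(1L, length(mu) %/% 10L))
  bin <- cut(rank(mu, ties.method = "first"), breaks = nb, labels = FALSE)
  z <- stats::ave(disp, bin, FUN = function(d) {
    s <- stats::sd(d)
    if (!is.finite(s) || s == 0) rep(0, length(d)) else (d - mean(d)) / s
  })
  ord <- order(-z, m$gene_ids)
  m$gene_ids[ord][seq_len(min(n, length(ord)))]
}

.row_vars <- function(x) {
  n <- ncol(x)
  if (n < 2L) return(rep(0, nrow(x)))
  mu <- rowMeans(x)
  (rowSums(x^2) - n * mu^2) / (n - 1L)
}

#' Analytic negative-binomial Pearson residuals
#'
#' Residuals of the counts under the null model `mu_gc = g_mean * c_size`
#' (gene mean times cell size factor) with NB variance `mu + mu^2/theta`:
#' \deqn{r_{gc} = (x_{gc} - \mu_{gc}) / \sqrt{\mu_{gc} + \mu_{gc}^2/\theta}.}
#' Unlike log-normalization this keeps the magnitude of strongly elevated
#' counts on a comparable scale across genes, which is what separates
#' populations in the K-means step. Residuals are clipped at
#' `+/- sqrt(n_cells)` by default.
#'
#' @param m Counts-layer [expression_matrix()].
#' @param theta NB shape of the null model (default 100).
#' @param clip Clipping bound; `NULL` for `sqrt(n_cells)`.
#' @return Numeric matrix, genes x cells, same dimnames as `m$values`.
#' @export
pearson_residuals <- function(m, theta = 100, clip = NULL) {
  .check_layer(m, "counts")
  counts <- m$values
  tot <- colSums(counts)
  if (all(tot == 0)) stop("all cells are empty", call. = FALSE)
  sf <- tot / mean(tot)
  sf[sf == 0] <- min(sf[sf > 0])
  gm <- rowSums(counts) / sum(sf)
  mu <- outer(gm, sf)
  r <- (counts - mu) / sqrt(mu + mu^2 / theta)
  r[!is.finite(r)] <- 0                     # all-zero genes
  if (is.null(clip)) clip <- sqrt(ncol(counts))
  r[r > clip] <- clip
  r[r < -clip] <- -clip
  r
}

# per-gene z-score of lognorm rows, clipped; constant rows map to 0
.zscore_rows <- function(x, clip = 10) {
  mu <- rowMeans(x)
  sd <- sqrt(.row_vars(x))
  sd[sd == 0] <- 1
  z <- (x - mu) / sd
  z[z > clip] <- clip
  z[z < -clip] <- -clip
  z
}

# subset a cascc_matrix by gene ids (keeps layer)
.subset_genes <- function(m, gene_ids) {
  missing <- setdiff(gene_ids, m$gene_ids)
  if (length(missing)) {
    stop("gene id(s) absent from matrix: ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  expression_matrix(m$values[gene_ids, , drop = FALSE], gene_ids,
                    m$cell_ids, layer = m$layer)
}
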