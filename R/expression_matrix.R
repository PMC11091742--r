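#' Construct an expression matrix
#'
#' The container every stage of the pipeline consumes: a dense non-negative
#' numeric matrix with genes as rows and cells as columns (the 10x on-disk
#' convention), carrying unique gene and cell identifiers and a layer tag
#' recording whether the values are raw counts or log-normalized expression.
#'
#' @param values Numeric matrix, genes x cells, finite and non-negative.
#' @param gene_ids Character vector of unique gene identifiers, one per row.
#' @param cell_ids Character vector of unique cell identifiers, one per column.
#' @param layer Either `"counts"` or `"lognorm"`.
#'
#' @return An object of class `"cascc_matrix"`: a list with elements
#'   `values`, `gene_ids`, `cell_ids`, `layer`. Row and column names of
#'   `values` are set to the ids.
#' @export
expression_matrix <- function(values, gene_ids, cell_ids,
                              layer = c("counts", "lognorm")) {
  layer <- match.arg(layer)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) != length(gene_ids) || ncol(values) != length(cell_ids)) {
    stop("dimensions of 'values' (", nrow(values), " x ", ncol(values),
         ") do not match id lists (", length(gene_ids), " genes, ",
         length(cell_ids), " cells)", call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop("expression values must be finite (found NA/NaN/Inf)", call. = FALSE)
  }
  if (any(values < 0)) {
    stop("expression values must be non-negative", call. = FALSE)
  }
  gene_ids <- .dedup_ids(as.character(gene_ids), "gene")
  cell_ids <- .dedup_ids(as.character(cell_ids), "cell")
  dimnames(values) <- list(gene_ids, cell_ids)
  structure(list(values = values, gene_ids = gene_ids,
                 cell_ids = cell_ids, layer = layer),
            class = "cascc_matrix")
}

# duplicate ids get a ".<k>" suffix (never silently dropped), with a warning
.dedup_ids <- function(ids, what) {
  if (anyNA(ids) || any(!nzchar(ids))) {
    stop("missing or empty ", what, " ids", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    warning(length(dup), " duplicated ", what,
            " id(s) disambiguated with a numeric suffix (e.g. '",
            dup[1L], "')", call. = FALSE)
    ids <- make.unique(ids, sep = ".")
  }
  ids
}

#' @export
print.cascc_matrix <- function(x, ...) {
  cat(sprintf("<cascc_matrix> %d genes x %d cells, layer = %s\n",
              nrow(x$values), ncol(x$values), x$layer))
  nz <- mean(x$values != 0)
  cat(sprintf("  nonzero fraction: %.3f\n", nz))
  invisible(x)
}

#' @export
dim.cascc_matrix <- function(x) dim(x$values)

.check_layer <- function(m, layer) {
  if (!inherits(m, "cascc_matrix")) {
    stop("expected a 'cascc_matrix' object", call. = FALSE)
  }
  if (m$layer != layer) {
    stop("this operation requires the '", layer, "' layer, got '",
         m$layer, "'", call. = FALSE)
  }
  invisible(m)
}
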