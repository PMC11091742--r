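#' Read an expression matrix from disk
#'
#' Supports the 10x-style Matrix Market triplet layout (a directory holding
#' `matrix.mtx`, a `features.tsv`/`genes.tsv` sidecar and a `barcodes.tsv`
#' sidecar, each optionally gzipped) and dense CSV/TSV with gene rows, cell
#' columns and a header row of cell ids. Always returns the counts layer.
#'
#' @param path Directory (for `mtx_dir`) or file path.
#' @param format One of `"auto"`, `"mtx_dir"`, `"csv"`, `"tsv"`. With
#'   `"auto"`, a directory is read as `mtx_dir` and files are dispatched on
#'   their extension.
#' @return A [expression_matrix()] with `layer = "counts"`.
#' @export
load_matrix <- function(path, format = c("auto", "mtx_dir", "csv", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    if (dir.exists(path)) {
      format <- "mtx_dir"
    } else {
      ext <- tolower(sub(".*\\.", "", sub("\\.gz$", "", path)))
      format <- switch(ext, csv = "csv", tsv = "tsv", txt = "tsv",
                       stop("cannot infer format from '", path,
                            "'; pass format= explicitly", call. = FALSE))
    }
  }
  if (!file.exists(path)) {
    stop("input path does not exist: ", path, call. = FALSE)
  }
  switch(format,
         mtx_dir = .load_mtx_dir(path),
         csv = .load_dense(path, ","),
         tsv = .load_dense(path, "\t"))
}

.find_sidecar <- function(dir, stems) {
  for (stem in stems) {
    for (suffix in c("", ".gz")) {
      f <- file.path(dir, paste0(stem, suffix))
      if (file.exists(f)) return(f)
    }
  }
  NULL
}

.open_text <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}

.load_mtx_dir <- function(dir) {
  mtx <- .find_sidecar(dir, c("matrix.mtx"))
  feat <- .find_sidecar(dir, c("features.tsv", "genes.tsv"))
  bc <- .find_sidecar(dir, c("barcodes.tsv"))
  if (is.null(mtx)) {
    stop("format error: no matrix.mtx(.gz) in ", dir, call. = FALSE)
  }
  if (is.null(feat)) {
    stop("format error: no features.tsv/genes.tsv(.gz) in ", dir,
         call. = FALSE)
  }
  if (is.null(bc)) {
    stop("format error: no barcodes.tsv(.gz) in ", dir, call. = FALSE)
  }
  con <- .open_text(mtx)
  on.exit(close(con), add = TRUE)
  sp <- tryCatch(Matrix::readMM(con), error = function(e) {
    stop("data error reading ", mtx, ": ", conditionMessage(e),
         call. = FALSE)
  })
  features <- utils::read.delim(feat, header = FALSE,
                                colClasses = "character")
  barcodes <- utils::read.delim(bc, header = FALSE,
                                colClasses = "character")
  if (nrow(features) != nrow(sp) || nrow(barcodes) != ncol(sp)) {
    stop("data error: sidecar sizes (", nrow(features), " features, ",
         nrow(barcodes), " barcodes) do not match matrix dimensions ",
         nrow(sp), " x ", ncol(sp), call. = FALSE)
  }
  vals <- as.matrix(sp)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("data error: negative or non-finite entries in ", mtx,
         call. = FALSE)
  }
  expression_matrix(vals, features[[1L]], barcodes[[1L]], layer = "counts")
}

.load_dense <- function(path, sep) {
  # the header row may name only the cells (one field fewer than the data
  # rows) or carry a leading label for the gene-id column; peek to decide
  con <- .open_text(path)
  head2 <- readLines(con, n = 2L)
  close(con)
  if (length(head2) < 2L) {
    stop("format error: ", path, " has no data rows", call. = FALSE)
  }
  nf <- lengths(strsplit(head2, sep, fixed = TRUE))
  con <- .open_text(path)
  on.exit(close(con), add = TRUE)
  df <- utils::read.table(con, header = FALSE, sep = sep, skip = 1L,
                          check.names = FALSE, comment.char = "",
                          stringsAsFactors = FALSE)
  gene_ids <- as.character(df[[1L]])
  vals <- as.matrix(df[, -1L, drop = FALSE])
  hdr <- strsplit(head2[1L], sep, fixed = TRUE)[[1L]]
  cell_ids <- if (nf[1L] == nf[2L]) hdr[-1L] else hdr
  if (length(cell_ids) != ncol(vals)) {
    stop("format error: header of ", path, " names ", length(cell_ids),
         " cells but rows have ", ncol(vals), " value fields",
         call. = FALSE)
  }
  if (!is.numeric(vals)) {
    stop("data error: non-numeric entries in ", path, call. = FALSE)
  }
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("data error: negative or non-finite entries in ", path,
         call. = FALSE)
  }
  expression_matrix(vals, gene_ids, cell_ids, layer = "counts")
}

#' Write an expression matrix to disk
#'
#' Inverse of [load_matrix()]: emits either a 10x-style Matrix Market triplet
#' directory (`matrix.mtx`, `features.tsv` with id and symbol columns,
#' `barcodes.tsv`) or a dense delimited file with gene rows and a header row
#' of cell ids. A load of the written output reproduces values and ids
#' exactly, in the same order.
#'
#' @param m A [expression_matrix()].
#' @param path Output directory (`mtx_dir`) or file path (`csv`/`tsv`).
#' @param format One of `"mtx_dir"`, `"csv"`, `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, format = c("mtx_dir", "csv", "tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(m, "cascc_matrix"))
  if (format == "mtx_dir") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    sp <- methods::as(Matrix::Matrix(m$values, sparse = TRUE), "CsparseMatrix")
    Matrix::writeMM(sp, file.path(path, "matrix.mtx"))
    utils::write.table(data.frame(m$gene_ids, m$gene_ids),
                       file.path(path, "features.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    writeLines(m$cell_ids, file.path(path, "barcodes.tsv"))
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- as.data.frame(m$values, check.names = FALSE)
    utils::write.table(cbind(gene_id = m$gene_ids, df), path, sep = sep,
                       quote = FALSE, row.names = FALSE, col.names = TRUE)
  }
  invisible(path)
}

#' Read a cell label file
#'
#' Two-column CSV `cell_id,label` with a header, as written by
#' [write_fixture()] and by [cascc_run()].
#'
#' @param path CSV path (optionally gzipped).
#' @return Named vector of labels, names are cell ids.
#' @export
load_labels <- function(path) {
  con <- .open_text(path)
  on.exit(close(con), add = TRUE)
  df <- utils::read.csv(con, colClasses = c("character", NA))
  if (ncol(df) < 2L) {
    stop("format error: label file must have columns cell_id,label",
         call. = FALSE)
  }
  stats::setNames(df[[2L]], df[[1L]])
}
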