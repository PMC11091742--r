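#' 2D embedding of cells in feature space
#'
#' Embeds the feature-selected, per-gene z-scored expression of the cells
#' into two dimensions for visualization and silhouette evaluation.
#' `"tsne"` runs the exact (non-approximated) t-SNE implemented in this
#' package: Gaussian input affinities calibrated per cell to the target
#' perplexity by bisection, Student-t output affinities, gradient descent
#' with momentum and early exaggeration, initialized from the first two
#' principal components plus seeded jitter -- deterministic given `seed`.
#' `"umap"` is not implemented and raises a capability error so callers can
#' continue without an embedding.
#'
#' @param x Numeric matrix of cells (rows) x features, or a
#'   lognorm-layer [expression_matrix()] (cells are taken as columns and
#'   genes z-scored).
#' @param method `"tsne"` or `"umap"`.
#' @param seed Integer seed for the embedding initialization.
#' @param perplexity t-SNE perplexity; capped at `(n_cells - 1) / 3`.
#' @param max_iter Gradient-descent iterations (default 500).
#' @return Numeric matrix, cells x 2, rownames preserved.
#' @export
embed_2d <- function(x, method = c("tsne", "umap"), seed = 0L,
                     perplexity = 30, max_iter = 500L) {
  method <- match.arg(method)
  if (method == "umap") {
    stop("capability error: embedding method 'umap' is not provided by ",
         "this package; use method = 'tsne'", call. = FALSE)
  }
  if (inherits(x, "cascc_matrix")) {
    .check_layer(x, "lognorm")
    x <- t(.zscore_rows(x$values, clip = 10))
  }
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 3L) stop("need at least 3 cells to embed", call. = FALSE)
  perplexity <- max(0.5, min(perplexity, (n - 1) / 3))
  P <- .tsne_affinities(x, perplexity)
  set.seed(seed)
  # PCA initialization makes the layout reproducible and well-spread;
  # tiny jitter breaks exact ties between duplicate cells
  pc <- stats::prcomp(x, rank. = 2L, center = TRUE, scale. = FALSE)$x
  if (ncol(pc) < 2L) pc <- cbind(pc, 0)
  sds <- apply(pc, 2L, stats::sd)
  sds[sds == 0] <- 1
  Y <- sweep(pc, 2L, sds, `/`) * 1e-4 +
    matrix(stats::rnorm(n * 2L, sd = 1e-6), n, 2L)
  .tsne_descend(P, Y, max_iter = max_iter, rown = rownames(x))
}

.tsne_affinities <- function(x, perplexity) {
  n <- nrow(x)
  D <- .dist2_matrix(x, x)
  diag(D) <- Inf
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    P[i, ] <- .perplexity_row(D[i, ], target)
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, .Machine$double.xmin)
}

# bisection on the Gaussian precision beta so the row entropy matches
# log(perplexity)
.perplexity_row <- function(d2, target, iters = 50L) {
  beta <- 1
  lo <- 0
  hi <- Inf
  p <- NULL
  for (it in seq_len(iters)) {
    w <- exp(-d2 * beta)
    w[!is.finite(d2)] <- 0
    s <- sum(w)
    if (s <= 0) {
      # all mass lost: precision too high
      hi <- beta
      beta <- beta / 2
      next
    }
    p <- w / s
    h <- -sum(p[p > 0] * log(p[p > 0]))
    if (abs(h - target) < 1e-5) break
    if (h > target) {          # too spread out: increase precision
      lo <- beta
      beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2
    } else {
      hi <- beta
      beta <- (beta + lo) / 2
    }
  }
  p
}

.tsne_descend <- function(P, Y, max_iter = 500L, rown = NULL,
                          momentum_start = 0.5, momentum_final = 0.8,
                          eta = 200, exaggeration = 12,
                          exaggeration_iters = 100L) {
  n <- nrow(Y)
  V <- matrix(0, n, 2L)
  gains <- matrix(1, n, 2L)
  Pe <- P * exaggeration
  for (it in seq_len(max_iter)) {
    Pit <- if (it <= exaggeration_iters) Pe else P
    num <- 1 / (1 + .dist2_matrix(Y, Y))
    diag(num) <- 0
    Q <- num / sum(num)
    Q <- pmax(Q, .Machine$double.xmin)
    L <- (Pit - Q) * num
    grad <- 4 * (rowSums(L) * Y - L %*% Y)
    mom <- if (it <= 250L) momentum_start else momentum_final
    gains <- ifelse(sign(grad) != sign(V), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    V <- mom * V - eta * gains * grad
    Y <- Y + V
    Y <- sweep(Y, 2L, colMeans(Y))
  }
  rownames(Y) <- rown
  colnames(Y) <- c("dim1", "dim2")
  Y
}
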