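#' Normalized mutual-information association between two expression vectors
#'
#' The co-expression measure driving the attractor iteration. Each vector is
#' rank-transformed to `[0, 1]` (ties by minimum rank, so the zero-inflation
#' mass of scRNA-seq data sits in the lowest bin) and softly assigned to
#' `bins` B-spline basis functions of the given order; mutual information of
#' the resulting joint histogram is normalized by the smaller marginal
#' entropy and clipped to `[0, 1]`:
#' \deqn{J(x, y) = \mathrm{MI}(x, y) / \min(H(x), H(y)).}
#' The rank transform makes J invariant under strictly increasing maps of
#' either input. A constant vector has zero entropy and returns `J = 0` by
#' convention.
#'
#' @param x,y Numeric vectors of equal length (per-cell values).
#' @param bins Number of B-spline bins (default 6).
#' @param spline_order B-spline order (default 3, i.e. quadratic).
#' @return A single number in `[0, 1]`, symmetric in `x` and `y`.
#' @export
mi_association <- function(x, y, bins = 6L, spline_order = 3L) {
  if (length(x) != length(y)) {
    stop("'x' and 'y' must have the same length", call. = FALSE)
  }
  if (anyNA(x) || anyNA(y)) stop("NA/NaN in input", call. = FALSE)
  wx <- .spline_weights(x, bins, spline_order)
  wy <- .spline_weights(y, bins, spline_order)
  if (is.null(wx) || is.null(wy)) return(0)
  hx <- .self_information(wx)
  hy <- .self_information(wy)
  hmin <- min(hx, hy)
  if (hmin <= .Machine$double.eps) return(0)
  pxy <- crossprod(wx, wy) / nrow(wx)
  mi <- .mi_from_joint(pxy, colMeans(wx), colMeans(wy))
  min(max(mi / hmin, 0), 1)
}

# soft bin-membership weights: n x bins matrix of B-spline basis values
# evaluated at the rank-uniformized positions; rows sum to 1 (partition of
# unity). Returns NULL for constant input (no information).
.spline_weights <- function(x, bins = 6L, order = 3L) {
  n <- length(x)
  if (n < 2L) return(NULL)
  rng <- range(x)
  if (rng[1L] == rng[2L]) return(NULL)
  pos <- (rank(x, ties.method = "min") - 1) / (n - 1)
  .spline_basis(pos, bins, order)
}

.spline_basis <- function(pos, bins, order) {
  if (bins < order) stop("'bins' must be >= 'spline_order'", call. = FALSE)
  breaks <- seq(0, 1, length.out = bins - order + 2L)
  knots <- c(rep(0, order - 1L), breaks, rep(1, order - 1L))
  splines::splineDesign(knots, pos, ord = order)
}

.entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

# marginal information content of a soft-binned vector, defined as the
# estimator's MI of the vector with itself so that J(x, x) = 1 exactly;
# equals the Shannon marginal entropy in the hard-binning limit
.self_information <- function(w) {
  p <- colMeans(w)
  .mi_from_joint(crossprod(w, w) / nrow(w), p, p)
}

.mi_from_joint <- function(pxy, px, py) {
  lp <- log(pxy)
  lp[!is.finite(lp)] <- 0
  sum(pxy * (lp - outer(log(px), log(py), `+`)), na.rm = TRUE)
}

# Precomputed association machinery for one expression matrix: the spline
# weight matrix of every gene (cells x bins, stacked column-wise) and each
# gene's marginal entropy. Constant genes carry NA entropy and always get
# association 0.
.assoc_cache <- function(values, bins = 6L, spline_order = 3L) {
  g <- nrow(values)
  n <- ncol(values)
  W <- matrix(0, n, g * bins)
  H <- rep(NA_real_, g)
  px <- matrix(NA_real_, g, bins)
  for (i in seq_len(g)) {
    w <- .spline_weights(values[i, ], bins, spline_order)
    if (!is.null(w)) {
      W[, ((i - 1L) * bins + 1L):(i * bins)] <- w
      px[i, ] <- colMeans(w)
      H[i] <- .self_information(w)
    }
  }
  # centered rank vectors for the Spearman sign of each gene against a
  # metagene (mutual information is blind to the direction of association;
  # anti-correlated genes must not enter a co-expression signature)
  R <- apply(values, 1L, function(x) {
    r <- rank(x)
    r - mean(r)
  })                                          # n x g
  list(W = W, H = H, px = px, R = R, bins = bins,
       spline_order = spline_order, gene_ids = rownames(values), n = n)
}

# sign of the Spearman correlation of every cached gene with `scores`;
# zero-variance genes get sign 0
.assoc_sign <- function(cache, scores) {
  r <- rank(scores)
  s <- as.vector(crossprod(cache$R, r - mean(r)))
  sign(s)
}

# association of every cached gene with one metagene score vector;
# vectorized over genes through a single crossprod
.assoc_profile <- function(cache, scores) {
  bins <- cache$bins
  wm <- .spline_weights(scores, bins, cache$spline_order)
  g <- length(cache$H)
  if (is.null(wm)) return(rep(0, g))
  py <- colMeans(wm)
  hy <- .self_information(wm)
  P <- crossprod(cache$W, wm) / cache$n      # (g*bins) x bins
  lP <- log(P)
  lP[!is.finite(lP)] <- 0
  lpx <- as.vector(t(log(cache$px)))         # g*bins values, gene-major
  lpx[!is.finite(lpx)] <- 0
  lpy <- log(py)
  lpy[!is.finite(lpy)] <- 0
  contrib <- P * lP - P * lpx - sweep(P, 2L, lpy, `*`)
  mi <- rowsum(rowSums(contrib), rep(seq_len(g), each = bins))
  hmin <- pmin(cache$H, hy)
  J <- as.vector(mi) / hmin
  J[!is.finite(J)] <- 0
  pmin(pmax(J, 0), 1)
}
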