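#' Adjusted Rand index
#'
#' Hubert-Arabie chance-adjusted agreement between two partitions of the
#' same items, computed from the contingency table:
#' \deqn{ARI = \frac{\sum_{ij} \binom{n_{ij}}{2} - E}
#'   {\tfrac12\left(\sum_i \binom{a_i}{2} + \sum_j \binom{b_j}{2}\right) - E},
#'   \quad E = \sum_i \binom{a_i}{2} \sum_j \binom{b_j}{2} / \binom{n}{2}.}
#' Pair counts are integers represented exactly in double precision for any
#' realistic n. When the denominator is zero (e.g. one side is a single
#' cluster and the adjustment is degenerate) the result is 0 by convention,
#' except that two identical trivial partitions score 1.
#'
#' @param a,b Label vectors over the same items. If both are named they are
#'   aligned by name (order-independent); otherwise they are aligned by
#'   position.
#' @return A single number, 1 for identical partitions.
#' @export
ari <- function(a, b) {
  p <- .align_pair(a, b)
  tab <- table(p$a, p$b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  E <- sum_a * sum_b / choose(n, 2)
  den <- (sum_a + sum_b) / 2 - E
  if (den == 0) {
    return(if (identical(unname(as.integer(factor(p$a))),
                         unname(as.integer(factor(p$b))))) 1 else 0)
  }
  (sum_ij - E) / den
}

.align_pair <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    common <- intersect(names(a), names(b))
    if (length(common) < length(a) || length(common) < length(b)) {
      if (length(common) == 0L) {
        stop("label vectors share no item ids", call. = FALSE)
      }
      warning("aligning on the ", length(common), " shared item ids",
              call. = FALSE)
    }
    a <- a[common]
    b <- b[common]
  } else if (length(a) != length(b)) {
    stop("label vectors differ in length and carry no ids to align on",
         call. = FALSE)
  }
  if (length(a) < 2L) {
    stop("partition comparison needs at least 2 items", call. = FALSE)
  }
  list(a = as.vector(a), b = as.vector(b))
}

.partition_entropy <- function(counts, n) {
  p <- counts[counts > 0] / n
  -sum(p * log(p))
}

.mutual_information <- function(tab) {
  n <- sum(tab)
  pij <- tab / n
  pi <- rowSums(pij)
  pj <- colSums(pij)
  keep <- pij > 0
  sum(pij[keep] * (log(pij[keep]) -
                     outer(log(pi), log(pj), `+`)[keep]))
}

#' Normalized mutual information between two partitions
#'
#' `I(A;B)` divided by a symmetric normalizer of the two partition
#' entropies (natural logarithms). Two identical trivial partitions (a
#' single cluster each) score 1 by convention.
#'
#' @inheritParams ari
#' @param norm Normalizer: `"arithmetic"` (default), `"geometric"`,
#'   `"min"`, or `"max"` of the two entropies.
#' @return A number in `[0, 1]`.
#' @export
nmi <- function(a, b, norm = c("arithmetic", "geometric", "min", "max")) {
  norm <- match.arg(norm)
  p <- .align_pair(a, b)
  tab <- table(p$a, p$b)
  n <- sum(tab)
  ha <- .partition_entropy(rowSums(tab), n)
  hb <- .partition_entropy(colSums(tab), n)
  den <- switch(norm,
                arithmetic = (ha + hb) / 2,
                geometric = sqrt(ha * hb),
                min = min(ha, hb),
                max = max(ha, hb))
  if (den == 0) {
    return(if (ha == 0 && hb == 0) 1 else 0)
  }
  max(0, min(1, .mutual_information(tab) / den))
}

#' Adjusted mutual information between two partitions
#'
#' \deqn{AMI = (I - E[I]) / (\mathrm{mean}(H_A, H_B) - E[I])} where `E[I]`
#' is the expected mutual information under the permutation model with the
#' observed marginals. The expectation uses the exact hypergeometric sum
#' for `n <= exact_limit` and a Monte-Carlo permutation estimate above.
#' AMI of two independent random partitions concentrates near 0; identical
#' partitions (including two trivial one-cluster partitions) score 1.
#'
#' @inheritParams ari
#' @param exact_limit Largest n for which the exact expected-MI formula is
#'   used (default 5000).
#' @param n_mc Monte-Carlo resamples beyond `exact_limit` (default 200).
#' @param seed Seed for the Monte-Carlo path.
#' @return A number, at most 1.
#' @export
ami <- function(a, b, exact_limit = 5000L, n_mc = 200L, seed = 0L) {
  p <- .align_pair(a, b)
  tab <- table(p$a, p$b)
  n <- sum(tab)
  ha <- .partition_entropy(rowSums(tab), n)
  hb <- .partition_entropy(colSums(tab), n)
  if (ha == 0 && hb == 0) return(1)
  I <- .mutual_information(tab)
  emi <- if (n <= exact_limit) {
    .expected_mi(rowSums(tab), colSums(tab), n)
  } else {
    .expected_mi_mc(p$a, p$b, n_mc, seed)
  }
  den <- (ha + hb) / 2 - emi
  if (abs(den) < .Machine$double.eps) {
    return(if (I >= (ha + hb) / 2) 1 else 0)
  }
  (I - emi) / den
}

# exact E[I] under the permutation (hypergeometric) model
.expected_mi <- function(ai, bj, n) {
  lgn <- lgamma(n + 1)
  emi <- 0
  for (x in ai[ai > 0]) {
    for (y in bj[bj > 0]) {
      lo <- max(1, x + y - n)
      hi <- min(x, y)
      if (hi < lo) next
      nij <- lo:hi
      lw <- lgamma(x + 1) + lgamma(y + 1) + lgamma(n - x + 1) +
        lgamma(n - y + 1) - lgn - lgamma(nij + 1) - lgamma(x - nij + 1) -
        lgamma(y - nij + 1) - lgamma(n - x - y + nij + 1)
      emi <- emi + sum(nij / n * log(n * nij / (x * y)) * exp(lw))
    }
  }
  emi
}

.expected_mi_mc <- function(a, b, n_mc, seed) {
  set.seed(seed)
  mean(vapply(seq_len(n_mc), function(i) {
    .mutual_information(table(a, sample(b)))
  }, numeric(1L)))
}

#' Absolute log-modulus error of an estimated cluster number
#'
#' `|L(k_est - k_true)|` with the log-modulus transform
#' `L(x) = sign(x) * log10(|x| + 1)`. Zero iff the estimate is exact; an
#' over- and an under-estimate of the same magnitude score equally.
#'
#' @param k_est Estimated number of clusters.
#' @param k_true True number of cell types (>= 1).
#' @return Non-negative number.
#' @export
log_modulus_k <- function(k_est, k_true) {
  stopifnot(k_true >= 1)
  d <- k_est - k_true
  abs(sign(d) * log10(abs(d) + 1))
}

#' Signed relative deviation of an estimated cluster number
#'
#' `(k_est - k_true) / k_true`: positive when the method over-estimates the
#' number of cell types, negative when it under-estimates.
#'
#' @inheritParams log_modulus_k
#' @return A number in `[-1, Inf)`.
#' @export
deviation_k <- function(k_est, k_true) {
  stopifnot(k_true >= 1)
  (k_est - k_true) / k_true
}

#' Average silhouette width of a labeling in a 2D embedding
#'
#' Mean over cells of the silhouette `s(i) = (b(i) - a(i)) / max(a(i),
#' b(i))` with Euclidean distances in the embedding; singleton clusters
#' contribute `s = 0`. Higher values indicate cohesive, well-separated
#' clusters.
#'
#' @param embedding Numeric matrix, cells x 2 (any dimensionality is
#'   accepted).
#' @param labels Cluster labels per cell (at least 2 distinct).
#' @return A number in `[-1, 1]`.
#' @export
asw <- function(embedding, labels) {
  embedding <- as.matrix(embedding)
  labels <- as.integer(factor(labels))
  if (length(labels) != nrow(embedding)) {
    stop("labels length does not match embedding rows", call. = FALSE)
  }
  if (length(unique(labels)) < 2L) {
    stop("silhouette is undefined for a single cluster", call. = FALSE)
  }
  sil <- cluster::silhouette(labels, stats::dist(embedding))
  mean(sil[, "sil_width"])
}

#' Clustering evaluation report
#'
#' Compares predicted labels with ground truth using every metric of the
#' package: ARI, AMI, NMI, the estimated and true cluster numbers with
#' their absolute log-modulus and signed deviation scores, and (when an
#' embedding is supplied) the average silhouette width of the predicted
#' labels in that embedding.
#'
#' @param pred Named (by cell id) or positional vector of predicted labels.
#' @param truth Ground-truth labels, aligned as in [ari()].
#' @param embedding Optional cells x 2 matrix for [asw()]; if it has
#'   rownames they are used to align to `pred`.
#' @return Named list: `ari`, `ami`, `nmi`, `k_est`, `k_true`,
#'   `log_modulus`, `deviation`, and `asw` (NA without an embedding).
#' @export
evaluate_clustering <- function(pred, truth, embedding = NULL) {
  k_est <- length(unique(pred))
  k_true <- length(unique(truth))
  sil <- NA_real_
  if (!is.null(embedding)) {
    emb <- as.matrix(embedding)
    lab <- pred
    if (!is.null(rownames(emb)) && !is.null(names(pred))) {
      lab <- pred[rownames(emb)]
    }
    sil <- asw(emb, lab)
  }
  list(ari = ari(pred, truth),
       ami = ami(pred, truth),
       nmi = nmi(pred, truth),
       k_est = k_est, k_true = k_true,
       log_modulus = log_modulus_k(k_est, k_true),
       deviation = deviation_k(k_est, k_true),
       asw = sil)
}
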