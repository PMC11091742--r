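#' One attractor iteration: re-weight genes by association with a metagene
#'
#' Computes the association `J_g` of every gene with the current metagene,
#' then forms the next metagene as the convex combination of gene rows with
#' weights `J_g^a / sum_h J_h^a`. Higher exponents `a` sharpen the weighting
#' towards the most associated genes.
#'
#' @param m Lognorm-layer [expression_matrix()].
#' @param scores Numeric per-cell metagene scores (e.g. a seed gene's row).
#' @param a Weighting exponent, `a > 0`.
#' @param bins,spline_order Passed to [mi_association()].
#' @param cache Optional precomputed association cache for `m` (internal
#'   reuse across iterations); built on the fly when `NULL`.
#' @param signed Give genes anti-correlated (Spearman) with the metagene a
#'   negative association so they are excluded from the weighting (default
#'   TRUE; mutual information alone cannot tell co-expression from
#'   mutual exclusion).
#' @return List with `scores` (the new metagene) and `J` (named per-gene
#'   association vector used to form it; negative entries mark
#'   anti-correlated genes when `signed`).
#' @export
metagene_update <- function(m, scores, a, bins = 6L, spline_order = 3L,
                            cache = NULL, signed = TRUE) {
  .check_layer(m, "lognorm")
  if (!is.numeric(a) || a <= 0) stop("'a' must be positive", call. = FALSE)
  if (length(scores) != ncol(m$values)) {
    stop("metagene length does not match the number of cells",
         call. = FALSE)
  }
  if (is.null(cache)) cache <- .assoc_cache(m$values, bins, spline_order)
  J <- .assoc_profile(cache, scores)
  if (signed) J <- J * .assoc_sign(cache, scores)
  names(J) <- m$gene_ids
  if (all(J <= 0)) {
    stop(structure(class = c("cascc_degenerate", "error", "condition"),
                   list(message = paste("degenerate convergence: metagene",
                                        "is unassociated with every gene"),
                        call = NULL)))
  }
  w <- pmax(J, 0)^a
  w <- w / sum(w)
  new_scores <- as.vector(w %*% m$values)
  if (max(new_scores) - min(new_scores) <= .Machine$double.eps) {
    stop(structure(class = c("cascc_degenerate", "error", "condition"),
                   list(message = "degenerate convergence: constant metagene",
                        call = NULL)))
  }
  list(scores = new_scores, J = J)
}

#' Converge an attractor signature from a seed gene
#'
#' Initializes the metagene at the seed gene's expression row and iterates
#' [metagene_update()] until the top-`top_n` ranked gene set is identical
#' between consecutive iterations and the largest association change is
#' below `tol`. A metagene revisiting the state of two iterations earlier
#' (without converging) is flagged as oscillating; a metagene losing all
#' association is flagged degenerate; otherwise the iteration cap yields
#' `max_iter` status. Only `converged` signatures are used downstream.
#'
#' @param m Lognorm-layer [expression_matrix()].
#' @param seed_gene Gene id present and non-constant in `m`.
#' @param a Weighting exponent (default 2).
#' @param max_iter Iteration cap (default 100).
#' @param top_n Size of the ranked set compared across iterations
#'   (default 20).
#' @param tol Convergence tolerance on `max |Delta J|` (default 1e-7).
#' @param bins,spline_order,cache,signed As in [metagene_update()].
#' @param init Optional metagene scores overriding the seed-row
#'   initialization (used by [adapt_exponent()] when re-converging at a
#'   sharper exponent).
#' @return Object of class `"cascc_attractor"`: list with `ranked_genes`
#'   (all genes, association-descending, ties by gene id), `associations`
#'   (aligned J values), `seed`, `exponent`, `n_iterations`, `status` (one
#'   of `"converged"`, `"oscillating"`, `"max_iter"`, `"degenerate"`), and
#'   `metagene` (final per-cell scores).
#' @export
converge_attractor <- function(m, seed_gene, a = 2, max_iter = 100L,
                               top_n = 20L, tol = 1e-7, bins = 6L,
                               spline_order = 3L, cache = NULL,
                               init = NULL, signed = TRUE) {
  .check_layer(m, "lognorm")
  if (is.null(cache)) cache <- .assoc_cache(m$values, bins, spline_order)
  if (is.null(init)) {
    if (!seed_gene %in% m$gene_ids) {
      stop("seed gene '", seed_gene, "' not in matrix", call. = FALSE)
    }
    scores <- m$values[seed_gene, ]
    if (max(scores) == min(scores)) {
      stop("seed gene '", seed_gene, "' is constant", call. = FALSE)
    }
  } else {
    scores <- init
  }
  J <- .assoc_profile(cache, scores)
  if (signed) J <- J * .assoc_sign(cache, scores)
  J <- stats::setNames(J, m$gene_ids)
  status <- if (all(J <= 0)) "degenerate" else "max_iter"
  top_hist <- list(.rank_top(J, top_n))
  iter <- 0L
  while (status == "max_iter" && iter < max_iter) {
    iter <- iter + 1L
    # inline metagene_update, reusing the profile already in hand
    w <- pmax(J, 0)^a
    if (iter == 1L && is.null(init)) {
      # the seed's self-association of 1 against its own row is
      # uninformative and would lock the iteration onto the seed; let the
      # seed's co-expression partners define the first metagene
      w[seed_gene] <- 0
      if (sum(w) == 0) {
        status <- "degenerate"
        break
      }
    }
    w <- w / sum(w)
    scores <- as.vector(w %*% m$values)
    if (max(scores) - min(scores) <= .Machine$double.eps) {
      status <- "degenerate"
      break
    }
    J_new <- .assoc_profile(cache, scores)
    if (signed) J_new <- J_new * .assoc_sign(cache, scores)
    J_new <- stats::setNames(J_new, m$gene_ids)
    if (all(J_new <= 0)) {
      status <- "degenerate"
      break
    }
    top <- .rank_top(J_new, top_n)
    if (identical(top, top_hist[[length(top_hist)]]) &&
        max(abs(J_new - J)) < tol) {
      status <- "converged"
      J <- J_new
      break
    }
    # period-2 oscillation: same top set as two iterations back but not one
    if (length(top_hist) >= 2L &&
        identical(top, top_hist[[length(top_hist) - 1L]]) &&
        !identical(top, top_hist[[length(top_hist)]])) {
      status <- "oscillating"
      J <- J_new
      break
    }
    top_hist[[length(top_hist) + 1L]] <- top
    J <- J_new
  }
  ord <- order(-J, names(J))
  structure(list(ranked_genes = names(J)[ord],
                 associations = unname(J[ord]),
                 seed = seed_gene,
                 exponent = a,
                 n_iterations = iter,
                 status = status,
                 metagene = scores,
                 noise_floor = stats::median(abs(J))),
            class = "cascc_attractor")
}

.rank_top <- function(J, top_n) {
  ord <- order(-J, names(J))
  sort(names(J)[ord][seq_len(min(top_n, length(J)))])
}

#' @export
print.cascc_attractor <- function(x, n = 10L, ...) {
  cat(sprintf("<cascc_attractor> seed=%s a=%g status=%s iterations=%d\n",
              x$seed, x$exponent, x$status, x$n_iterations))
  k <- min(n, length(x$ranked_genes))
  cat("  top genes:",
      paste(sprintf("%s(%.2f)", x$ranked_genes[seq_len(k)],
                    x$associations[seq_len(k)]), collapse = " "), "\n")
  invisible(x)
}

#' Adaptive-exponent attractor search
#'
#' Runs [converge_attractor()] at `a = a_min` and checks the breadth of the
#' converged signature: a signature with more than `breadth_cap` genes
#' within half of its top association is considered generic
#' (housekeeping-like) rather than population-specific, so the exponent is
#' raised by `a_step` and the iteration re-converged from the seed gene at
#' the sharper exponent (a sharper weighting keeps the iterate inside the
#' seed's own co-expression instead of drifting to the generic signature).
#' The search stops at the first acceptably narrow signature or at
#' `a_max`.
#'
#' @inheritParams converge_attractor
#' @param a_min,a_max,a_step Exponent schedule (defaults 2, 10, 1).
#' @param breadth_cap Maximum number of genes with `J >= breadth_level *
#'   J_top` for a signature to count as specific (default 100).
#' @param breadth_level Fraction of the top association defining the
#'   breadth count (default 0.5; the association scale of real data
#'   depends on its sparsity, so the level adapts to the signature).
#' @return A `"cascc_attractor"` with the final exponent recorded. If no
#'   exponent converges the best-status signature is returned (status not
#'   `"converged"`) for the caller to discard.
#' @export
adapt_exponent <- function(m, seed_gene, a_min = 2, a_max = 10, a_step = 1,
                           breadth_cap = 100L, breadth_level = 0.5,
                           max_iter = 100L, top_n = 20L,
                           tol = 1e-7, bins = 6L, spline_order = 3L,
                           cache = NULL) {
  stopifnot(a_min <= a_max, a_step > 0)
  if (is.null(cache)) cache <- .assoc_cache(m$values, bins, spline_order)
  a <- a_min
  best <- NULL
  repeat {
    sig <- converge_attractor(m, seed_gene, a = a, max_iter = max_iter,
                              top_n = top_n, tol = tol, bins = bins,
                              spline_order = spline_order, cache = cache)
    if (is.null(best) || sig$status == "converged") best <- sig
    if (sig$status == "converged") {
      breadth <- sum(sig$associations >=
                       breadth_level * sig$associations[1L])
      if (breadth <= breadth_cap || a >= a_max) return(sig)
    } else if (a >= a_max) {
      return(best)
    }
    a <- min(a + a_step, a_max)
  }
}

#' Collapse redundant attractor signatures
#'
#' Different seeds belonging to one co-expression converge to the same
#' signature; this merges them. A signature counts as genuine only if its
#' rank-`strength_rank` association stands at least `strength_ratio` times
#' above the signature's association noise floor (the median J over all
#' genes) -- a one-gene fixed point or a noise signature has no such deep
#' support -- and above the optional absolute floor `strength_min`.
#' Survivors are grouped by single-link (transitive) clustering on the
#' Jaccard overlap of their top-`top_n` gene sets at threshold
#' `jaccard_min`, and each group is represented by its member with the
#' highest mean association over the top genes. Output is ordered by that
#' mean, descending.
#'
#' @param signatures List of converged `"cascc_attractor"` objects.
#' @param top_n Genes per signature used for overlap and strength
#'   (default 20).
#' @param jaccard_min Jaccard threshold for merging (default 0.5).
#' @param strength_min Absolute minimum association at rank
#'   `strength_rank` (default 0, i.e. only the relative criterion).
#' @param strength_rank Rank at which signature strength is read
#'   (default 10).
#' @param strength_ratio Required ratio of the rank-`strength_rank`
#'   association to the signature's noise floor (default 5).
#' @return Filtered, deduplicated, ordered list of signatures.
#' @export
dedup_attractors <- function(signatures, top_n = 20L, jaccard_min = 0.5,
                             strength_min = 0, strength_rank = 10L,
                             strength_ratio = 5) {
  if (length(signatures) == 0L) return(list())
  ok <- vapply(signatures, function(s) {
    r <- min(strength_rank, length(s$associations))
    floor_j <- if (is.null(s$noise_floor)) 0 else s$noise_floor
    s$status == "converged" &&
      s$associations[r] >= strength_min &&
      s$associations[r] >= strength_ratio * floor_j
  }, logical(1L))
  signatures <- signatures[ok]
  ns <- length(signatures)
  if (ns == 0L) return(list())
  tops <- lapply(signatures, function(s) {
    s$ranked_genes[seq_len(min(top_n, length(s$ranked_genes)))]
  })
  strength <- vapply(signatures, function(s) {
    mean(s$associations[seq_len(min(top_n, length(s$associations)))])
  }, numeric(1L))
  # single-link grouping = connected components of the overlap graph,
  # order-independent by construction
  comp <- seq_len(ns)
  for (i in seq_len(ns - 1L)) {
    for (j in seq(i + 1L, ns)) {
      jac <- length(intersect(tops[[i]], tops[[j]])) /
        length(union(tops[[i]], tops[[j]]))
      if (jac >= jaccard_min) {
        merged <- comp %in% comp[c(i, j)]
        comp[merged] <- min(comp[c(i, j)])
      }
    }
  }
  reps <- vapply(split(seq_len(ns), comp), function(idx) {
    idx[which.max(strength[idx])]
  }, integer(1L))
  reps <- reps[order(-strength[reps])]
  unname(signatures[reps])
}

#' Scan attractors from a set of seed genes
#'
#' Runs the adaptive attractor search over the candidate seeds and
#' collapses the converged signatures with [dedup_attractors()]. Two
#' economies keep the scan fast without changing its outcome: a seed whose
#' immediate co-expression neighborhood (the first association profile of
#' its own expression row) does not stand `strength_ratio` times above the
#' noise floor at rank `strength_rank` cannot found a genuine signature
#' and is screened out after a single profile evaluation; and a seed
#' already ranked within the top `strength_rank` genes of an accepted
#' signature is skipped, since any seed inside a co-expression converges
#' to that co-expression's signature.
#'
#' The scan runs in two phases: the leading seed of every group (in
#' parallel over `threads` workers), then the remaining seeds
#' sequentially with the skip rule. Output is byte-identical for any
#' worker count.
#'
#' @inheritParams adapt_exponent
#' @inheritParams dedup_attractors
#' @param seeds Candidate seed gene ids: either a character vector or a
#'   list of character vectors (one per initial cluster, each ordered by
#'   marker rank; the per-cluster leaders form the parallel first phase).
#' @param threads Number of parallel workers (default 1).
#' @return List of deduplicated converged signatures, strongest first.
#' @export
find_attractors <- function(m, seeds, a_min = 2, a_max = 10, a_step = 1,
                            breadth_cap = 100L, breadth_level = 0.5,
                            max_iter = 100L, top_n = 20L, tol = 1e-7,
                            bins = 6L, spline_order = 3L,
                            jaccard_min = 0.5, strength_min = 0,
                            strength_rank = 10L, strength_ratio = 5,
                            threads = 1L) {
  .check_layer(m, "lognorm")
  if (!is.list(seeds)) seeds <- list(as.character(seeds))
  seeds <- lapply(seeds, function(s) s[s %in% m$gene_ids])
  leaders <- unique(unlist(lapply(seeds, function(s) s[1L]),
                           use.names = FALSE))
  # remaining seeds interleaved by marker rank across clusters
  depth <- max(c(1L, lengths(seeds)))
  rest <- unlist(lapply(seq_len(depth), function(r) {
    unlist(lapply(seeds, function(s) if (length(s) >= r) s[r] else NULL))
  }), use.names = FALSE)
  rest <- setdiff(unique(rest), leaders)
  if (length(leaders) == 0L) return(list())
  cache <- .assoc_cache(m$values, bins, spline_order)

  screen_ok <- function(s) {
    row <- m$values[s, ]
    p <- .assoc_profile(cache, row) * .assoc_sign(cache, row)
    names(p) <- m$gene_ids
    q <- sort(p[names(p) != s], decreasing = TRUE)
    r <- min(strength_rank, length(q))
    md <- stats::median(abs(p))
    md > 0 && q[r] >= strength_ratio * md && q[r] >= strength_min
  }
  run_one <- function(s) {
    tryCatch(
      adapt_exponent(m, s, a_min = a_min, a_max = a_max, a_step = a_step,
                     breadth_cap = breadth_cap,
                     breadth_level = breadth_level, max_iter = max_iter,
                     top_n = top_n, tol = tol, bins = bins,
                     spline_order = spline_order, cache = cache),
      error = function(e) NULL)
  }
  apply_fun <- if (threads > 1L) {
    function(xs, f) parallel::mclapply(xs, f, mc.cores = threads)
  } else {
    lapply
  }

  keep <- unlist(apply_fun(leaders, screen_ok))
  sigs <- apply_fun(leaders[keep], run_one)
  sigs <- Filter(Negate(is.null), sigs)

  accepted <- function(s) {
    length(dedup_attractors(list(s), top_n = top_n,
                            jaccard_min = jaccard_min,
                            strength_min = strength_min,
                            strength_rank = strength_rank,
                            strength_ratio = strength_ratio)) == 1L
  }
  covered <- unique(unlist(lapply(Filter(accepted, sigs), function(s) {
    s$ranked_genes[seq_len(min(strength_rank, length(s$ranked_genes)))]
  })))
  for (s in rest) {
    if (s %in% covered) next
    if (!screen_ok(s)) next
    sig <- run_one(s)
    if (is.null(sig)) next
    sigs[[length(sigs) + 1L]] <- sig
    if (accepted(sig)) {
      covered <- unique(c(
        covered,
        sig$ranked_genes[seq_len(min(strength_rank,
                                     length(sig$ranked_genes)))]))
    }
  }
  dedup_attractors(sigs, top_n = top_n, jaccard_min = jaccard_min,
                   strength_min = strength_min,
                   strength_rank = strength_rank,
                   strength_ratio = strength_ratio)
}
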