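#' Detect fused edges in a fit
#'
#' An edge is declared fused (its two mode-`d` subarrays assigned to the same
#' cluster) when its dual block lies strictly inside its ball,
#' \eqn{\|\hat\lambda_{d,l}\|_2 \le (1-\delta)\,\gamma w_{d,l}} — at an exact
#' optimum an interior dual block forces the primal difference to vanish —
#' or when the primal difference norm itself is numerically zero,
#' \eqn{\|v_{d,l}\|_2 \le \epsilon_{abs} + \epsilon_{rel}\|x\|_F}. The dual
#' test is only applied to edges whose ball radius \eqn{\gamma w_{d,l}}
#' exceeds the same numerical threshold: below it the radius is smaller than
#' floating-point noise at the problem's scale and the test carries no
#' information. With `gamma = 0` no edges are fused by convention.
#'
#' @param fit A `"coco_fit"`.
#' @param graph The `"coco_graph"` the fit was produced with.
#' @param x Data tensor (for the relative norm threshold).
#' @param delta Interior margin for the dual test.
#' @param eps_rel,eps_abs Norm-threshold tolerances.
#' @return List (per mode) of logical vectors aligned with the edge lists.
#' @export
fused_edges <- function(fit, graph, x, delta = 1e-3, eps_rel = 1e-8,
                        eps_abs = 1e-10) {
  xnorm <- tensor_norm(x)
  lapply(seq_along(graph$modes), function(d) {
    w <- graph$modes[[d]]$weights
    if (!length(w)) return(logical(0))
    if (fit$gamma == 0) return(rep(FALSE, length(w)))
    radius <- fit$gamma * w
    # the interior test is only meaningful when the ball radius is resolvable
    # above floating-point noise at the problem's scale; below that, any
    # wobble in the dual block looks "interior", so only the primal norm
    # test may declare fusion
    resolvable <- radius > eps_abs + eps_rel * xnorm
    interior <- resolvable & (fit$dual_norms[[d]] <= (1 - delta) * radius)
    tiny <- fit$diff_norms[[d]] <= eps_abs + eps_rel * xnorm
    interior | tiny
  })
}

#' Connected components of a fused-edge graph
#'
#' Labels `1..n_d` nodes by breadth-first search over the fused edges,
#' starting from the smallest unvisited index; two indices share a label iff
#' joined by a path of fused edges. Labels are canonical: component label
#' order follows the smallest member index, so the output is invariant to the
#' order in which edges are listed.
#'
#' @param n_d Number of nodes.
#' @param edges Two-column integer matrix of fused edges (may have 0 rows).
#' @return Integer label vector of length `n_d`.
#' @export
connected_components <- function(n_d, edges) {
  edges <- matrix(as.integer(edges), ncol = 2L)
  if (nrow(edges) && (any(edges < 1L) || any(edges > n_d))) {
    stop("edge endpoint out of range")
  }
  bfs_components(n_d, edges)
}

#' Extract per-mode partitions from a fit
#'
#' Applies [fused_edges()] then [connected_components()] per mode, and
#' computes the implied co-cluster means.
#'
#' @inheritParams fused_edges
#' @return A `"coco_clustering"`: `labels` (list of per-mode integer
#'   vectors), `k` (per-mode cluster counts), `means` (the
#'   \eqn{\hat k_1 \times \cdots \times \hat k_D} co-cluster means of `x`).
#' @export
coco_clusters <- function(fit, graph, x, delta = 1e-3, eps_rel = 1e-8,
                          eps_abs = 1e-10) {
  fused <- fused_edges(fit, graph, x, delta, eps_rel, eps_abs)
  labels <- lapply(seq_along(graph$modes), function(d) {
    keep <- fused[[d]]
    connected_components(graph$dims[d],
                         graph$modes[[d]]$edges[keep, , drop = FALSE])
  })
  structure(list(labels = labels,
                 k = vapply(labels, max, 0L),
                 means = co_cluster_means(x, labels)),
            class = "coco_clustering")
}

#' Co-cluster means
#'
#' The sample mean of the data over every cell of the checkerbox implied by
#' the per-mode partitions:
#' \eqn{\hat c_{r_1 \cdots r_D}} is the average of `x` over
#' \eqn{G_{r_1} \times \cdots \times G_{r_D}}.
#'
#' @param x Data tensor.
#' @param labels List of per-mode integer label vectors.
#' @return Array of shape \eqn{\hat k_1 \times \cdots \times \hat k_D}.
#' @export
co_cluster_means <- function(x, labels) {
  D <- length(dim(x))
  if (length(labels) != D) stop("one label vector per mode required")
  sums <- x
  for (d in seq_len(D)) {
    lab <- as.integer(labels[[d]])
    if (length(lab) != dim(sums)[d]) stop("label length mismatch in mode ", d)
    k <- max(lab)
    M <- matrix(0, k, length(lab))
    M[cbind(lab, seq_along(lab))] <- 1
    sums <- ttm(sums, M, d)
  }
  counts <- Reduce(function(a, b) outer(a, b),
                   lapply(labels, function(lab) tabulate(as.integer(lab))))
  sums / array(counts, dim = dim(sums))
}

#' Expand co-cluster means to a full tensor
#'
#' Inverse of the averaging step: maps a means tensor through the membership
#' matrices implied by the labels, giving a tensor constant on each
#' co-cluster cell.
#'
#' @param means Means array, one entry per co-cluster.
#' @param labels List of per-mode label vectors.
#' @return Dense array of shape `lengths(labels)`.
#' @export
expand_means <- function(means, labels) {
  out <- means
  for (d in seq_along(labels)) {
    lab <- as.integer(labels[[d]])
    k <- dim(means)[d]
    if (max(lab) > k) stop("labels exceed means extent in mode ", d)
    M <- matrix(0, length(lab), k)
    M[cbind(seq_along(lab), lab)] <- 1
    out <- ttm(out, M, d)
  }
  out
}

#' Adjusted Rand index
#'
#' Hubert-Arabie chance-corrected agreement between two labelings of the
#' same items: 1 for identical partitions, about 0 for random agreement,
#' negative when agreement is below chance.
#'
#' @param a,b Label vectors of equal length (>= 2).
#' @return Scalar in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("labelings must have equal length")
  if (length(a) < 2L) stop("need at least two items")
  out <- mclust::adjustedRandIndex(a, b)
  if (is.nan(out)) {
    # degenerate 0/0 case: both partitions trivial (all singletons or all one
    # cluster); they either coincide (perfect match) or not
    same <- identical(as.integer(factor(a, levels = unique(a))),
                      as.integer(factor(b, levels = unique(b))))
    out <- if (same) 1 else 0
  }
  out
}

#' @export
print.coco_clustering <- function(x, ...) {
  cat("<coco_clustering> per-mode cluster counts:",
      paste(x$k, collapse = " x "), "\n")
  invisible(x)
}

#' Tidy a co-clustering into a label table
#'
#' @param x A `"coco_clustering"`.
#' @param ... Unused.
#' @return Tibble with columns `mode`, `index`, `label`.
#' @export
tidy.coco_clustering <- function(x, ...) {
  do.call(rbind, lapply(seq_along(x$labels), function(d) {
    tibble::tibble(mode = d, index = seq_along(x$labels[[d]]),
                   label = x$labels[[d]])
  }))
}
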