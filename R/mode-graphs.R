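#' Pairwise distances between mode-d subarrays
#'
#' Frobenius distances between the rows of the mode-`d` matricization,
#' i.e. \eqn{\|X_{(d),i:} - X_{(d),j:}\|_F} for every pair of mode-`d`
#' subarrays.
#'
#' @param x A dense numeric array.
#' @param mode Mode index.
#' @return Symmetric `n_d x n_d` matrix with zero diagonal.
#' @export
mode_distances <- function(x, mode) {
  m <- tensor_unfold(x, mode)
  dm <- as.matrix(stats::dist(m, method = "euclidean"))
  dimnames(dm) <- NULL
  dm
}

#' k-nearest-neighbour mask
#'
#' `mask[i, j]` is `TRUE` iff `j` is among `i`'s `k` nearest neighbours or
#' vice versa (the union rule), so the mask is symmetric by construction.
#' Distance ties are broken toward the smaller index for determinism.
#'
#' @param distances Symmetric distance matrix.
#' @param k Number of neighbours, `1 <= k <= n_d - 1`.
#' @return Symmetric logical matrix with `FALSE` diagonal.
#' @export
knn_mask <- function(distances, k) {
  nd <- nrow(distances)
  if (k < 1L || k > nd - 1L) stop("k must be in 1..(n_d - 1)")
  mask <- matrix(FALSE, nd, nd)
  for (i in seq_len(nd)) {
    ord <- order(distances[i, -i], seq_len(nd)[-i])  # ties -> smaller index
    nb <- (seq_len(nd)[-i])[ord[seq_len(k)]]
    mask[i, nb] <- TRUE
  }
  mask <- mask | t(mask)
  diag(mask) <- FALSE
  mask
}

# connected components of an undirected graph given as a logical adjacency
# matrix or an edge list; breadth-first search from the smallest unvisited
# index, labels assigned in discovery order
bfs_components <- function(n, edges) {
  adj <- vector("list", n)
  if (length(edges) && nrow(edges) > 0L) {
    for (l in seq_len(nrow(edges))) {
      i <- edges[l, 1L]; j <- edges[l, 2L]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  labels <- integer(n)
  lab <- 0L
  for (s in seq_len(n)) {
    if (labels[s] > 0L) next
    lab <- lab + 1L
    queue <- s
    labels[s] <- lab
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      for (w in adj[[v]]) {
        if (labels[w] == 0L) {
          labels[w] <- lab
          queue <- c(queue, w)
        }
      }
    }
  }
  labels
}

mask_edges <- function(mask) {
  idx <- which(mask & upper.tri(mask), arr.ind = TRUE)
  matrix(as.integer(idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]), ncol = 2L)
}

#' Smallest k giving a connected k-NN graph
#'
#' Scans `k = 1, 2, ...` and returns the first value for which the union-rule
#' k-nearest-neighbour graph on the `n_d` subarrays is connected.
#' `k = n_d - 1` always connects, so the scan terminates.
#'
#' @param distances Symmetric distance matrix, `n_d >= 2`.
#' @return The minimal connecting `k`.
#' @export
smallest_connected_k <- function(distances) {
  nd <- nrow(distances)
  if (nd < 2L) stop("need at least two subarrays")
  for (k in seq_len(nd - 1L)) {
    mask <- knn_mask(distances, k)
    labels <- bfs_components(nd, mask_edges(mask))
    if (max(labels) == 1L) return(k)
  }
  nd - 1L
}

#' Median inverse-scale for the Gaussian kernel
#'
#' Computes the kernel inverse-scale \eqn{\tau_d} from the median `m` of the
#' masked pairwise distances. The default convention is \eqn{\tau_d = 1/m^2}
#' so that the kernel exponent \eqn{\tau_d \, \mathrm{dist}^2} is
#' dimensionless; `convention = "inverse"` gives \eqn{\tau_d = 1/m}.
#'
#' @param distances Symmetric distance matrix.
#' @param mask Symmetric logical mask with at least one `TRUE` pair.
#' @param convention `"inverse_square"` (default) or `"inverse"`.
#' @return Nonnegative scalar \eqn{\tau_d}.
#' @export
median_scale <- function(distances, mask, convention = c("inverse_square", "inverse")) {
  convention <- match.arg(convention)
  sel <- mask & upper.tri(mask)
  if (!any(sel)) stop("mask selects no pairs")
  m <- stats::median(distances[sel])
  if (m == 0) stop("degenerate scale: all masked distances are zero")
  if (convention == "inverse_square") 1 / m^2 else 1 / m
}

#' Gaussian-kernel pre-weights
#'
#' \eqn{\tilde w_{d,ij} = \iota^k_{\{i,j\}} \exp(-\tau_d \,
#' \mathrm{dist}(i,j)^2)}: the k-NN indicator times a Gaussian kernel on the
#' squared subarray distance. \eqn{\tau_d = 0} yields uniform pre-weights on
#' the masked pairs.
#'
#' @param distances Symmetric distance matrix.
#' @param mask Symmetric logical k-NN mask.
#' @param tau Nonnegative inverse scale.
#' @return Symmetric matrix of pre-weights in `[0, 1]`.
#' @export
gaussian_preweights <- function(distances, mask, tau) {
  if (tau < 0) stop("tau must be nonnegative")
  w <- exp(-tau * distances^2)
  w[!mask] <- 0
  diag(w) <- 0
  w
}

#' Normalize mode weights
#'
#' Rescales pre-weights so the mode-`d` weights sum to \eqn{n_d / n}, putting
#' the per-mode penalty terms on a common scale so no single mode dominates
#' the co-clustering as the penalty grows.
#'
#' @param w Vector of pre-weights (one per retained edge), not all zero.
#' @param nd Mode length.
#' @param n Total element count of the tensor.
#' @return Weights summing to `nd / n`.
#' @export
normalize_mode_weights <- function(w, nd, n) {
  s <- sum(w)
  if (s <= 0) stop("pre-weights sum to zero")
  w * (nd / n) / s
}

#' Tucker low-rank denoising
#'
#' Rank-\eqn{(r_1,\dots,r_D)} Tucker approximation by higher-order orthogonal
#' iteration (HOOI), initialized with the truncated higher-order SVD. Used to
#' reduce the noise variance entering the kernel weights: a checkerbox mean
#' tensor is low Tucker rank, so truncation suppresses noise while preserving
#' the block structure.
#'
#' @param x A dense numeric array.
#' @param ranks Integer vector of per-mode ranks, `1 <= ranks[d] <= n_d`.
#' @param max_sweeps Maximum HOOI sweeps.
#' @param tol Relative change in fit at which to stop.
#' @return Array of the same shape as `x`.
#' @export
tucker_denoise <- function(x, ranks, max_sweeps = 25L, tol = 1e-8) {
  d <- dim(x)
  D <- length(d)
  ranks <- as.integer(ranks)
  if (length(ranks) != D || any(ranks < 1L) || any(ranks > d)) {
    stop("ranks must satisfy 1 <= ranks[d] <= n_d for every mode")
  }
  lead_svd <- function(m, r) {
    # leading r left singular vectors
    s <- svd(m, nu = r, nv = 0)
    s$u
  }
  U <- vector("list", D)
  for (dd in seq_len(D)) U[[dd]] <- lead_svd(tensor_unfold(x, dd), ranks[dd])
  prev_fit <- -Inf
  core <- NULL
  for (sweep in seq_len(max_sweeps)) {
    for (dd in seq_len(D)) {
      y <- x
      for (j in seq_len(D)) {
        if (j != dd) y <- ttm(y, t(U[[j]]), j)
      }
      U[[dd]] <- lead_svd(tensor_unfold(y, dd), ranks[dd])
    }
    core <- x
    for (j in seq_len(D)) core <- ttm(core, t(U[[j]]), j)
    fit <- tensor_norm(core)
    if (is.finite(prev_fit) && abs(fit - prev_fit) <= tol * max(1, prev_fit)) break
    prev_fit <- fit
  }
  out <- core
  for (j in seq_len(D)) out <- ttm(out, U[[j]], j)
  out
}

default_tucker_ranks <- function(dims) {
  pmin(dims, pmax(2L, ceiling(sqrt(dims))))
}

# relative weight floor under which an edge is numerically inert: in the
# penalty sum over a mode, a term whose weight sits more than ~12 decades
# below the mode's largest weight is smaller than the double-precision
# rounding of that sum, so the edge cannot influence the estimate, and the
# penalty needed to fuse it lies beyond any reachable grid
inert_weight_floor <- function() 1e-12

#' Weight configuration
#'
#' Collects the tunables of adaptive weight construction. All entries may be
#' scalars (recycled across modes) or per-mode vectors/lists.
#'
#' @param k Neighbours per mode, or `"auto"` for the smallest connecting k.
#' @param tau Kernel inverse scale per mode, or `"auto"` for the median rule,
#'   or `0` for uniform pre-weights on the k-NN graph.
#' @param tucker_ranks Per-mode Tucker ranks, `"auto"` for the shape-driven
#'   default `min(n_d, max(2, ceiling(sqrt(n_d))))`, or `"off"` to skip
#'   denoising.
#' @param scheme `"adaptive"` (k-NN Gaussian-kernel weights) or
#'   `"theory_uniform"` (complete graph, every weight `1/n_d`).
#' @param tau_convention Median-scale convention, see [median_scale()].
#' @return A list of class `"weight_config"`.
#' @export
weight_config <- function(k = "auto", tau = "auto", tucker_ranks = "auto",
                          scheme = c("adaptive", "theory_uniform"),
                          tau_convention = c("inverse_square", "inverse")) {
  structure(list(k = k, tau = tau, tucker_ranks = tucker_ranks,
                 scheme = match.arg(scheme),
                 tau_convention = match.arg(tau_convention)),
            class = "weight_config")
}

per_mode <- function(value, D) {
  if (is.list(value)) {
    if (length(value) == 1L) value <- rep(value, D)
    if (length(value) != D) stop("per-mode setting has wrong length")
    return(value)
  }
  if (length(value) == 1L) return(rep(list(value), D))
  if (length(value) != D) stop("per-mode setting has wrong length")
  as.list(value)
}

#' Build per-mode fusion graphs and weights
#'
#' For the adaptive scheme: optionally Tucker-denoise the tensor, compute
#' per-mode subarray distances on the denoised tensor, sparsify by
#' k-nearest-neighbours (auto k = smallest connecting k), evaluate
#' Gaussian-kernel pre-weights at the median scale, and normalize each mode's
#' weights to sum to \eqn{n_d/n}. The theory-uniform scheme returns the
#' complete graph per mode with every weight \eqn{1/n_d}.
#'
#' Edges whose final weight underflows to zero are dropped; if a mode graph
#' thereby becomes disconnected a warning is issued (the objective then
#' separates over the components and full fusion to the grand mean is no
#' longer attainable).
#'
#' @param x A dense numeric array.
#' @param config A [weight_config()].
#' @return A `"coco_graph"`: list with `dims`, `modes` (per mode: `edges`,
#'   `weights`, `k`, `tau`), `scheme`, `tucker_ranks`.
#' @export
coco_weights <- function(x, config = weight_config()) {
  dims <- dim(x)
  D <- length(dims)
  n <- prod(dims)
  if (config$scheme == "theory_uniform") {
    modes <- lapply(seq_len(D), function(d) {
      nd <- dims[d]
      pairs <- which(upper.tri(diag(nd)), arr.ind = TRUE)
      edges <- matrix(as.integer(pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]),
                      ncol = 2L)
      list(edges = edges, weights = rep(1 / nd, nrow(edges)),
           k = nd - 1L, tau = 0)
    })
    return(structure(list(dims = dims, modes = modes, scheme = "theory_uniform",
                          tucker_ranks = NULL),
                     class = "coco_graph"))
  }
  ranks_spec <- config$tucker_ranks
  if (identical(ranks_spec, "off")) {
    xd <- x
    ranks <- NULL
  } else {
    ranks <- if (identical(ranks_spec, "auto")) default_tucker_ranks(dims)
             else as.integer(ranks_spec)
    xd <- tucker_denoise(x, ranks)
  }
  ks <- per_mode(config$k, D)
  taus <- per_mode(config$tau, D)
  modes <- vector("list", D)
  for (d in seq_len(D)) {
    dm <- mode_distances(xd, d)
    k <- if (identical(ks[[d]], "auto")) smallest_connected_k(dm) else as.integer(ks[[d]])
    mask <- knn_mask(dm, k)
    tau <- taus[[d]]
    if (identical(tau, "auto")) {
      tau <- tryCatch(median_scale(dm, mask, config$tau_convention),
                      error = function(e) 0)
    }
    tau <- as.double(tau)
    pw <- gaussian_preweights(dm, mask, tau)
    edges <- mask_edges(mask)
    w <- pw[edges]
    if (!any(w > 0)) stop("all pre-weights are zero in mode ", d)
    w <- normalize_mode_weights(w, dims[d], n)
    # drop numerically inert edges (weights >12 decades below the mode's
    # leading weight): their penalty terms are below the rounding of the
    # per-mode sum, and the gamma needed to fuse them is unreachable, so
    # keeping them only stalls full fusion; the removed mass is < 1e-12
    # relative, leaving the n_d/n sum constraint intact
    keep <- w > max(w) * inert_weight_floor()
    edges <- edges[keep, , drop = FALSE]
    w <- w[keep]
    labels <- bfs_components(dims[d], edges)
    if (max(labels) > 1L) {
      warning("mode ", d, " graph is disconnected after dropping ",
              "numerically inert edges; the objective separates over its ",
              max(labels), " components and full fusion to the grand mean ",
              "is unattainable")
    }
    modes[[d]] <- list(edges = edges, weights = w, k = k, tau = tau)
  }
  structure(list(dims = dims, modes = modes, scheme = "adaptive",
                 tucker_ranks = ranks),
            class = "coco_graph")
}

#' Serialize mode graphs to an edge table
#'
#' @param graph A `"coco_graph"`.
#' @return A tibble with columns `mode`, `i`, `j`, `weight` (1-based indices).
#' @export
graph_edge_table <- function(graph) {
  rows <- lapply(seq_along(graph$modes), function(d) {
    g <- graph$modes[[d]]
    if (nrow(g$edges) == 0L) return(NULL)
    tibble::tibble(mode = d, i = g$edges[, 1L], j = g$edges[, 2L],
                   weight = g$weights)
  })
  do.call(rbind, rows)
}
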