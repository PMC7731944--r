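# Independent brute-force oracles used by the tests. These deliberately use
# dense Kronecker assembly and generic algorithms, never the package's
# matrix-free code paths.

# dense matrix of the per-edge difference map: I_{n_D} x ... x Delta x ... x I_{n_1}
dense_edge_matrix <- function(dims, mode, i, j) {
  D <- length(dims)
  delta <- matrix(0, 1, dims[mode])
  delta[1, i] <- 1
  delta[1, j] <- -1
  factors <- lapply(seq_len(D), function(d) diag(dims[d]))
  factors[[mode]] <- delta
  out <- factors[[D]]
  if (D > 1) for (d in (D - 1):1) out <- kronecker(out, factors[[d]])
  out
}

# stacked dense operator rows for a whole graph: list of per-mode lists of
# n_{-d} x n matrices, one per edge
dense_graph_matrices <- function(graph) {
  lapply(seq_along(graph$modes), function(d) {
    e <- graph$modes[[d]]$edges
    lapply(seq_len(nrow(e)), function(l) {
      dense_edge_matrix(graph$dims, d, e[l, 1], e[l, 2])
    })
  })
}

# naive primal objective via the dense matrices
naive_primal <- function(u, x, graph, gamma, mats = dense_graph_matrices(graph)) {
  val <- 0.5 * sum((as.vector(x) - as.vector(u))^2)
  for (d in seq_along(mats)) {
    w <- graph$modes[[d]]$weights
    for (l in seq_along(mats[[d]])) {
      val <- val + gamma * w[l] * sqrt(sum((mats[[d]][[l]] %*% as.vector(u))^2))
    }
  }
  val
}

block_soft <- function(z, thr) {
  nz <- sqrt(sum(z^2))
  if (nz <= thr) z * 0 else z * (1 - thr / nz)
}

# independent primal minimizer: ADMM on the variable-split problem with dense
# operators and block soft-thresholding
admm_primal_oracle <- function(x, graph, gamma, rho = 1, iters = 4000L) {
  xvec <- as.vector(x)
  n <- length(xvec)
  mats <- dense_graph_matrices(graph)
  A_list <- list()
  w_list <- numeric(0)
  for (d in seq_along(mats)) {
    for (l in seq_along(mats[[d]])) {
      A_list[[length(A_list) + 1L]] <- mats[[d]][[l]]
      w_list <- c(w_list, graph$modes[[d]]$weights[l])
    }
  }
  if (!length(A_list) || gamma == 0) return(array(xvec, dim = graph$dims))
  AtA <- Reduce(`+`, lapply(A_list, crossprod))
  M <- solve(diag(n) + rho * AtA)
  v <- lapply(A_list, function(A) as.vector(A %*% xvec))
  z <- lapply(v, function(vl) vl * 0)
  u <- xvec
  for (it in seq_len(iters)) {
    rhs <- xvec
    for (l in seq_along(A_list)) {
      rhs <- rhs + rho * as.vector(crossprod(A_list[[l]], v[[l]] - z[[l]]))
    }
    u <- as.vector(M %*% rhs)
    for (l in seq_along(A_list)) {
      au <- as.vector(A_list[[l]] %*% u)
      v[[l]] <- block_soft(au + z[[l]], gamma * w_list[l] / rho)
      z[[l]] <- z[[l]] + au - v[[l]]
    }
  }
  array(u, dim = graph$dims)
}

# direct Hubert-Arabie ARI from the contingency table
ari_oracle <- function(a, b) {
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  expected <- ai * bj / n2
  maxi <- (ai + bj) / 2
  if (maxi == expected) return(0)
  (nij - expected) / (maxi - expected)
}

# a small random sparse connected graph on nd nodes with positive weights
random_mode_graph <- function(nd, p = 0.6) {
  repeat {
    pairs <- which(upper.tri(diag(nd)), arr.ind = TRUE)
    keep <- stats::runif(nrow(pairs)) < p
    edges <- pairs[keep, , drop = FALSE]
    if (nrow(edges) >= 1 &&
        max(cocotensor::connected_components(nd, edges)) == 1) {
      return(list(edges = matrix(as.integer(edges), ncol = 2),
                  weights = stats::runif(nrow(edges), 0.2, 1)))
    }
  }
}

random_graph <- function(dims, p = 0.6) {
  modes <- lapply(dims, function(nd) {
    g <- random_mode_graph(nd, p)
    c(g, list(k = NA_integer_, tau = NA_real_))
  })
  structure(list(dims = as.integer(dims), modes = modes, scheme = "manual",
                 tucker_ranks = NULL), class = "coco_graph")
}

rand_tensor <- function(dims) {
  array(stats::rnorm(prod(dims)), dim = dims)
}
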