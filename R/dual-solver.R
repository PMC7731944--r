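#' Euclidean projection onto a centered ball
#'
#' Returns `z` when `||z||_2 <= r`, otherwise `z * r / ||z||_2`. This is the
#' projection onto the dual feasible set
#' \eqn{C_{d,l} = \{z : \|z\|_2 \le \gamma w_{d,l}\}}.
#'
#' @param z Numeric vector.
#' @param r Nonnegative radius.
#' @return Projected vector.
#' @export
project_to_ball <- function(z, r) {
  if (r < 0) stop("radius must be nonnegative")
  nz <- sqrt(sum(z^2))
  if (nz <= r) z else z * (r / nz)
}

build_ops <- function(graph) {
  lapply(seq_along(graph$modes), function(d) {
    difference_op(graph$dims, d, graph$modes[[d]]$edges)
  })
}

#' Primal co-clustering objective
#'
#' \eqn{F_\gamma(u) = \tfrac12\|x - u\|_2^2 + \gamma \sum_d \sum_l w_{d,l}
#' \|A_{d,l} u\|_2}: squared-error fit plus the weighted sum of l2 norms of
#' the per-edge mode-subarray differences.
#'
#' @param u Candidate tensor (array or vector).
#' @param x Data tensor (array or vector) of the same size.
#' @param graph A `"coco_graph"`.
#' @param gamma Nonnegative penalty parameter.
#' @param ops Optional precomputed difference operators.
#' @return Scalar objective value.
#' @export
primal_objective <- function(u, x, graph, gamma, ops = build_ops(graph)) {
  uvec <- as.vector(u)
  xvec <- as.vector(x)
  pen <- 0
  for (d in seq_along(ops)) {
    w <- graph$modes[[d]]$weights
    if (!length(w)) next
    V <- diff_apply(ops[[d]], tensor_unvec(uvec, graph$dims))
    pen <- pen + sum(w * sqrt(colSums(V^2)))
  }
  0.5 * sum((xvec - uvec)^2) + gamma * pen
}

lambda_zero <- function(graph) {
  n_minus <- prod(graph$dims) / graph$dims
  lapply(seq_along(graph$modes), function(d) {
    matrix(0, nrow = n_minus[d], ncol = nrow(graph$modes[[d]]$edges))
  })
}

at_lambda <- function(ops, lambda, dims) {
  # A^T lambda as a vector
  out <- numeric(prod(dims))
  for (d in seq_along(ops)) {
    if (ncol(lambda[[d]]) == 0L) next
    out <- out + diff_apply_t(ops[[d]], lambda[[d]])
  }
  out
}

lambda_feasible <- function(lambda, graph, gamma, slack = 1e-9) {
  for (d in seq_along(lambda)) {
    w <- graph$modes[[d]]$weights
    if (!length(w)) next
    norms <- sqrt(colSums(lambda[[d]]^2))
    if (any(norms > gamma * w * (1 + slack) + slack)) return(FALSE)
  }
  TRUE
}

#' Lagrangian dual objective
#'
#' \eqn{G(\lambda) = \tfrac12\|x\|_2^2 - \tfrac12\|x - A^\top\lambda\|_2^2}
#' on the feasible set (every block inside its ball), `-Inf` off it. Weak
#' duality gives \eqn{G(\lambda) \le F_\gamma(u)} for every feasible
#' \eqn{\lambda} and every \eqn{u}.
#'
#' @param lambda List of per-mode block matrices (`n_{-d} x |E_d|`).
#' @param x Data tensor (array or vector).
#' @param graph A `"coco_graph"`.
#' @param gamma Penalty parameter.
#' @param ops Optional precomputed difference operators.
#' @return Scalar dual value, `-Inf` when infeasible.
#' @export
dual_objective <- function(lambda, x, graph, gamma, ops = build_ops(graph)) {
  if (!lambda_feasible(lambda, graph, gamma)) return(-Inf)
  xvec <- as.vector(x)
  resid <- xvec - at_lambda(ops, lambda, graph$dims)
  0.5 * sum(xvec^2) - 0.5 * sum(resid^2)
}

#' Step size from a power-iteration bound
#'
#' Estimates the largest eigenvalue `L` of \eqn{A A^\top} (equivalently of
#' \eqn{A^\top A = \sum_d A_d^\top A_d}, the sum of graph-Laplacian Kronecker
#' lifts) by power iteration on the matrix-free operator with a fixed
#' iteration budget and seed, and returns `eta = 1/L`.
#'
#' @param graph A `"coco_graph"` with at least one edge.
#' @param iters Power-iteration budget.
#' @param seed Seed for the random start vector.
#' @return Positive step size.
#' @export
auto_step_size <- function(graph, iters = 100L, seed = 1L) {
  n_edges <- vapply(graph$modes, function(g) nrow(g$edges), 0L)
  if (sum(n_edges) == 0L) stop("graph has no edges")
  n <- prod(graph$dims)
  had_seed <- exists(".Random.seed", envir = globalenv())
  if (had_seed) saved <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  v <- stats::rnorm(n)
  if (had_seed) assign(".Random.seed", saved, envir = globalenv())
  v <- v / sqrt(sum(v^2))
  edge_list <- lapply(graph$modes, function(g) {
    storage.mode(g$edges) <- "integer"
    g$edges
  })
  dims <- as.integer(graph$dims)
  L <- 0
  for (it in seq_len(iters)) {
    av <- .coco_ata_apply(v, dims, edge_list)
    L <- sum(v * av)
    nv <- sqrt(sum(av^2))
    if (nv == 0) break
    v <- av / nv
  }
  if (L <= 0) stop("power iteration failed")
  1 / L
}

#' Solver configuration
#'
#' @param step Step size `eta`, or `"auto"` for the power-iteration bound.
#' @param max_iter Maximum projected-gradient iterations.
#' @param tol Relative duality-gap tolerance.
#' @param accelerate Use FISTA-style momentum with function-value restart;
#'   `FALSE` gives plain projected gradient with monotone dual ascent.
#' @param check_every Evaluate the duality gap every this many iterations.
#' @return A list of class `"solver_config"`.
#' @export
solver_config <- function(step = "auto", max_iter = 20000L, tol = 1e-6,
                          accelerate = TRUE, check_every = 10L) {
  if (!identical(step, "auto") && step <= 0) stop("step must be positive")
  if (tol <= 0) stop("tol must be positive")
  structure(list(step = step, max_iter = as.integer(max_iter), tol = tol,
                 accelerate = isTRUE(accelerate),
                 check_every = as.integer(check_every)),
            class = "solver_config")
}

project_lambda <- function(lambda, graph, gamma) {
  for (d in seq_along(lambda)) {
    w <- graph$modes[[d]]$weights
    if (!length(w)) next
    norms <- sqrt(colSums(lambda[[d]]^2))
    radii <- gamma * w
    over <- which(norms > radii)
    if (length(over)) {
      scale <- radii[over] / norms[over]
      lambda[[d]][, over] <- sweep(lambda[[d]][, over, drop = FALSE], 2L, scale, `*`)
    }
  }
  lambda
}

#' Solve the convex co-clustering problem at one gamma
#'
#' Minimizes the fusion-penalized least-squares objective by (accelerated)
#' projected gradient on its Lagrangian dual: alternate a gradient step on
#' \eqn{\tfrac12\|x - A^\top\lambda\|_2^2} with projection of every dual
#' block onto its ball \eqn{\|\lambda_{d,l}\|_2 \le \gamma w_{d,l}}. The
#' primal solution is recovered exactly as \eqn{\hat u = x - A^\top\hat\lambda}
#' and iteration stops when the relative duality gap
#' \eqn{(F - G)/\max(1, F)} falls below `tol`.
#'
#' @param x Data tensor (dense array).
#' @param graph A `"coco_graph"` built on the same shape.
#' @param gamma Nonnegative penalty parameter.
#' @param control A [solver_config()].
#' @param lambda0 Optional warm-start dual blocks (projected onto the new
#'   feasible set before use).
#' @return A `"coco_fit"`: `u_hat` (array), `gamma`, `lambda` (dual blocks),
#'   `diff_norms` / `dual_norms` (per mode, per edge), `iterations`, `gap`
#'   (relative duality gap), `converged`, `primal`, `dual`.
#' @export
coco_fit <- function(x, graph, gamma, control = solver_config(), lambda0 = NULL) {
  stopifnot(gamma >= 0)
  dims <- graph$dims
  if (!identical(as.integer(dim(x)), as.integer(dims))) {
    stop("tensor shape does not match graph")
  }
  xvec <- as.vector(x)
  n_edges <- vapply(graph$modes, function(g) nrow(g$edges), 0L)
  if (gamma == 0 || sum(n_edges) == 0L) {
    ops <- build_ops(graph)
    u <- tensor_unvec(xvec, dims)
    diff_norms <- lapply(seq_along(ops), function(d) {
      if (n_edges[d] == 0L) return(numeric(0))
      sqrt(colSums(diff_apply(ops[[d]], u)^2))
    })
    lambda <- lambda_zero(graph)
    return(structure(list(u_hat = u, gamma = gamma, lambda = lambda,
                          diff_norms = diff_norms,
                          dual_norms = lapply(n_edges, numeric),
                          iterations = 0L, gap = 0, converged = TRUE,
                          primal = primal_objective(xvec, xvec, graph, gamma, ops),
                          dual = NULL, dims = dims),
                     class = "coco_fit"))
  }
  eta <- if (identical(control$step, "auto")) auto_step_size(graph) else control$step
  edge_list <- lapply(graph$modes, function(g) {
    storage.mode(g$edges) <- "integer"
    g$edges
  })
  weight_list <- lapply(graph$modes, function(g) as.double(g$weights))
  out <- .coco_dual_pg(as.double(xvec), as.integer(dims), edge_list,
                       weight_list, gamma, eta, control$max_iter,
                       control$tol, control$accelerate, control$check_every,
                       lambda0)
  structure(list(u_hat = tensor_unvec(out$u, dims), gamma = gamma,
                 lambda = out$lambda, diff_norms = out$diff_norms,
                 dual_norms = out$dual_norms, iterations = out$iterations,
                 gap = max(out$gap, 0), converged = out$converged,
                 primal = out$primal, dual = out$dual, dims = dims),
            class = "coco_fit")
}

#' Solve a path of gammas with warm starts
#'
#' Fits the model at each grid value in ascending order, initializing each
#' solve at the previous solution's dual variables projected onto the new
#' feasible set (the estimator is continuous in gamma, so warm starts save
#' substantial work without changing the answer).
#'
#' @param x Data tensor.
#' @param graph A `"coco_graph"`.
#' @param gammas Ascending nonnegative grid.
#' @param control A [solver_config()].
#' @param warm_start Use warm starts (default `TRUE`).
#' @param keep_dual Keep the dual block matrices on every returned fit. With
#'   `FALSE` the `lambda` field is dropped after each solve (the per-edge
#'   `dual_norms` needed for partition extraction are always retained), which
#'   bounds the path's memory at roughly one fit regardless of grid length.
#' @return List of `"coco_fit"` objects, one per grid value, class
#'   `"coco_path_fits"`.
#' @export
coco_path_fits <- function(x, graph, gammas, control = solver_config(),
                           warm_start = TRUE, keep_dual = TRUE) {
  if (is.unsorted(gammas)) stop("gamma grid must be ascending")
  if (any(gammas < 0)) stop("gammas must be nonnegative")
  if (identical(control$step, "auto")) {
    control$step <- auto_step_size(graph)  # depends on the graph only
  }
  fits <- vector("list", length(gammas))
  lambda_prev <- NULL
  for (t in seq_along(gammas)) {
    fits[[t]] <- coco_fit(x, graph, gammas[t], control,
                          lambda0 = if (warm_start) lambda_prev else NULL)
    lambda_prev <- fits[[t]]$lambda
    if (!keep_dual) fits[[t]]$lambda <- NULL
  }
  structure(fits, class = "coco_path_fits")
}

#' @export
print.coco_fit <- function(x, ...) {
  cat("<coco_fit> gamma =", format(x$gamma),
      "| iterations =", x$iterations,
      "| rel. duality gap =", format(x$gap, digits = 3),
      "| converged =", x$converged, "\n")
  invisible(x)
}
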