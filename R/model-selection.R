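#' Number of co-clusters implied by per-mode partitions
#'
#' The degrees of freedom of a checkerbox fit: the product
#' \eqn{\prod_d \hat k_d} of per-mode cluster counts, one estimated mean per
#' cell.
#'
#' @param labels List of per-mode integer label vectors (or a
#'   `"coco_clustering"`).
#' @return Integer count.
#' @export
count_co_clusters <- function(labels) {
  if (inherits(labels, "coco_clustering")) labels <- labels$labels
  prod(vapply(labels, function(l) as.integer(max(l)), 0L))
}

#' Extended BIC for a fitted tensor
#'
#' \eqn{\mathrm{eBIC}(\gamma) = n \log(\mathrm{RSS}_\gamma / n) +
#' 2\,\mathrm{df}_\gamma \log n} with
#' \eqn{\mathrm{RSS}_\gamma = \|x - \hat u_\gamma\|_2^2} and df the number of
#' co-clusters. A floor of \eqn{10^{-12}\|x\|_2^2} guards the log when the
#' fit is exact (RSS = 0); the returned value carries attribute `"floored"`
#' when the guard triggered.
#'
#' @param x Data tensor (array or vector).
#' @param u_hat Fitted tensor of the same size.
#' @param df Number of co-clusters, `>= 1`.
#' @return Scalar criterion value.
#' @export
ebic <- function(x, u_hat, df) {
  if (df < 1) stop("df must be >= 1")
  xvec <- as.vector(x)
  n <- length(xvec)
  rss <- sum((xvec - as.vector(u_hat))^2)
  floor_val <- 1e-12 * sum(xvec^2)
  floored <- rss < floor_val
  val <- n * log(max(rss, floor_val) / n) + 2 * df * log(n)
  attr(val, "floored") <- floored
  val
}

#' Select gamma by minimum eBIC
#'
#' Returns the grid index attaining the smallest eBIC; ties are broken toward
#' the smaller gamma.
#'
#' @param gammas Grid values.
#' @param ebics Finite criterion values aligned with `gammas`.
#' @return Index of the selected gamma.
#' @export
select_gamma <- function(gammas, ebics) {
  if (!length(gammas)) stop("empty path")
  if (length(gammas) != length(ebics)) stop("length mismatch")
  which.min(ebics)  # which.min returns the first (smallest-gamma) minimizer
}

#' Find a fully-fusing gamma by doubling
#'
#' Starts at `gamma = 1` and doubles until the fit at that gamma is fully
#' fused, up to `max_doublings`. With connected mode graphs "fully fused"
#' means a single co-cluster (the grand mean); when a mode graph has several
#' connected components the objective separates and the attainable limit is
#' one cluster per component, so the search stops there instead.
#'
#' @param x Data tensor.
#' @param graph A `"coco_graph"`.
#' @param control A [solver_config()].
#' @param max_doublings Cap on doublings.
#' @return The discovered gamma.
#' @export
gamma_max <- function(x, graph, control = solver_config(), max_doublings = 60L) {
  g <- 1
  if (identical(control$step, "auto")) control$step <- auto_step_size(graph)
  # full fusion can only reach one cluster per graph component
  k_target <- vapply(seq_along(graph$modes), function(d) {
    max(bfs_components(graph$dims[d], graph$modes[[d]]$edges))
  }, 0L)
  lambda <- NULL
  for (i in seq_len(max_doublings + 1L)) {
    fit <- coco_fit(x, graph, g, control, lambda0 = lambda)
    lambda <- fit$lambda
    cl <- coco_clusters(fit, graph, x)
    if (all(cl$k <= k_target)) return(g)
    g <- 2 * g
  }
  warning("gamma_max cap reached without full fusion")
  g
}

#' Default gamma grid
#'
#' Geometric grid of `size` points from \eqn{10^{-4}\gamma_{max}} to the
#' doubling-discovered \eqn{\gamma_{max}}. With `theory = TRUE` the endpoints
#' are instead the tuning-window bounds \eqn{2\log(n)/(nD)} and
#' \eqn{2 c_0 \log(n)/(nD)} appropriate for uniform weights.
#'
#' @param x Data tensor.
#' @param graph A `"coco_graph"`.
#' @param size Number of grid points, `>= 2`.
#' @param control A [solver_config()].
#' @param theory Use the theory window instead of the data-driven range.
#' @param c0 Constant `> 1` for the theory window's upper endpoint.
#' @return Strictly increasing positive grid.
#' @export
default_gamma_grid <- function(x, graph, size = 30L, control = solver_config(),
                               theory = FALSE, c0 = 2) {
  if (size < 2L) stop("size must be >= 2")
  if (theory) {
    if (c0 <= 1) stop("c0 must exceed 1")
    n <- prod(dim(x))
    D <- length(dim(x))
    lo <- 2 * log(n) / (n * D)
    hi <- 2 * c0 * log(n) / (n * D)
  } else {
    hi <- gamma_max(x, graph, control)
    lo <- 1e-4 * hi
  }
  exp(seq(log(lo), log(hi), length.out = size))
}

#' Fit a path and score it with the eBIC
#'
#' Solves the model over a gamma grid with warm starts, extracts partitions
#' at every grid point, scores each by eBIC and selects the minimizer.
#'
#' @param x Data tensor.
#' @param graph A `"coco_graph"` (default: adaptive weights on `x`).
#' @param gammas Grid; default [default_gamma_grid()].
#' @param control A [solver_config()].
#' @param ... Passed to [coco_clusters()].
#' @return A `"coco_path"`: tibble-backed `summary` (gamma, rss, df, ebic,
#'   per-mode k, selected flag), `fits`, `clusterings`, `selected` index,
#'   `graph`.
#' @export
coco_path <- function(x, graph = coco_weights(x), gammas = NULL,
                      control = solver_config(), ...) {
  if (is.null(gammas)) gammas <- default_gamma_grid(x, graph, control = control)
  fits <- coco_path_fits(x, graph, gammas, control, keep_dual = FALSE)
  clusterings <- lapply(fits, coco_clusters, graph = graph, x = x, ...)
  xvec <- as.vector(x)
  rss <- vapply(fits, function(f) sum((xvec - as.vector(f$u_hat))^2), 0)
  df <- vapply(clusterings, count_co_clusters, 0)
  ebics <- vapply(seq_along(fits),
                  function(t) as.numeric(ebic(x, fits[[t]]$u_hat, df[t])), 0)
  # a saturated fit (df = n, every element its own co-cluster) interpolates,
  # so its likelihood term n*log(RSS/n) diverges and the criterion carries no
  # information; select among non-saturated candidates when any exist
  n <- length(xvec)
  usable <- df < n
  sel <- if (any(usable)) {
    which(usable)[select_gamma(gammas[usable], ebics[usable])]
  } else {
    select_gamma(gammas, ebics)
  }
  kmat <- do.call(rbind, lapply(clusterings, function(cl) cl$k))
  colnames(kmat) <- paste0("k", seq_len(ncol(kmat)))
  summary <- tibble::tibble(gamma = gammas, rss = rss, df = df, ebic = ebics,
                            tibble::as_tibble(kmat),
                            selected = seq_along(gammas) == sel)
  structure(list(summary = summary, fits = fits, clusterings = clusterings,
                 selected = sel, gamma_star = gammas[sel], graph = graph),
            class = "coco_path")
}

#' Convex co-clustering with automatic tuning
#'
#' End-to-end front door: builds adaptive fusion weights, fits the penalty
#' path, selects gamma by eBIC and returns the selected clustering together
#' with the whole path.
#'
#' @param x Data tensor (dense numeric array, `D >= 2`).
#' @param weights A [weight_config()] or a prebuilt `"coco_graph"`.
#' @param gammas Optional explicit grid.
#' @param grid_size Grid size when `gammas` is `NULL`.
#' @param control A [solver_config()].
#' @return A `"coco"` object: `clustering` (the selected
#'   `"coco_clustering"`), `fit` (selected `"coco_fit"`), `path`
#'   (`"coco_path"`), `gamma_star`.
#' @examples
#' sim <- simulate_checkerbox(checkerbox_spec(dims = c(12, 12, 12),
#'                                            clusters = c(2, 2, 2),
#'                                            delta = 3, sigma = 0.5, seed = 1))
#' res <- coco(sim$x, grid_size = 10)
#' res$clustering$k
#' @export
coco <- function(x, weights = weight_config(), gammas = NULL, grid_size = 30L,
                 control = solver_config()) {
  x <- as_tensor(x)
  graph <- if (inherits(weights, "coco_graph")) weights else coco_weights(x, weights)
  if (is.null(gammas)) {
    gammas <- default_gamma_grid(x, graph, size = grid_size, control = control)
  }
  path <- coco_path(x, graph, gammas, control)
  structure(list(clustering = path$clusterings[[path$selected]],
                 fit = path$fits[[path$selected]],
                 path = path, gamma_star = path$gamma_star),
            class = "coco")
}

#' @export
print.coco <- function(x, ...) {
  cat("<coco> selected gamma =", format(x$gamma_star),
      "| co-clusters =", count_co_clusters(x$clustering),
      "(", paste(x$clustering$k, collapse = " x "), ")\n")
  invisible(x)
}

#' @export
print.coco_path <- function(x, ...) {
  cat("<coco_path>", nrow(x$summary), "grid points, selected gamma =",
      format(x$gamma_star), "\n")
  print(x$summary)
  invisible(x)
}

#' Tidy the path summary
#'
#' @param x A `"coco_path"` or `"coco"`.
#' @param ... Unused.
#' @return Tibble with one row per grid point: gamma, rss, df, ebic,
#'   per-mode cluster counts and the selected flag.
#' @export
tidy.coco_path <- function(x, ...) x$summary

#' @rdname tidy.coco_path
#' @export
tidy.coco <- function(x, ...) x$path$summary

#' One-row summary of a tuned fit
#'
#' @param x A `"coco"`.
#' @param ... Unused.
#' @return Tibble with gamma_star, rss, df, ebic, convergence diagnostics.
#' @export
glance.coco <- function(x, ...) {
  s <- x$path$summary[x$path$selected, ]
  tibble::tibble(gamma_star = x$gamma_star, rss = s$rss, df = s$df,
                 ebic = s$ebic, iterations = x$fit$iterations,
                 gap = x$fit$gap, converged = x$fit$converged)
}

#' Plot the eBIC path
#'
#' @param object A `"coco_path"` or `"coco"`.
#' @param ... Unused.
#' @return A ggplot showing eBIC (and df) against gamma with the selected
#'   gamma marked.
#' @export
autoplot.coco_path <- function(object, ...) {
  s <- object$summary
  ggplot2::ggplot(s, ggplot2::aes(x = gamma, y = ebic)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = selected)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(gamma), y = "eBIC",
                  colour = "selected") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.coco_path
#' @export
autoplot.coco <- function(object, ...) autoplot.coco_path(object$path, ...)

utils::globalVariables(c("gamma", "ebic", "selected"))
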