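khatri_rao <- function(a, b) {
  # column-wise Khatri-Rao product
  out <- matrix(0, nrow(a) * nrow(b), ncol(a))
  for (r in seq_len(ncol(a))) out[, r] <- kronecker(a[, r], b[, r])
  out
}

#' Rank-R CP decomposition by alternating least squares
#'
#' Standard CP-ALS with seeded random initialization and multi-start
#' best-fit: each mode's factor matrix is updated in turn by a least-squares
#' solve against the Khatri-Rao product of the others, with column
#' normalization absorbed into the scale vector.
#'
#' @param x Dense numeric array.
#' @param R Target rank.
#' @param n_starts Number of random restarts; the best-fit solution is kept.
#' @param max_iter ALS sweeps per start.
#' @param tol Relative fit-change tolerance.
#' @param seed Integer seed.
#' @return List with `factors` (list of `n_d x R` matrices), `lambda`
#'   (component scales), `fit` (relative reconstruction fit in `[0, 1]`).
#' @export
cp_als <- function(x, R, n_starts = 3L, max_iter = 100L, tol = 1e-7, seed = 1L) {
  dims <- dim(x)
  D <- length(dims)
  if (R < 1L || R > min(prod(dims) / dims)) stop("infeasible CP rank")
  xnorm <- tensor_norm(x)
  unfolds <- lapply(seq_len(D), function(d) tensor_unfold(x, d))
  best <- NULL
  for (s in seq_len(n_starts)) {
    set.seed(seed + s - 1L)
    U <- lapply(dims, function(nd) matrix(stats::rnorm(nd * R), nd, R))
    fit_prev <- -Inf
    lambda <- rep(1, R)
    for (it in seq_len(max_iter)) {
      for (d in seq_len(D)) {
        # Khatri-Rao of all other factors, reverse mode order, skipping d
        others <- rev(setdiff(seq_len(D), d))
        kr <- U[[others[1L]]]
        for (j in others[-1L]) kr <- khatri_rao(kr, U[[j]])
        G <- Reduce(`*`, lapply(setdiff(seq_len(D), d),
                                function(j) crossprod(U[[j]])))
        Ud <- unfolds[[d]] %*% kr %*% solve(G + 1e-12 * diag(R))
        lambda <- sqrt(colSums(Ud^2))
        lambda[lambda == 0] <- 1e-12
        U[[d]] <- sweep(Ud, 2L, lambda, `/`)
      }
      # reconstruction fit
      full <- cp_reconstruct(U, lambda, dims)
      fit <- 1 - tensor_norm(x - full) / max(xnorm, .Machine$double.eps)
      if (is.finite(fit_prev) && abs(fit - fit_prev) < tol) break
      if (!is.finite(fit)) break
      fit_prev <- fit
    }
    if (!is.finite(fit)) next
    if (is.null(best) || fit > best$fit) {
      best <- list(factors = U, lambda = lambda, fit = fit)
    }
  }
  if (is.null(best)) stop("CP-ALS failed to produce a finite fit")
  best
}

cp_reconstruct <- function(U, lambda, dims) {
  D <- length(U)
  others <- rev(seq_len(D))[rev(seq_len(D)) != 1L]
  kr <- U[[others[1L]]]
  for (j in others[-1L]) kr <- khatri_rao(kr, U[[j]])
  m1 <- U[[1L]] %*% diag(lambda, nrow = length(lambda)) %*% t(kr)
  tensor_fold(m1, 1L, dims)
}

seeded_kmeans <- function(feats, k, seed, nstart = 10L) {
  if (k == 1L) return(rep(1L, nrow(feats)))
  set.seed(seed)
  km <- stats::kmeans(feats, centers = k, nstart = nstart, iter.max = 100L)
  as.integer(km$cluster)
}

#' Gap statistic for choosing k
#'
#' Compares the log within-cluster dispersion against its expectation under
#' `B` uniform reference draws over the feature bounding box, and selects the
#' smallest `k` whose gap is within one reference standard error of the next
#' one: `gap(k) >= gap(k+1) - s_{k+1}`. Constant (degenerate) features
#' return 1.
#'
#' @param feats Feature matrix (rows are objects).
#' @param k_max Largest candidate `k` (candidates are `1..k_max`).
#' @param B Number of reference draws.
#' @param seed Integer seed.
#' @return Selected `k`.
#' @export
gap_statistic <- function(feats, k_max = 8L, B = 25L, seed = 1L) {
  feats <- as.matrix(feats)
  if (max(apply(feats, 2L, function(col) diff(range(col)))) == 0) return(1L)
  k_max <- min(k_max, nrow(feats) - 1L)
  if (k_max < 2L) return(1L)
  set.seed(seed)
  gp <- cluster::clusGap(feats,
                         FUNcluster = function(z, k) {
                           list(cluster = seeded_kmeans(as.matrix(z), k,
                                                        seed = seed, nstart = 10L))
                         },
                         K.max = k_max, B = B, spaceH0 = "original",
                         verbose = FALSE)
  tab <- gp$Tab
  as.integer(cluster::maxSE(tab[, "gap"], tab[, "SE.sim"],
                            method = "Tibs2001SEmax"))
}

#' CP decomposition + per-mode k-means baseline
#'
#' Performs a rank-`R` CP decomposition and clusters the rows of each factor
#' matrix independently with seeded multi-start k-means; `k = "auto"` chooses
#' each mode's k by the gap statistic.
#'
#' @param x Dense numeric array.
#' @param R CP rank, or `"auto"` to pick the best-fitting rank among
#'   `ranks`.
#' @param k Per-mode cluster counts, a single count recycled across modes,
#'   or `"auto"`.
#' @param ranks Candidate ranks for `R = "auto"`.
#' @param k_max Candidate range for the gap statistic.
#' @param seed Integer seed.
#' @param truth Optional list of per-mode true labels; adds per-mode ARI.
#' @return A `"baseline_result"`: `method`, `labels`, `k`, `R`, `ari`.
#' @export
cpd_kmeans <- function(x, R = "auto", k = "auto", ranks = 2:5, k_max = 8L,
                       seed = 1L, truth = NULL) {
  D <- length(dim(x))
  if (identical(R, "auto")) {
    fits <- lapply(ranks, function(r) cp_als(x, r, seed = seed))
    R <- ranks[which.max(vapply(fits, `[[`, 0, "fit"))]
    cp <- fits[[which.max(vapply(fits, `[[`, 0, "fit"))]]
  } else {
    cp <- cp_als(x, R, seed = seed)
  }
  ks <- if (identical(k, "auto")) rep(list("auto"), D) else per_mode(k, D)
  labels <- vector("list", D)
  kd <- integer(D)
  for (d in seq_len(D)) {
    feats <- cp$factors[[d]]
    kd[d] <- if (identical(ks[[d]], "auto")) {
      gap_statistic(feats, k_max = k_max, seed = seed + d)
    } else as.integer(ks[[d]])
    labels[[d]] <- seeded_kmeans(feats, kd[d], seed = seed + 100L + d)
  }
  baseline_result("cpd_kmeans", labels, kd, truth, R = R)
}

#' Per-mode k-means on matricizations (CoTeC-style baseline)
#'
#' Applies k-means directly to the rows of each mode-`d` matricization,
#' independently per mode, ignoring the multiway structure.
#'
#' @inheritParams cpd_kmeans
#' @return A `"baseline_result"`.
#' @export
cotec_kmeans <- function(x, k = "auto", k_max = 8L, seed = 1L, truth = NULL) {
  D <- length(dim(x))
  ks <- if (identical(k, "auto")) rep(list("auto"), D) else per_mode(k, D)
  labels <- vector("list", D)
  kd <- integer(D)
  for (d in seq_len(D)) {
    feats <- tensor_unfold(x, d)
    kd[d] <- if (identical(ks[[d]], "auto")) {
      gap_statistic(feats, k_max = k_max, seed = seed + d)
    } else as.integer(ks[[d]])
    labels[[d]] <- seeded_kmeans(feats, kd[d], seed = seed + 100L + d)
  }
  baseline_result("cotec_kmeans", labels, kd, truth)
}

baseline_result <- function(method, labels, k, truth = NULL, R = NULL) {
  ari <- if (!is.null(truth)) {
    vapply(seq_along(labels),
           function(d) adjusted_rand_index(labels[[d]], truth[[d]]), 0)
  } else NULL
  structure(list(method = method, labels = labels, k = k, R = R, ari = ari),
            class = "baseline_result")
}

#' @export
print.baseline_result <- function(x, ...) {
  cat("<baseline_result>", x$method, "| per-mode k:",
      paste(x$k, collapse = ", "))
  if (!is.null(x$ari)) cat(" | per-mode ARI:", paste(round(x$ari, 3), collapse = ", "))
  cat("\n")
  invisible(x)
}
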