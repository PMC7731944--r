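#' Checkerbox simulation specification
#'
#' Describes a block-constant mean tensor plus independent Gaussian noise:
#' each mode is partitioned into `clusters[d]` groups (balanced by default,
#' or explicit size lists for imbalance), co-cluster means are either given
#' explicitly or drawn once as iid Normal(0, `delta^2`), and the noise
#' standard deviation may be a single scalar (homoskedastic) or a per-cell
#' array (heteroskedastic).
#'
#' @param dims Tensor shape `(n_1, ..., n_D)`.
#' @param clusters Per-mode cluster counts `(k_1, ..., k_D)`.
#' @param sizes Optional list of per-mode cluster-size vectors (each summing
#'   to `n_d`); default balanced (remainders to the earlier clusters).
#' @param means Optional explicit means array of shape `clusters`.
#' @param delta Spread of the iid Normal draw for means when `means` is
#'   `NULL`.
#' @param sigma Noise standard deviation: scalar or array of shape
#'   `clusters`.
#' @param shuffle Shuffle the mode indices by a seeded permutation (the
#'   estimator is permutation-equivariant, so contiguous blocks are never
#'   required).
#' @param seed Integer seed; fixed seed gives bit-reproducible output.
#' @return A list of class `"checkerbox_spec"`.
#' @export
checkerbox_spec <- function(dims, clusters, sizes = NULL, means = NULL,
                            delta = 3, sigma = 1, shuffle = FALSE, seed = 1L) {
  dims <- as.integer(dims)
  clusters <- as.integer(clusters)
  D <- length(dims)
  if (length(clusters) != D) stop("clusters must have one entry per mode")
  if (any(clusters < 1L) || any(clusters > dims)) stop("invalid cluster counts")
  if (is.null(sizes)) {
    sizes <- lapply(seq_len(D), function(d) {
      base <- dims[d] %/% clusters[d]
      s <- rep(base, clusters[d])
      extra <- dims[d] - sum(s)
      if (extra > 0L) s[seq_len(extra)] <- s[seq_len(extra)] + 1L
      s
    })
  }
  for (d in seq_len(D)) {
    if (sum(sizes[[d]]) != dims[d] || any(sizes[[d]] < 1L)) {
      stop("cluster sizes must be positive and sum to n_d (mode ", d, ")")
    }
  }
  if (!is.null(means) && !identical(as.integer(dim(means)), clusters)) {
    stop("means array must have shape `clusters`")
  }
  if (length(sigma) > 1L && !identical(as.integer(dim(sigma)), clusters)) {
    stop("sigma must be a scalar or an array of shape `clusters`")
  }
  if (any(sigma < 0)) stop("sigma must be nonnegative")
  structure(list(dims = dims, clusters = clusters, sizes = sizes,
                 means = means, delta = delta, sigma = sigma,
                 shuffle = isTRUE(shuffle), seed = as.integer(seed)),
            class = "checkerbox_spec")
}

labels_from_sizes <- function(sizes) {
  rep(seq_along(sizes), times = sizes)
}

#' Simulate a checkerbox tensor
#'
#' Draws \eqn{X = U^* + E} where \eqn{U^*} expands a co-cluster means tensor
#' through the per-mode memberships and the noise entries are independent
#' Normal with the per-cell standard deviation. Returns the observation, the
#' noiseless mean tensor, the per-mode true labels, and the means array.
#'
#' @param spec A [checkerbox_spec()].
#' @return List with `x`, `u_star`, `labels`, `means`, `spec`.
#' @export
simulate_checkerbox <- function(spec) {
  stopifnot(inherits(spec, "checkerbox_spec"))
  set.seed(spec$seed)
  D <- length(spec$dims)
  means <- spec$means
  if (is.null(means)) {
    means <- array(stats::rnorm(prod(spec$clusters), sd = spec$delta),
                   dim = spec$clusters)
  }
  labels <- lapply(spec$sizes, labels_from_sizes)
  if (spec$shuffle) {
    labels <- lapply(seq_len(D), function(d) {
      labels[[d]][sample.int(spec$dims[d])]
    })
    # relabel by first occurrence so labels stay canonical
    labels <- lapply(labels, function(l) as.integer(factor(l, levels = unique(l))))
  }
  u_star <- expand_means(means, labels)
  sig_cell <- if (length(spec$sigma) == 1L) {
    array(spec$sigma, dim = spec$clusters)
  } else {
    spec$sigma
  }
  sig_full <- expand_means(sig_cell, labels)
  e <- array(stats::rnorm(prod(spec$dims)), dim = spec$dims) * sig_full
  list(x = u_star + e, u_star = u_star, labels = labels, means = means,
       spec = spec)
}

halfmoons_points <- function(n_per = 40L, noise = 0.06, seed = 1L) {
  set.seed(seed)
  t1 <- stats::runif(n_per, 0, pi)
  t2 <- stats::runif(n_per, 0, pi)
  upper <- cbind(cos(t1), sin(t1))
  lower <- cbind(1 - cos(t2), 0.5 - sin(t2))
  pts <- rbind(upper, lower)
  pts + matrix(stats::rnorm(2L * 2L * n_per, sd = noise), ncol = 2L)
}

bullseye_points <- function(n_per = 40L, r_inner = 1, r_outer = 3,
                            noise = 0.1, seed = 1L) {
  set.seed(seed)
  th1 <- stats::runif(n_per, 0, 2 * pi)
  th2 <- stats::runif(n_per, 0, 2 * pi)
  r1 <- r_inner + stats::rnorm(n_per, sd = noise)
  r2 <- r_outer + stats::rnorm(n_per, sd = noise)
  rbind(cbind(r1 * cos(th1), r1 * sin(th1)),
        cbind(r2 * cos(th2), r2 * sin(th2)))
}

#' CP-shape simulation specification
#'
#' Rank-2 symmetric CP model: a factor matrix `A` (two columns) whose rows
#' are 2-D points on a named non-convex shape, the mean tensor
#' \eqn{\mathcal{U}^* = \sum_{i=1,2} a_i \circ a_i \circ a_i} built from its
#' columns, plus iid Gaussian noise. The first `n_per` rows of `A` form class
#' one, the remaining `n_per` rows class two.
#'
#' @param shape `"halfmoons"` (two interleaved crescents) or `"bullseye"`
#'   (two concentric annuli).
#' @param n_per Rows per class (default 40, so `A` is 80 x 2).
#' @param sigma Noise standard deviation added to the mean tensor.
#' @param point_noise Jitter of the 2-D shape points.
#' @param seed Integer seed.
#' @return A list of class `"cp_shape_spec"`.
#' @export
cp_shape_spec <- function(shape = c("halfmoons", "bullseye"), n_per = 40L,
                          sigma = 0.1, point_noise = NULL, seed = 1L) {
  shape <- match.arg(shape)
  if (is.null(point_noise)) point_noise <- if (shape == "halfmoons") 0.06 else 0.1
  structure(list(shape = shape, n_per = as.integer(n_per), sigma = sigma,
                 point_noise = point_noise, seed = as.integer(seed)),
            class = "cp_shape_spec")
}

#' Simulate a rank-2 symmetric CP tensor
#'
#' @param spec A [cp_shape_spec()].
#' @return List with `x` (cubic tensor of side `2 * n_per`), `u_star`,
#'   `labels` (two-class row labels, shared by all modes by symmetry),
#'   `factors` (the matrix `A`), `spec`.
#' @export
simulate_cp_shapes <- function(spec) {
  stopifnot(inherits(spec, "cp_shape_spec"))
  A <- switch(spec$shape,
              halfmoons = halfmoons_points(spec$n_per, spec$point_noise, spec$seed),
              bullseye = bullseye_points(spec$n_per, noise = spec$point_noise,
                                         seed = spec$seed))
  nr <- nrow(A)
  u_star <- array(0, dim = rep(nr, 3L))
  for (i in 1:2) {
    a <- A[, i]
    u_star <- u_star + outer(outer(a, a), a)
  }
  set.seed(spec$seed + 1L)
  x <- u_star + array(stats::rnorm(nr^3, sd = spec$sigma), dim = rep(nr, 3L))
  labels <- rep(1:2, each = spec$n_per)
  list(x = x, u_star = u_star, labels = labels, factors = A, spec = spec)
}
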