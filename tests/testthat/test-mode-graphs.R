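test_that("mode distances match a brute-force element loop", {
  set.seed(21)
  x <- rand_tensor(c(3, 4, 2))
  for (d in 1:3) {
    dm <- mode_distances(x, d)
    expect_equal(dm, t(dm))
    expect_equal(diag(dm), rep(0, dim(x)[d]))
    u <- tensor_unfold(x, d)
    for (i in seq_len(nrow(u))) for (j in seq_len(nrow(u))) {
      ref <- sqrt(sum((u[i, ] - u[j, ])^2))
      expect_equal(dm[i, j], ref, tolerance = 1e-12)
    }
  }
  # identical subarrays have distance zero
  x2 <- x
  x2[2, , ] <- x2[1, , ]
  expect_equal(mode_distances(x2, 1)[1, 2], 0)
})

test_that("knn mask obeys the union rule and matches row sorting", {
  set.seed(22)
  n <- 7
  dm <- as.matrix(stats::dist(matrix(rnorm(n * 2), n, 2)))
  for (k in 1:(n - 1)) {
    mask <- knn_mask(dm, k)
    expect_true(isSymmetric(mask))
    expect_false(any(diag(mask)))
    # brute force: neighbour-of relation by sorting each row
    direct <- matrix(FALSE, n, n)
    for (i in seq_len(n)) {
      nb <- order(dm[i, -i])[seq_len(k)]
      direct[i, (seq_len(n)[-i])[nb]] <- TRUE
    }
    expect_equal(mask, direct | t(direct))
  }
  expect_true(all(knn_mask(dm, n - 1)[upper.tri(dm)]))
  expect_error(knn_mask(dm, n), "k must be")
})

test_that("smallest connected k agrees with a linear scan", {
  # two points: k = 1
  expect_equal(smallest_connected_k(matrix(c(0, 1, 1, 0), 2, 2)), 1L)
  # equally spaced points on a line chain together at k = 1
  pts <- matrix(seq_len(6), ncol = 1)
  expect_equal(smallest_connected_k(as.matrix(stats::dist(pts))), 1L)
  set.seed(23)
  for (rep in 1:5) {
    n <- sample(4:9, 1)
    dm <- as.matrix(stats::dist(matrix(rnorm(n * 3), n, 3)))
    k_star <- smallest_connected_k(dm)
    connected_at <- function(k) {
      max(connected_components(n, mask_edges(knn_mask(dm, k)))) == 1
    }
    expect_true(connected_at(k_star))
    if (k_star > 1) expect_false(connected_at(k_star - 1))
  }
})

test_that("median scale follows the declared conventions", {
  dm <- matrix(2, 4, 4); diag(dm) <- 0
  mask <- matrix(TRUE, 4, 4); diag(mask) <- FALSE
  expect_equal(median_scale(dm, mask), 1 / 4)            # 1/median^2
  expect_equal(median_scale(dm, mask, "inverse"), 1 / 2) # 1/median
  set.seed(24)
  dvals <- runif(25, 0.5, 3)
  # place 25 random values on a masked band and check against a sort-based
  # median oracle (odd count, so the median is an order statistic)
  nn <- 26
  dm2 <- matrix(0, nn, nn)
  mask2 <- matrix(FALSE, nn, nn)
  for (i in 1:25) {
    dm2[i, i + 1] <- dm2[i + 1, i] <- dvals[i]
    mask2[i, i + 1] <- mask2[i + 1, i] <- TRUE
  }
  m_oracle <- sort(dvals)[13]
  expect_equal(median_scale(dm2, mask2), 1 / m_oracle^2)
  dm0 <- matrix(0, 3, 3)
  mask0 <- matrix(TRUE, 3, 3); diag(mask0) <- FALSE
  expect_error(median_scale(dm0, mask0), "degenerate")
})

test_that("gaussian pre-weights match scalar evaluation and the uniform limit", {
  set.seed(25)
  dm <- as.matrix(stats::dist(matrix(rnorm(10), 5, 2)))
  mask <- knn_mask(dm, 2)
  w0 <- gaussian_preweights(dm, mask, 0)
  expect_true(all(w0[mask] == 1))   # tau = 0 gives uniform weights
  tau <- 0.7
  w <- gaussian_preweights(dm, mask, tau)
  expect_true(all(w >= 0 & w <= 1))
  for (i in 1:5) for (j in 1:5) {
    if (mask[i, j]) expect_equal(w[i, j], exp(-tau * dm[i, j]^2))
    else expect_equal(w[i, j], 0)
  }
  dm2 <- dm; dm2[1, 2] <- dm2[2, 1] <- 0
  expect_equal(gaussian_preweights(dm2, mask | TRUE & !diag(5), tau)[1, 2], 1)
})

test_that("weight normalization hits the n_d/n target and is scale invariant", {
  set.seed(26)
  w <- runif(11)
  out <- normalize_mode_weights(w, nd = 6, n = 120)
  expect_equal(sum(out), 6 / 120, tolerance = 1e-12)
  expect_equal(normalize_mode_weights(7 * w, 6, 120), out, tolerance = 1e-14)
  eq <- normalize_mode_weights(rep(0.3, 10), nd = 5, n = 60)
  expect_equal(eq, rep((5 / 60) / 10, 10))
  expect_error(normalize_mode_weights(rep(0, 3), 5, 60), "zero")
})

test_that("tucker denoising recovers exact low rank and is monotone in rank", {
  set.seed(27)
  x <- rand_tensor(c(4, 5, 3))
  expect_equal(tucker_denoise(x, c(4, 5, 3)), x, tolerance = 1e-10)

  # exactly rank-(2,2,2) tensor
  core <- rand_tensor(c(2, 2, 2))
  U <- lapply(c(6, 6, 6), function(nd) qr.Q(qr(matrix(rnorm(nd * 2), nd, 2))))
  low <- ttm(ttm(ttm(core, U[[1]], 1), U[[2]], 2), U[[3]], 3)
  rec <- tucker_denoise(low, c(2, 2, 2))
  expect_lt(tensor_norm(rec - low) / tensor_norm(low), 1e-8)

  y <- rand_tensor(c(6, 6, 6))
  errs <- sapply(2:6, function(r) tensor_norm(y - tucker_denoise(y, c(r, 3, 3))))
  expect_true(all(diff(errs) <= 1e-8))
  expect_error(tucker_denoise(y, c(0, 3, 3)), "ranks")
})

test_that("build_weights composes its stages and honours the uniform scheme", {
  set.seed(28)
  x <- rand_tensor(c(4, 4, 4))
  gu <- coco_weights(x, weight_config(scheme = "theory_uniform"))
  for (d in 1:3) {
    expect_equal(nrow(gu$modes[[d]]$edges), 6)  # complete graph on 4 nodes
    expect_equal(gu$modes[[d]]$weights, rep(1 / 4, 6))
  }

  ga <- coco_weights(x, weight_config(tucker_ranks = "off"))
  n <- prod(dim(x))
  for (d in 1:3) {
    expect_equal(sum(ga$modes[[d]]$weights), dim(x)[d] / n, tolerance = 1e-12)
    labels <- connected_components(dim(x)[d], ga$modes[[d]]$edges)
    expect_equal(max(labels), 1L)  # auto-k graphs are connected
  }

  # end-to-end equals manual stage-by-stage composition (no denoising)
  for (d in 1:3) {
    dm <- mode_distances(x, d)
    k <- smallest_connected_k(dm)
    mask <- knn_mask(dm, k)
    tau <- median_scale(dm, mask)
    pw <- gaussian_preweights(dm, mask, tau)
    edges <- mask_edges(mask)
    w <- normalize_mode_weights(pw[edges], dim(x)[d], n)
    expect_equal(ga$modes[[d]]$edges, edges)
    expect_equal(ga$modes[[d]]$weights, w, tolerance = 1e-12)
    expect_equal(ga$modes[[d]]$k, k)
    expect_equal(ga$modes[[d]]$tau, tau)
  }
})

test_that("weight construction is equivariant to permuting mode indices", {
  set.seed(29)
  x <- rand_tensor(c(5, 4, 3))
  perm <- sample(5)
  xp <- x[perm, , ]
  g <- coco_weights(x, weight_config(tucker_ranks = "off"))
  gp <- coco_weights(xp, weight_config(tucker_ranks = "off"))
  # edge sets correspond under the permutation (as unordered pairs)
  canon <- function(e) {
    s <- t(apply(e, 1, sort))
    s[order(s[, 1], s[, 2]), , drop = FALSE]
  }
  mapped <- canon(matrix(match(g$modes[[1]]$edges, perm), ncol = 2))
  expect_equal(canon(gp$modes[[1]]$edges), mapped)
  expect_equal(sort(gp$modes[[1]]$weights), sort(g$modes[[1]]$weights),
               tolerance = 1e-10)
  # untouched modes are unchanged
  for (d in 2:3) {
    expect_equal(gp$modes[[d]]$edges, g$modes[[d]]$edges)
    expect_equal(gp$modes[[d]]$weights, g$modes[[d]]$weights, tolerance = 1e-10)
  }
})

test_that("noiseless checkerbox gives within-cluster pre-weight one", {
  sim <- simulate_checkerbox(checkerbox_spec(dims = c(8, 8, 8),
                                             clusters = c(2, 2, 2),
                                             delta = 3, sigma = 0, seed = 31))
  for (d in 1:3) {
    dm <- mode_distances(sim$x, d)
    mask <- knn_mask(dm, 3)  # within-cluster neighbour count is 3
    pw <- gaussian_preweights(dm, mask, 1)
    same <- outer(sim$labels[[d]], sim$labels[[d]], `==`)
    expect_true(all(pw[mask & same] == 1))  # distance 0 within a cluster
    expect_true(all(mask[same & upper.tri(same)]))
  }
})
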