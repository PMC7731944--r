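test_that("connected components reproduce the worked similarity graph", {
  # seven nodes, fused edges {(1,2),(2,3),(4,5),(4,6),(6,7)} give components
  # {1,2,3} and {4,5,6,7}
  edges <- rbind(c(1L, 2L), c(2L, 3L), c(4L, 5L), c(4L, 6L), c(6L, 7L))
  labels <- connected_components(7, edges)
  expect_equal(labels, c(1L, 1L, 1L, 2L, 2L, 2L, 2L))
  # invariant to edge listing order
  for (rep in 1:5) {
    perm <- sample(nrow(edges))
    expect_equal(connected_components(7, edges[perm, , drop = FALSE]), labels)
  }
  expect_equal(connected_components(4, matrix(integer(0), 0, 2)), 1:4)
  expect_error(connected_components(3, matrix(c(1L, 9L), 1, 2)), "out of range")
})

test_that("fusion detection honours the gamma limits", {
  set.seed(61)
  dims <- c(3, 4, 3)
  x <- rand_tensor(dims)
  graph <- random_graph(dims)
  fit0 <- coco_fit(x, graph, 0)
  fused0 <- fused_edges(fit0, graph, x)
  expect_false(any(unlist(fused0)))  # generic data, gamma = 0: nothing fuses
  cl0 <- coco_clusters(fit0, graph, x)
  expect_equal(unname(cl0$k), dims)  # all singletons

  gm <- gamma_max(x, graph)
  fitm <- coco_fit(x, graph, gm)
  expect_true(all(unlist(fused_edges(fitm, graph, x))))
  expect_equal(coco_clusters(fitm, graph, x)$k, c(1L, 1L, 1L))
})

test_that("dual-interior and norm-threshold rules agree near convergence", {
  set.seed(62)
  agree <- 0; total <- 0
  for (rep in 1:6) {
    dims <- sample(3:4, 3, replace = TRUE)
    x <- rand_tensor(dims)
    graph <- random_graph(dims)
    gamma <- stats::runif(1, 0.3, 2)
    fit <- coco_fit(x, graph, gamma, solver_config(tol = 1e-10))
    xnorm <- tensor_norm(x)
    for (d in seq_along(graph$modes)) {
      w <- graph$modes[[d]]$weights
      interior <- fit$dual_norms[[d]] <= (1 - 1e-3) * gamma * w
      tiny <- fit$diff_norms[[d]] <= 1e-6 * xnorm
      agree <- agree + sum(interior == tiny)
      total <- total + length(w)
    }
  }
  expect_gte(agree / total, 0.99)
})

test_that("co-cluster means match a brute-force nested-loop average", {
  set.seed(63)
  x <- rand_tensor(c(4, 4, 4))
  labels <- list(sample(1:2, 4, TRUE), sample(1:3, 4, TRUE), sample(1:2, 4, TRUE))
  # ensure every label value occurs
  labels <- lapply(labels, function(l) { l[1] <- 1L; l[2] <- max(l); l })
  labels <- lapply(labels, function(l) as.integer(factor(l, levels = sort(unique(l)))))
  means <- co_cluster_means(x, labels)
  for (r1 in seq_len(max(labels[[1]]))) {
    for (r2 in seq_len(max(labels[[2]]))) {
      for (r3 in seq_len(max(labels[[3]]))) {
        cell <- x[labels[[1]] == r1, labels[[2]] == r2, labels[[3]] == r3,
                  drop = FALSE]
        expect_equal(means[r1, r2, r3], mean(cell), tolerance = 1e-12)
      }
    }
  }
  # degenerate partitions
  singletons <- lapply(dim(x), seq_len)
  expect_equal(co_cluster_means(x, singletons), x)
  ones <- lapply(dim(x), function(nd) rep(1L, nd))
  expect_equal(as.vector(co_cluster_means(x, ones)), mean(x))
})

test_that("expanding means and re-extracting reproduces the same partitions", {
  sim <- simulate_checkerbox(checkerbox_spec(dims = c(9, 9, 9),
                                             clusters = c(3, 2, 2),
                                             delta = 4, sigma = 0.3, seed = 64))
  res <- suppressWarnings(coco(sim$x, grid_size = 12))
  cl <- res$clustering
  rebuilt <- expand_means(cl$means, cl$labels)
  # rebuilt tensor is constant on each co-cluster cell, and re-clustering the
  # noiseless rebuild gives the same partitions and df
  for (d in 1:3) {
    u <- tensor_unfold(rebuilt, d)
    for (r in seq_len(cl$k[d])) {
      rows <- which(cl$labels[[d]] == r)
      if (length(rows) > 1) {
        expect_equal(max(apply(u[rows, , drop = FALSE], 2, function(cc) diff(range(cc)))), 0,
                     tolerance = 1e-10)
      }
    }
    relab <- connected_components(
      dim(rebuilt)[d],
      mask_edges(outer(cl$labels[[d]], cl$labels[[d]], `==`))
    )
    expect_equal(adjusted_rand_index(relab, cl$labels[[d]]), 1)
  }
  expect_equal(count_co_clusters(cl), prod(cl$k))
})

test_that("adjusted Rand index matches the contingency-table formula", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  expect_equal(adjusted_rand_index(1:6, rep(1, 6)), 0)
  set.seed(65)
  for (rep in 1:20) {
    a <- sample(1:4, 12, TRUE)
    b <- sample(1:3, 12, TRUE)
    expect_equal(adjusted_rand_index(a, b), ari_oracle(a, b), tolerance = 1e-12)
  }
  expect_error(adjusted_rand_index(1:3, 1:4), "equal length")
})

test_that("partition extraction does not depend on input ordering", {
  sim <- simulate_checkerbox(checkerbox_spec(dims = c(10, 10, 10),
                                             clusters = c(2, 2, 2),
                                             delta = 3, sigma = 0.4,
                                             shuffle = TRUE, seed = 66))
  res <- suppressWarnings(coco(sim$x, grid_size = 10))
  for (d in 1:3) {
    expect_equal(adjusted_rand_index(res$clustering$labels[[d]],
                                     sim$labels[[d]]), 1)
  }
})
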