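test_that("ball projection is exact", {
  expect_equal(project_to_ball(c(0.3, 0.1), 1), c(0.3, 0.1))
  expect_equal(project_to_ball(c(3, 4), 1), c(0.6, 0.8))
  expect_equal(project_to_ball(c(3, 4), 0), c(0, 0))
  expect_error(project_to_ball(c(1, 0), -1), "nonnegative")
})

test_that("primal and dual objectives match naive evaluation and weak duality", {
  set.seed(41)
  dims <- c(3, 3, 2)
  x <- rand_tensor(dims)
  graph <- random_graph(dims)
  gamma <- 0.4
  u <- rand_tensor(dims)
  expect_equal(primal_objective(u, x, graph, gamma),
               naive_primal(u, x, graph, gamma), tolerance = 1e-12)
  expect_equal(primal_objective(x, x, graph, 0), 0)
  # fit term vanishes at u = x
  expect_equal(primal_objective(x, x, graph, gamma),
               naive_primal(x, x, graph, gamma))

  lam0 <- lapply(seq_along(graph$modes), function(d) {
    matrix(0, prod(dims) / dims[d], nrow(graph$modes[[d]]$edges))
  })
  expect_equal(dual_objective(lam0, x, graph, gamma), 0)
  # random feasible lambdas never exceed the primal value
  for (rep in 1:10) {
    lam <- lapply(seq_along(graph$modes), function(d) {
      m <- matrix(rnorm(prod(dims) / dims[d] * nrow(graph$modes[[d]]$edges)),
                  ncol = nrow(graph$modes[[d]]$edges))
      radii <- gamma * graph$modes[[d]]$weights
      for (l in seq_len(ncol(m))) m[, l] <- project_to_ball(m[, l], radii[l])
      m
    })
    g <- dual_objective(lam, x, graph, gamma)
    expect_lte(g, primal_objective(u, x, graph, gamma) + 1e-10)
  }
  # infeasible lambda reports -Inf
  lam_bad <- lam0
  lam_bad[[1]][, 1] <- 10 * gamma * graph$modes[[1]]$weights[1]
  expect_identical(dual_objective(lam_bad, x, graph, gamma), -Inf)
})

test_that("auto step size matches the dense eigen bound", {
  # single mode, single edge: ||Delta||^2 = 2, eta = 1/2
  g1 <- structure(list(dims = c(2L, 2L),
                       modes = list(list(edges = matrix(c(1L, 2L), 1, 2),
                                         weights = 1, k = 1L, tau = 0),
                                    list(edges = matrix(integer(0), 0, 2),
                                         weights = numeric(0), k = 1L, tau = 0))),
                  class = "coco_graph")
  expect_equal(auto_step_size(g1), 0.5, tolerance = 1e-10)

  set.seed(42)
  dims <- c(3, 3, 2)
  graph <- random_graph(dims)
  eta <- auto_step_size(graph)
  expect_gt(eta, 0)
  # dense AA^T largest eigenvalue
  mats <- dense_graph_matrices(graph)
  A <- do.call(rbind, unlist(mats, recursive = FALSE))
  L <- max(eigen(A %*% t(A), symmetric = TRUE, only.values = TRUE)$values)
  expect_equal(1 / eta, L, tolerance = 0.01)
})

test_that("solver reproduces analytic limits", {
  set.seed(43)
  dims <- c(3, 4, 2)
  x <- rand_tensor(dims)
  graph <- random_graph(dims)
  fit0 <- coco_fit(x, graph, 0)
  expect_identical(fit0$u_hat, x)  # gamma = 0 returns the data exactly

  gm <- gamma_max(x, graph)
  fitm <- coco_fit(x, graph, gm, solver_config(tol = 1e-9))
  gbar <- array(mean(x), dim = dims)
  expect_lt(tensor_norm(fitm$u_hat - gbar) / tensor_norm(gbar), 1e-6)
  cl <- coco_clusters(fitm, graph, x)
  expect_equal(cl$k, c(1L, 1L, 1L))
})

test_that("solver matches the independent ADMM primal oracle", {
  set.seed(44)
  for (rep in 1:4) {
    dims <- sample(2:4, 3, replace = TRUE)
    x <- rand_tensor(dims)
    graph <- random_graph(dims)
    for (gamma in c(0.01, 0.1, 1)) {
      fit <- coco_fit(x, graph, gamma, solver_config(tol = 1e-10))
      expect_true(fit$converged)
      u_oracle <- admm_primal_oracle(x, graph, gamma, iters = 6000L)
      rel <- tensor_norm(fit$u_hat - u_oracle) / max(tensor_norm(u_oracle), 1e-12)
      expect_lt(rel, 1e-4)
      # duality gap certificate
      expect_gte(fit$gap, 0)
      expect_lt(fit$gap, 1e-5)
    }
  }
})

test_that("dual iterates stay feasible and unaccelerated ascent is monotone", {
  set.seed(45)
  dims <- c(3, 3, 2)
  x <- rand_tensor(dims)
  graph <- random_graph(dims)
  gamma <- 0.5
  # run plain projected gradient step by step via max_iter and check the
  # dual objective never decreases
  vals <- sapply(seq(5, 60, by = 5), function(mi) {
    f <- coco_fit(x, graph, gamma,
                  solver_config(accelerate = FALSE, max_iter = mi,
                                tol = 1e-14, check_every = mi))
    dual_objective(f$lambda, x, graph, gamma)
  })
  expect_true(all(is.finite(vals)))
  expect_true(all(diff(vals) >= -1e-9))
  # feasibility of the final iterate
  f <- coco_fit(x, graph, gamma, solver_config(max_iter = 200))
  for (d in seq_along(f$lambda)) {
    expect_true(all(f$dual_norms[[d]] <= gamma * graph$modes[[d]]$weights + 1e-9))
  }
})

test_that("estimator is nonexpansive in the data", {
  set.seed(46)
  dims <- c(3, 3, 2)
  graph <- random_graph(dims)
  gamma <- 0.5
  for (rep in 1:20) {
    x <- rand_tensor(dims)
    xt <- x + 0.3 * rand_tensor(dims)
    u1 <- coco_fit(x, graph, gamma)$u_hat
    u2 <- coco_fit(xt, graph, gamma)$u_hat
    expect_lte(tensor_norm(u1 - u2), tensor_norm(x - xt) + 1e-6)
  }
})

test_that("estimator is equivariant to mode permutations", {
  set.seed(47)
  dims <- c(4, 3, 2)
  x <- rand_tensor(dims)
  graph <- random_graph(dims)
  gamma <- 0.3
  perm <- sample(4)
  xp <- x[perm, , ]
  # relabel the mode-1 graph accordingly: node v in x becomes position
  # match(v, perm) in xp
  gp <- graph
  e <- graph$modes[[1]]$edges
  ep <- matrix(match(e, perm), ncol = 2)
  swap <- ep[, 1] > ep[, 2]
  ep[swap, ] <- ep[swap, 2:1]
  ord <- order(ep[, 1], ep[, 2])
  gp$modes[[1]]$edges <- ep[ord, , drop = FALSE]
  gp$modes[[1]]$weights <- graph$modes[[1]]$weights[ord]
  u <- coco_fit(x, graph, gamma, solver_config(tol = 1e-10))$u_hat
  up <- coco_fit(xp, gp, gamma, solver_config(tol = 1e-10))$u_hat
  expect_equal(up, u[perm, , ], tolerance = 1e-5)
  # identical partitions up to relabeling
  clu <- coco_clusters(coco_fit(x, graph, gamma), graph, x)
  clup <- coco_clusters(coco_fit(xp, gp, gamma), gp, xp)
  expect_equal(adjusted_rand_index(clup$labels[[1]], clu$labels[[1]][perm]), 1)
})

test_that("estimator is continuous in gamma", {
  set.seed(48)
  dims <- c(3, 3, 2)
  x <- rand_tensor(dims)
  graph <- random_graph(dims)
  gamma <- 0.4
  u0 <- coco_fit(x, graph, gamma, solver_config(tol = 1e-10))$u_hat
  dev <- sapply(c(0.1, 0.01, 0.001), function(delta) {
    tensor_norm(coco_fit(x, graph, gamma + delta,
                         solver_config(tol = 1e-10))$u_hat - u0)
  })
  expect_true(all(diff(dev) < 0))      # shrinking perturbation shrinks the change
  expect_lt(dev[3], 1e-2)
})

test_that("warm-started paths match cold starts and RSS is monotone", {
  set.seed(49)
  dims <- c(3, 4, 3)
  x <- rand_tensor(dims)
  graph <- random_graph(dims)
  gammas <- exp(seq(log(0.01), log(5), length.out = 8))
  warm <- coco_path_fits(x, graph, gammas, solver_config(tol = 1e-12))
  cold <- coco_path_fits(x, graph, gammas, solver_config(tol = 1e-12),
                         warm_start = FALSE)
  for (t in seq_along(gammas)) {
    rel <- tensor_norm(warm[[t]]$u_hat - cold[[t]]$u_hat) /
      max(tensor_norm(cold[[t]]$u_hat), 1e-12)
    expect_lt(rel, 1e-5)
    expect_lte(warm[[t]]$gap, 1e-11)
  }
  rss <- sapply(warm, function(f) sum((as.vector(x) - as.vector(f$u_hat))^2))
  expect_true(all(diff(rss) >= -1e-8))

  single <- coco_path_fits(x, graph, 0)
  expect_identical(single[[1]]$u_hat, x)
})
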