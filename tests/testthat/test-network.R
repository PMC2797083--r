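test_that("all-to-all graphs are symmetric, balanced, with row sums (n-1)k", {
  g <- build_all_to_all(2, 1)
  expect_equal(g$weights, matrix(c(0, 1, 1, 0), 2))
  expect_true(g$balanced)
  for (n in c(3, 7, 12)) {
    g <- build_all_to_all(n, 2.5)
    expect_true(g$symmetric)
    expect_true(is_balanced(g, tol = 0))
    expect_equal(rowSums(g$weights), rep((n - 1) * 2.5, n))
  }
  expect_error(build_all_to_all(1, 1), class = "oscnet_invalid_input")
})

test_that("probabilistic graphs: edge cases, reproducibility, edge counts", {
  expect_equal(suppressWarnings(build_probabilistic(6, 0, 1, seed = 1))$weights,
               matrix(0, 6, 6))
  expect_equal(build_probabilistic(6, 1, 2, seed = 1)$weights,
               build_all_to_all(6, 2)$weights)
  g1 <- suppressWarnings(build_probabilistic(30, 0.3, 1, seed = 42))
  g2 <- suppressWarnings(build_probabilistic(30, 0.3, 1, seed = 42))
  expect_identical(g1$weights, g2$weights)
  expect_true(g1$symmetric)
  expect_true(is_balanced(g1, tol = 0))
  # binomial oracle: mean edge count over 100 seeds within 3 standard
  # errors of p * n(n-1)/2
  n <- 40; p <- 0.3
  counts <- vapply(1:100, function(s) {
    sum(suppressWarnings(build_probabilistic(n, p, 1, seed = s))$weights > 0) / 2
  }, numeric(1))
  pairs <- n * (n - 1) / 2
  expect_lt(abs(mean(counts) - p * pairs),
            3 * sqrt(pairs * p * (1 - p)) / sqrt(100))
  expect_error(build_probabilistic(5, 1.2, 1, seed = 1),
               class = "oscnet_invalid_input")
})

test_that("is_balanced distinguishes directed configurations", {
  # one-way edge: unbalanced
  w <- matrix(0, 2, 2); w[1, 2] <- 1
  expect_false(is_balanced(coupling_graph(w)))
  # directed 3-cycle with equal weights: balanced (in = out at every node)
  w <- matrix(0, 3, 3)
  w[2, 1] <- w[3, 2] <- w[1, 3] <- 2
  expect_true(is_balanced(coupling_graph(w), tol = 0))
})

test_that("coupling graphs reject self-loops and negative weights", {
  expect_error(coupling_graph(matrix(1, 2, 2)), class = "oscnet_invalid_input")
  w <- matrix(0, 2, 2); w[1, 2] <- -1
  expect_error(coupling_graph(w), class = "oscnet_invalid_input")
})

test_that("coupling_term: vanishes on the synchronization subspace and sums to zero on balanced graphs", {
  g <- build_all_to_all(5, 2)
  same <- matrix(rep(c(1.2, -0.4), each = 5), 5)
  expect_equal(coupling_term(g, same), matrix(0, 5, 2))
  # node sum cancels for balanced graphs, arbitrary states
  w <- matrix(0, 3, 3); w[2, 1] <- w[3, 2] <- w[1, 3] <- 1.5  # directed cycle
  for (graph in list(g, coupling_graph(w),
                     suppressWarnings(build_probabilistic(8, 0.4, 1, seed = 3)))) {
    X <- random_states(graph$n_nodes, 2, seed = graph$n_nodes)
    ct <- coupling_term(graph, X)
    expect_lt(max(abs(colSums(ct))), 1e-12 * max(1, max(abs(ct))))
  }
  # two nodes: k (y - x) and k (x - y)
  g2 <- build_all_to_all(2, 3)
  X <- rbind(c(1, 0), c(-2, 0))
  expect_equal(coupling_term(g2, X)[, 1], c(3 * (-2 - 1), 3 * (1 - -2)))
  # translation equivariance: depends only on differences
  X <- random_states(5, 2, seed = 9)
  shifted <- sweep(X, 2, c(10, -3), "+")
  expect_equal(coupling_term(g, X), coupling_term(g, shifted), tolerance = 1e-10)
  expect_error(coupling_term(g, X[1:3, ]), class = "oscnet_invalid_input")
})

test_that("quorum star equals all-to-all algebraically and under shared noise", {
  # n = 2 algebraic identity for arbitrary states
  star <- to_quorum_star(2, 4)
  g <- build_all_to_all(2, 4)
  X <- rbind(c(0.3, 1), c(-1.1, 2))
  expect_equal(coupling_term(star, X), coupling_term(g, X), tolerance = 1e-14)
  # identical states: zero contribution in both forms
  same <- rbind(c(0.5, 1), c(0.5, 1))
  expect_equal(coupling_term(star, same), matrix(0, 2, 2))
  # shared noise stream: trajectories agree to 1e-10 over 1000 steps
  m <- fn_model()
  x0 <- sample_initial_conditions(m, 10, seed = 5)
  cfg <- sim_config(1e-3, 1, seed = 11)
  t_full <- euler_maruyama(m, build_all_to_all(10, 5), 0.5, x0 = x0, config = cfg)
  t_star <- euler_maruyama(m, to_quorum_star(10, 5), 0.5, x0 = x0, config = cfg)
  expect_lt(max(abs(t_full$states - t_star$states)), 1e-10)
})

test_that("edge-list CSV round trip preserves the graph", {
  g <- suppressWarnings(build_probabilistic(12, 0.4, 1.5, seed = 8))
  path <- tempfile(fileext = ".csv")
  graph_to_edgelist(g, path)
  g2 <- graph_from_edgelist(path, n_nodes = 12)
  expect_equal(g2$weights, g$weights)
  unlink(path)
})
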