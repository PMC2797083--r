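test_that("synchronization bound: zero without noise, monotone in k, scales as sigma^2, vanishes as k grows", {
  p <- fn_params()
  expect_identical(quiet_bound(sync_bound_all_to_all(10, 5, 0))$bound_value, 0)
  ks <- c(5, 10, 20, 40, 80)
  vals <- vapply(ks, function(k) {
    quiet_bound(sync_bound_all_to_all(10, k, 0.5))$bound_value
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
  # doubling k roughly halves the large-k asymptote
  b1 <- quiet_bound(sync_bound_all_to_all(10, 50, 0.5))
  b2 <- quiet_bound(sync_bound_all_to_all(10, 100, 0.5))
  expect_equal(b2$details$asymptotic / b1$details$asymptotic, 0.5)
  # proportional to sigma^2
  s1 <- quiet_bound(sync_bound_all_to_all(8, 20, 0.3))$bound_value
  s2 <- quiet_bound(sync_bound_all_to_all(8, 20, 0.6))$bound_value
  expect_equal(s2 / s1, 4, tolerance = 1e-12)
  # k -> infinity limit
  expect_lt(quiet_bound(sync_bound_all_to_all(10, 1e9, 1))$bound_value, 1e-7)
  expect_error(sync_bound_all_to_all(1, 5, 0.5), class = "oscnet_invalid_input")
  expect_warning(sync_bound_all_to_all(2, 1, 0.5), class = "oscnet_weak_coupling")
})

test_that("pair bound is consistent with the general-N pair decomposition", {
  # at n = 2 the ordered-pair sum counts the one pair twice
  b_pair <- quiet_bound(pair_bound(20, 0.5))
  b_net <- quiet_bound(sync_bound_all_to_all(2, 20, 0.5))
  expect_equal(b_net$bound_value, 2 * b_pair$bound_value, tolerance = 1e-14)
  # each pair in an n-network feels damping n k: summing the pair bound
  # evaluated at that damping over n(n-1) ordered pairs gives the network
  # bound
  n <- 7; k <- 10; sigma <- 0.4
  per_pair <- quiet_bound(pair_bound(n * k / 2, sigma))$bound_value
  expect_equal(quiet_bound(sync_bound_all_to_all(n, k, sigma))$bound_value,
               n * (n - 1) * per_pair, tolerance = 1e-14)
  # nonincreasing over a doubling grid
  vals <- vapply(c(2, 4, 8, 16, 32), function(k) {
    quiet_bound(pair_bound(k, 1))$bound_value
  }, numeric(1))
  expect_true(all(diff(vals) <= 0))
  expect_identical(quiet_bound(pair_bound(5, 0))$bound_value, 0)
})

test_that("eigenmode transform round-trips and kills the difference modes of identical pairs", {
  set.seed(31)
  for (i in 1:20) {
    X <- matrix(rnorm(4), 2)
    tr <- eigenmode_transform(X, k = 10)
    expect_equal(eigenmode_inverse(tr), X, tolerance = 1e-12)
  }
  same <- rbind(c(0.8, -0.1), c(0.8, -0.1))
  expect_equal(eigenmode_transform(same, k = 10)$y, c(0, 0))
  # singular at 2k = 1
  expect_error(eigenmode_transform(matrix(rnorm(4), 2), k = 0.5),
               class = "oscnet_degenerate_transform")
})

test_that("mode decay rates of the difference system match the eigenvalues", {
  p <- fn_params()
  k <- 20
  modes <- pair_modes(p, k)  # kappa = 2k, alpha = 0
  lam <- sort(Re(modes$values))  # fast (most negative) first
  M <- modes$M
  dt <- 1e-5
  fit_rate <- function(y0, t_end) {
    n <- round(t_end / dt)
    y <- y0
    norms <- numeric(n)
    for (s in 1:n) {
      y <- y + dt * (M %*% y)
      norms[s] <- sqrt(sum(y^2))
    }
    tt <- (1:n) * dt
    unname(coef(lm(log(norms) ~ tt))[2])
  }
  # start on each eigenvector, fit the exponential decay of the norm
  v_fast <- Re(modes$vectors[, which.min(Re(modes$values))])
  v_slow <- Re(modes$vectors[, which.max(Re(modes$values))])
  expect_equal(fit_rate(v_fast, 0.02), lam[1], tolerance = 0.05)
  expect_equal(fit_rate(v_slow, 1), lam[2], tolerance = 0.05)
})

test_that("Taylor mismatch: hand-computed cubic example and linear exactness", {
  cubic <- oscillator_model(
    "cubic", 1L,
    drift = function(states, t, input, params) {
      matrix(states[, 1L] - states[, 1L]^3 / 3 + input, ncol = 1L)
    },
    hessian_sup = function(radius, params) 2 * radius)
  out <- taylor_mismatch(cubic, matrix(c(0, 1), 2, 1), Q = 2)
  # mean drift (f(0) + f(1))/2 = 1/3; drift at mean f(1/2) = 11/24
  expect_equal(out$mismatch, 0.125)
  expect_equal(out$bound, 0.25)
  expect_lte(out$mismatch, out$bound)
  # linear dynamics contribute nothing to the mismatch
  lin <- linear_model(A = matrix(c(-1, 1, 0.5, -2), 2))
  X <- random_states(6, 2, seed = 12)
  out_lin <- taylor_mismatch(lin, X, Q = 0)
  expect_lt(out_lin$mismatch, 1e-12)
  expect_identical(out_lin$bound, 0)
  # states outside the curvature region are refused
  expect_error(taylor_mismatch(cubic, matrix(c(0, 3), 2, 1), Q = 2),
               class = "oscnet_precondition")
})

test_that("mean-impact bound combines averaging and nonlinearity terms", {
  expect_identical(mean_impact_bound(0, 1, 0, 5)$bound_value, 0)
  # pure averaging: inverse square root of n
  b1 <- mean_impact_bound(0, 0, 1, 1)$bound_value
  b4 <- mean_impact_bound(0, 0, 1, 4)$bound_value
  expect_equal(b4, b1 / 2)
  # joint limit n -> infinity, C -> 0
  expect_lt(mean_impact_bound(5, 1e-8, 1, 1e8)$bound_value, 1e-3)
  expect_error(mean_impact_bound(-1, 0, 0, 1), class = "oscnet_invalid_input")
})

test_that("bound reports expose tidy/glance tibbles", {
  b <- quiet_bound(sync_bound_all_to_all(10, 20, 0.5))
  td <- tidy(b)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$bound_value, b$bound_value)
  expect_equal(glance(b)$kind, "A4_all_to_all")
})
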