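test_that("FN drift matches the printed equations at reference points", {
  p <- fn_params()
  # cubic term vanishes at v = 0: voltage derivative is exactly c * w
  for (w in c(-1, 0, 0.5, 2)) {
    expect_identical(fn_drift(c(0, w))[1], p$c * w)
  }
  # equilibrium found by an independent scalar root find is a fixed point
  eq <- fn_equilibrium(p)
  expect_lt(max(abs(fn_drift(eq))), 1e-10)
  # input enters linearly, voltage channel only
  x <- c(0.7, -0.3)
  delta <- 0.37
  expect_equal(fn_drift(x, input = 1 + delta) - fn_drift(x, input = 1),
               c(delta, 0))
})

test_that("FN drift validates its inputs", {
  expect_error(fn_drift(c(NA, 0)), class = "oscnet_invalid_input")
  expect_error(fn_drift(c(Inf, 0)), class = "oscnet_invalid_input")
  expect_error(fn_drift(c(0, 0), params = list(a = 0.3, b = 0.8)),
               regexp = "c", class = "oscnet_invalid_input")
})

test_that("HR drift matches an independent polynomial expansion", {
  grid <- expand.grid(x = -2:2, y = c(-5, 0, 3), z = c(0, 2))
  for (i in seq_len(nrow(grid))) {
    s <- as.numeric(grid[i, ])
    expect_equal(hr_drift(s, input = 0.5), hr_poly_oracle(s, input = 0.5),
                 tolerance = 1e-12)
  }
  # input linearity: shift appears only in the first component
  s <- c(0.4, -1.2, 2.1)
  expect_equal(hr_drift(s, input = 2.5) - hr_drift(s, input = 1.5),
               c(1, 0, 0))
  # autonomous with constant input
  expect_identical(hr_drift(s, t = 0, input = 3), hr_drift(s, t = 100, input = 3))
  expect_error(hr_drift(s, params = list(a = 1)), class = "oscnet_invalid_input")
})

test_that("linear drift is affine with the expected special cases", {
  expect_equal(linear_drift(c(1, 2), A = matrix(0, 2, 2)), c(0, 0))
  # scalar Ornstein-Uhlenbeck
  expect_equal(linear_drift(0.7, A = -2.5), -2.5 * 0.7)
  # affine superposition
  A <- matrix(c(0, 1, -1, -0.5), 2)
  b <- c(0.3, -0.1)
  x <- c(1, -2); y <- c(0.5, 0.25)
  expect_equal(linear_drift(x + y, A = A, b = b),
               linear_drift(x, A = A, b = b) + linear_drift(y, A = A, b = b) - b)
  expect_error(linear_drift(c(1, 2, 3), A = A), class = "oscnet_invalid_input")
})

test_that("hessian_bound: zero for linear models, closed form for FN", {
  lin <- linear_model(A = matrix(c(-1, 0.5, 0, -2), 2))
  for (r in c(0, 1, 10)) expect_identical(hessian_bound(lin, r), 0)
  p <- fn_params()
  m <- fn_model()
  expect_equal(hessian_bound(m, 0), 0)
  # grid-search oracle over |v| <= 1 of |d^2/dv^2 c(v - v^3/3)| = |2 c v|
  grid <- seq(-1, 1, length.out = 2001)
  oracle <- max(abs(-2 * p$c * grid))
  expect_equal(hessian_bound(m, 1), oracle, tolerance = 1e-12)
  expect_error(hessian_bound(m, -1), class = "oscnet_invalid_input")
})

test_that("hessian_bound is nondecreasing in radius for built-in models", {
  radii <- c(0, 0.5, 1, 2, 5)
  for (m in list(fn_model(), hr_model())) {
    q <- vapply(radii, function(r) hessian_bound(m, r), numeric(1))
    expect_true(all(diff(q) >= 0))
  }
})

test_that("finite-difference Hessian fallback agrees with a closed form", {
  cubic <- oscillator_model(
    "cubic", 1L,
    drift = function(states, t, input, params) {
      matrix(states[, 1L] - states[, 1L]^3 / 3 + input, ncol = 1L)
    })
  # |f''(v)| = |2 v|, sup over |v| <= r is 2 r
  expect_equal(hessian_bound(cubic, 1.5), 3, tolerance = 1e-3)
})

test_that("trajectory_radius equals an exhaustive scan of the stored array", {
  m <- fn_model()
  cfg <- sim_config(1e-3, 40, transient = 0, record_stride = 5L)
  traj <- simulate_noise_free(m, x0 = c(0.5, 0), config = cfg)
  brute <- max(abs(as.vector(traj$states[, , 1])))
  expect_identical(trajectory_radius(traj), brute)
  # constant single unit
  const <- traj
  const$states[] <- -1.7
  expect_identical(trajectory_radius(const), 1.7)
  const$states[] <- 0
  expect_identical(trajectory_radius(const), 0)
})

test_that("model presets load from the shipped YAML single source", {
  pr <- model_presets()
  expect_named(pr$fn$params, c("a", "b", "c"))
  expect_setequal(names(pr$hr$params), c("a", "b", "c", "d", "r", "s", "x_r"))
  expect_length(pr$fn$noise_mask, 2L)
  expect_length(pr$hr$ic_box, 3L)
})
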