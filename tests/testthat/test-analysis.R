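test_that("center of mass equals a brute-force element-wise mean", {
  X <- random_states(5, 3, seed = 1)
  brute <- numeric(3)
  for (j in 1:3) {
    s <- 0
    for (i in 1:5) s <- s + X[i, j]
    brute[j] <- s / 5
  }
  expect_equal(center_of_mass(X), brute)
  expect_equal(center_of_mass(rbind(c(1, 2), c(-1, -2))), c(0, 0))
  expect_error(center_of_mass(X[0, , drop = FALSE]),
               class = "oscnet_invalid_input")
})

test_that("pairwise sum of squared distances equals 2N times the distances to the center", {
  for (seed in 1:5) {
    n <- sample(2:20, 1)
    dim <- sample(1:3, 1)
    X <- random_states(n, dim, seed = seed)
    com <- colMeans(X)
    com_form <- 2 * n * sum(sweep(X, 2, com)^2)
    expect_equal(brute_pair_sum(X), com_form, tolerance = 1e-12)
  }
})

test_that("sync_error conventions and trivial cases behave as documented", {
  m <- fn_model()
  # identical oscillators at all times -> exactly zero
  g <- build_all_to_all(4, 2)
  x0 <- matrix(rep(c(0.4, -0.2), each = 4), 4)
  traj <- euler_maruyama(m, g, 0, x0 = x0, config = sim_config(1e-2, 5))
  # identical rows stay on the synchronization subspace up to the rounding
  # of the weight-matrix sums
  expect_lt(sync_error(traj)$sync_error, 1e-12)
  # two constant units at distance d: sum convention counts both ordered
  # pairs, average divides by n(n-1)
  const <- traj
  const$states <- array(0, c(length(traj$times), 2, 2))
  const$states[, 2, 1] <- 3
  st_sum <- sync_error(const, transient = 0)
  st_avg <- sync_error(const, transient = 0, convention = "average")
  expect_equal(st_sum$sync_error, 2 * 9)
  expect_equal(st_avg$sync_error, 9)
  expect_error(sync_error(traj, transient = 10), class = "oscnet_invalid_input")
})

test_that("spatial mean series reduces correctly", {
  m <- fn_model()
  traj <- simulate_noise_free(m, x0 = c(0.5, 0), config = sim_config(1e-2, 5))
  expect_equal(spatial_mean_series(traj)$value, traj$states[, 1, 1])
  const <- traj
  const$states <- array(rep(c(1, 2, 3), each = length(traj$times)),
                        c(length(traj$times), 3, 1))
  const$coupling_mask <- TRUE
  expect_equal(unique(spatial_mean_series(const)$value), 2)
  expect_error(spatial_mean_series(traj, component = 5),
               class = "oscnet_invalid_input")
})

test_that("power spectrum is Parseval-consistent and locates pure tones", {
  dt <- 0.05
  t <- seq(0, 500 - dt, by = dt)
  x <- sin(2 * pi * 0.31 * t)
  sp <- power_spectrum(x, dt)
  expect_equal(sum(sp$table$power), mean((x - mean(x))^2), tolerance = 1e-8)
  peak_bin <- sp$table$frequency[which.max(sp$table$power)]
  expect_lt(abs(peak_bin - 0.31), sp$resolution)
  expect_lt(abs(dominant_frequency(sp) - 0.31), sp$resolution)
  # constant series: all power zero after mean removal
  spc <- power_spectrum(rep(2.5, 64), dt = 1)
  expect_equal(max(spc$table$power), 0)
  expect_error(power_spectrum(x[1:8], dt), class = "oscnet_invalid_input")
  expect_error(
    power_spectrum(tibble::tibble(time = cumsum(runif(100)), value = rnorm(100))),
    class = "oscnet_invalid_input")
})

test_that("white noise has a flat spectrum", {
  set.seed(5)
  sp <- power_spectrum(rnorm(1e5), dt = 1)
  pw <- sp$table$power[-1]
  half <- length(pw) %/% 2
  ratio <- mean(pw[1:half]) / mean(pw[(half + 1):(2 * half)])
  expect_gt(ratio, 0.8)
  expect_lt(ratio, 1.25)
})

test_that("harmonic match: self-comparison and frequency offsets", {
  dt <- 0.05
  t <- seq(0, 400 - dt, by = dt)
  sp1 <- power_spectrum(sin(2 * pi * 0.2 * t), dt)
  hm_self <- harmonic_match(sp1, sp1)
  expect_equal(hm_self$rel_diff[1], 0)
  expect_equal(hm_self$clarity_a, hm_self$clarity_b)
  sp2 <- power_spectrum(sin(2 * pi * 0.3 * t), dt)
  hm <- harmonic_match(sp1, sp2)
  expect_equal(hm$rel_diff[1], 0.5, tolerance = 0.02)
  # white noise against a tone: degraded clarity, lower score
  set.seed(8)
  spn <- power_spectrum(rnorm(length(t)), dt)
  hmn <- harmonic_match(sp1, spn)
  expect_lt(attr(hmn, "clarity_score_b"), attr(hm_self, "clarity_score_b"))
  expect_false(attr(hmn, "clear_b"))
})

test_that("trajectory distance: identity, offset, and triangle-type inequality", {
  m <- fn_model()
  cfg <- sim_config(1e-2, 10, seed = 9)
  a <- simulate_noise_free(m, x0 = c(0.5, 0), config = cfg)
  expect_identical(trajectory_distance(a, a), 0)
  b <- a
  b$states <- a$states + 0.7
  expect_equal(trajectory_distance(a, b), 2 * 0.7^2, tolerance = 1e-12)
  # squared-distance triangle property through the ensemble mean
  traj <- euler_maruyama(m, build_all_to_all(5, 5), 0.3,
                         x0 = sample_initial_conditions(m, 5, seed = 10),
                         config = cfg)
  com <- as.matrix(center_of_mass(traj)[, c("c1", "c2")])
  ref <- matrix(a$states[, 1, ], ncol = 2)
  for (i in 1:5) {
    xi <- matrix(traj$states[, i, ], ncol = 2)
    lhs <- mean(rowSums((xi - ref)^2))
    rhs <- 2 * mean(rowSums((xi - com)^2)) + 2 * mean(rowSums((com - ref)^2))
    expect_lte(lhs, rhs + 1e-12)
  }
  short <- simulate_noise_free(m, x0 = c(0.5, 0), config = sim_config(1e-2, 5))
  expect_error(trajectory_distance(a, short), class = "oscnet_invalid_input")
})

test_that("sync stats and spectra expose tidy/glance/autoplot", {
  m <- fn_model()
  traj <- euler_maruyama(m, build_all_to_all(3, 5), 0.2,
                         x0 = sample_initial_conditions(m, 3, seed = 2),
                         config = sim_config(1e-2, 10, seed = 2, transient = 2))
  st <- sync_error(traj)
  expect_s3_class(tidy(st), "tbl_df")
  expect_equal(glance(st)$n_osc, 3L)
  sp <- power_spectrum(spatial_mean_series(traj), 1e-2)
  expect_s3_class(tidy(sp), "tbl_df")
  expect_s3_class(ggplot2::autoplot(traj), "ggplot")
  expect_s3_class(ggplot2::autoplot(sp), "ggplot")
  expect_s3_class(ggplot2::autoplot(st), "ggplot")
})
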