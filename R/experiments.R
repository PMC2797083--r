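#' Common input signals
#'
#' Deterministic scalar signals applied identically to every unit of a
#' network (the analysis tolerates arbitrary common time-varying inputs,
#' as long as all units receive the same one).
#'
#' @param kind `"constant"`, `"step"`, `"sinusoid"` or `"piecewise"`.
#' @param params named list:
#'   constant: `value`;
#'   step: `t0`, `before`, `after`;
#'   sinusoid: `amplitude`, `frequency`, `phase` (0), `offset` (0);
#'   piecewise: `times` (breakpoints, increasing), `values`
#'   (length `length(times) + 1`, value on each interval).
#' @return a function of time.
#' @export
make_input_signal <- function(kind, params = list()) {
  switch(
    kind,
    constant = {
      v <- params$value %||% 0
      check_number(v, "value")
      function(t) v
    },
    step = {
      t0 <- params$t0 %||% abort_invalid("step input needs `t0`.")
      before <- params$before %||% 0
      after <- params$after %||% 1
      function(t) if (t < t0) before else after
    },
    sinusoid = {
      amp <- params$amplitude %||% 1
      freq <- params$frequency %||% abort_invalid("sinusoid input needs `frequency`.")
      phase <- params$phase %||% 0
      offset <- params$offset %||% 0
      function(t) offset + amp * sin(2 * pi * freq * t + phase)
    },
    piecewise = {
      times <- params$times %||% abort_invalid("piecewise input needs `times`.")
      values <- params$values %||% abort_invalid("piecewise input needs `values`.")
      if (length(values) != length(times) + 1L) {
        abort_invalid("piecewise input needs length(values) == length(times) + 1.")
      }
      function(t) values[[findInterval(t, times) + 1L]]
    },
    abort_invalid(sprintf("unknown input kind `%s`.", kind)))
}

derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1103 + 7919 * i) %% 2147483647)
}

#' Experiment presets and their defaults
#'
#' Named, fully self-contained experiment designs; every preset runs with
#' defaults and no external data.  Scales (network sizes, horizons) are
#' desk-scale -- reduced relative to a publication-scale study -- and the
#' manifests mark them `scaled_down`.
#'
#' @return named list of default parameter lists.
#' @export
experiment_presets <- function() {
  list(
    fig1_protection = list(
      n = 20L, k = 10, sigma = 0.5, dt = 1e-3, t_end = 400, transient = 52,
      record_stride = 5L),
    fig2_spatial_mean = list(
      n = 20L, k = 5, sigma = 0.5, dt = 5e-4, t_end = 200, transient = 40,
      record_stride = 10L),
    fig3a_bound_sweep = list(
      n_grid = c(5L, 10L), k_grid = c(10, 20), sigma = 0.5,
      kappa_dt = 0.0125, t_end = 60, transient = 20, record_dt = 2e-3),
    fig3b_observer_sweep = list(
      n = 10L, k_grid = c(10, 20, 40), sigma = 0.5, ke = 30, dt = 2e-4,
      t_end = 40, transient = 15, record_stride = 1L),
    fig4_probabilistic = list(
      n = 30L, p = 0.3, k = 5, sigma = 0.5, dt = 5e-4, t_end = 160,
      transient = 40, record_stride = 10L),
    fig5_hindmarsh_rose = list(
      n = 10L, k = 0.5, sigma = 0.3, dt = 0.01, t_end = 800, transient = 100,
      record_stride = 10L, step_time = 400, input_before = 1.3,
      input_after = 3.25),
    linear_sqrtN = list(
      a = 2, sigma = 1, n_grid = c(1L, 4L, 16L, 64L), dt = 0.01,
      slope_t_end = 1500, var_n = 10L, var_t_end = 6000, transient = 10,
      record_stride = 5L))
}

#' Run a preset experiment
#'
#' Executes one of the named experiment designs end-to-end --
#' simulations, statistics, theoretical bounds -- and returns a result
#' bundle with a machine-readable summary and a manifest (preset,
#' parameters, seed, config hash, package version) that makes every number
#' reproducible from the config alone.  Deterministic given `seed`.
#'
#' @param preset preset name; see [experiment_presets()].
#' @param overrides named list overriding preset defaults.
#' @param seed integer master seed; all simulation seeds derive from it.
#' @param output_dir optional directory; when given, writes `summary.csv`,
#'   `manifest.json` and any additional tables as CSV.
#' @return a list with `summary` (tibble), `tables` (named list of
#'   tibbles), `manifest`, and preset-specific objects.
#' @export
run_experiment <- function(preset, overrides = list(), seed = 1L,
                           output_dir = NULL) {
  presets <- experiment_presets()
  if (!preset %in% names(presets)) {
    abort_invalid(sprintf("unknown preset `%s`; available: %s.",
                          preset, paste(names(presets), collapse = ", ")))
  }
  pars <- utils::modifyList(presets[[preset]], overrides)
  runner <- switch(preset,
                   fig1_protection = exp_fig1,
                   fig2_spatial_mean = exp_fig2,
                   fig3a_bound_sweep = exp_fig3a,
                   fig3b_observer_sweep = exp_fig3b,
                   fig4_probabilistic = exp_fig4,
                   fig5_hindmarsh_rose = exp_fig5,
                   linear_sqrtN = exp_linear_sqrtn)
  result <- runner(pars, seed)
  result$manifest <- list(
    preset = preset, parameters = pars, seed = seed, scaled_down = TRUE,
    package = "oscnet",
    version = as.character(utils::packageVersion("oscnet")),
    config_hash = rlang::hash(list(preset, pars, seed)))
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(result$summary, file.path(output_dir, "summary.csv"),
              row.names = FALSE)
    for (nm in names(result$tables %||% list())) {
      write.csv(result$tables[[nm]],
                file.path(output_dir, paste0(nm, ".csv")), row.names = FALSE)
    }
    jsonlite::write_json(result$manifest,
                         file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  result
}

voltage_series <- function(traj, transient) {
  keep <- post_transient_index(traj$times, transient)
  d <- dim(traj$states)
  tibble(time = traj$times[keep],
         value = matrix(traj$states[, , 1L], nrow = d[1L])[keep, 1L])
}

# Noise protection of a single unit: noise-free vs. noisy uncoupled vs.
# noisy synchronized, compared in time and frequency domain.
exp_fig1 <- function(p, seed) {
  model <- fn_model()
  cfg <- function(s) sim_config(p$dt, p$t_end, seed = s,
                                transient = p$transient,
                                record_stride = p$record_stride)
  free <- simulate_noise_free(model, x0 = c(0.5, 0), config = cfg(NULL))
  uncoupled <- euler_maruyama(
    model, graph = NULL, noise = p$sigma,
    x0 = sample_initial_conditions(model, 1L, derive_seed(seed, 1L)),
    config = cfg(derive_seed(seed, 2L)))
  graph <- build_all_to_all(p$n, p$k)
  sync <- euler_maruyama(
    model, graph = graph, noise = p$sigma,
    x0 = sample_initial_conditions(model, p$n, derive_seed(seed, 3L)),
    config = cfg(derive_seed(seed, 4L)))

  dt_rec <- p$dt * p$record_stride
  sp_free <- power_spectrum(voltage_series(free, p$transient), dt_rec)
  sp_unc <- power_spectrum(voltage_series(uncoupled, p$transient), dt_rec)
  sp_sync <- power_spectrum(voltage_series(sync, p$transient), dt_rec)
  hm_sync <- harmonic_match(sp_free, sp_sync)
  hm_unc <- harmonic_match(sp_free, sp_unc)
  per <- estimate_period(voltage_series(free, p$transient)$value, dt_rec)

  summary <- tibble(
    n = p$n, k = p$k, sigma = p$sigma,
    period_free = per$period,
    f_free = dominant_frequency(sp_free),
    f_sync = dominant_frequency(sp_sync),
    f_uncoupled = dominant_frequency(sp_unc),
    rel_freq_diff_sync = hm_sync$rel_diff[1L],
    clarity_sync = attr(hm_sync, "clarity_score_b"),
    clarity_uncoupled = attr(hm_unc, "clarity_score_b"),
    harmonics_clear_sync = attr(hm_sync, "clear_b"),
    harmonics_clear_uncoupled = attr(hm_unc, "clear_b"),
    uncoupled_no_peak = attr(hm_unc, "no_peak_b"))
  list(summary = summary,
       tables = list(harmonics_sync = as_tibble(hm_sync),
                     harmonics_uncoupled = as_tibble(hm_unc)),
       spectra = list(free = sp_free, uncoupled = sp_unc, sync = sp_sync),
       trajectories = list(free = free, uncoupled = uncoupled, sync = sync))
}

# Population-mean readout: the spatial mean of uncoupled noisy units loses
# the oscillation; the mean of synchronized units reproduces it.  Both
# ensembles share initial conditions and noise seeds.
exp_fig2 <- function(p, seed) {
  model <- fn_model()
  x0 <- sample_initial_conditions(model, p$n, derive_seed(seed, 1L))
  cfg <- sim_config(p$dt, p$t_end, seed = derive_seed(seed, 2L),
                    transient = p$transient,
                    record_stride = p$record_stride)
  uncoupled <- euler_maruyama(model, NULL, p$sigma, x0 = x0, config = cfg)
  sync <- euler_maruyama(model, build_all_to_all(p$n, p$k), p$sigma,
                         x0 = x0, config = cfg)
  free <- simulate_noise_free(model, x0 = c(0.5, 0), config = sim_config(
    p$dt, p$t_end, transient = p$transient, record_stride = p$record_stride))

  dt_rec <- p$dt * p$record_stride
  keep <- post_transient_index(uncoupled$times, p$transient)
  mean_unc <- spatial_mean_series(uncoupled)[keep, ]
  mean_sync <- spatial_mean_series(sync)[keep, ]
  sp_unc <- power_spectrum(mean_unc, dt_rec)
  sp_sync <- power_spectrum(mean_sync, dt_rec)
  sp_free <- power_spectrum(voltage_series(free, p$transient), dt_rec)
  hm_sync <- harmonic_match(sp_free, sp_sync)
  hm_unc <- harmonic_match(sp_free, sp_unc)

  summary <- tibble(
    n = p$n, k = p$k, sigma = p$sigma,
    sd_mean_uncoupled = stats::sd(mean_unc$value),
    sd_mean_sync = stats::sd(mean_sync$value),
    sd_free = stats::sd(voltage_series(free, p$transient)$value),
    clarity_mean_sync = attr(hm_sync, "clarity_score_b"),
    clarity_mean_uncoupled = attr(hm_unc, "clarity_score_b"),
    harmonics_clear_sync = attr(hm_sync, "clear_b"),
    harmonics_clear_uncoupled = attr(hm_unc, "clear_b"),
    uncoupled_no_peak = attr(hm_unc, "no_peak_b"),
    rel_freq_diff_sync = hm_sync$rel_diff[1L])
  list(summary = summary,
       tables = list(mean_uncoupled = mean_unc, mean_sync = mean_sync),
       spectra = list(free = sp_free, uncoupled = sp_unc, sync = sp_sync))
}

# Empirical synchronization error vs. the theoretical bound over a
# (network size, coupling strength) grid.  The step shrinks with the
# effective pairwise damping kappa = n k (kappa * dt <= kappa_dt) so the
# explicit scheme's variance inflation, about kappa*dt/2, stays well below
# the bound's margin; halving dt moves the statistic by < 2%.
exp_fig3a <- function(p, seed) {
  model <- fn_model()
  grid <- expand.grid(n = p$n_grid, k = p$k_grid)
  rows <- purrr::pmap(grid, function(n, k) {
    n <- as.integer(n)
    dt <- min(2e-4, p$kappa_dt / (n * k))
    traj <- euler_maruyama(
      model, build_all_to_all(n, k), p$sigma,
      x0 = sample_initial_conditions(model, n, derive_seed(seed, n * 1000L + k)),
      config = sim_config(dt, p$t_end, seed = derive_seed(seed, n * 7L + k),
                          transient = p$transient,
                          record_stride = max(1L, round(p$record_dt / dt))))
    stats <- sync_error(traj, transient = p$transient)
    bnd <- sync_bound_all_to_all(n, k, p$sigma, model$params)
    tibble(n = n, k = k, sigma = p$sigma,
           empirical_C = stats$sync_error,
           bound_C = bnd$bound_value,
           empirical_avg_to_com = stats$mean_sq_to_com,
           bound_avg_to_com = bnd$details$avg_sq_to_com_bound,
           ratio = stats$sync_error / bnd$bound_value)
  })
  summary <- dplyr::bind_rows(rows)
  list(summary = summary, tables = list(bound_sweep = summary))
}

# Observer distance for a synchronized unit as coupling grows.
exp_fig3b <- function(p, seed) {
  model <- fn_model()
  rows <- purrr::map(p$k_grid, function(k) {
    traj <- euler_maruyama(
      model, build_all_to_all(p$n, k), p$sigma,
      x0 = sample_initial_conditions(model, p$n, derive_seed(seed, 11L + k)),
      config = sim_config(p$dt, p$t_end, seed = derive_seed(seed, 13L + k),
                          transient = p$transient, record_stride = 1L))
    run <- run_observer(traj, model, oscillator = 1L,
                        gains = list(ke = p$ke))
    tibble(n = p$n, k = k, sigma = p$sigma, ke = p$ke,
           observer_stat = observer_distance_stat(run, p$transient),
           bound = observer_bound(p$n, k, p$sigma, model$params,
                                  ke = p$ke)$bound_value)
  })
  summary <- dplyr::bind_rows(rows)
  list(summary = summary, tables = list(observer_sweep = summary))
}

# Random symmetric network: a unit synchronized through probabilistic
# connections is still protected.
exp_fig4 <- function(p, seed) {
  model <- fn_model()
  graph <- build_probabilistic(p$n, p$p, p$k, seed = derive_seed(seed, 5L))
  cfg <- sim_config(p$dt, p$t_end, seed = derive_seed(seed, 6L),
                    transient = p$transient, record_stride = p$record_stride)
  traj <- euler_maruyama(
    model, graph, p$sigma,
    x0 = sample_initial_conditions(model, p$n, derive_seed(seed, 7L)),
    config = cfg)
  free <- simulate_noise_free(model, x0 = c(0.5, 0), config = sim_config(
    p$dt, p$t_end, transient = p$transient, record_stride = p$record_stride))
  dt_rec <- p$dt * p$record_stride
  sp_free <- power_spectrum(voltage_series(free, p$transient), dt_rec)
  sp_net <- power_spectrum(voltage_series(traj, p$transient), dt_rec)
  hm <- harmonic_match(sp_free, sp_net)
  stats <- sync_error(traj, transient = p$transient)
  summary <- tibble(
    n = p$n, p_connect = p$p, k = p$k, sigma = p$sigma,
    connected = graph_is_connected(graph),
    edges = sum(graph$weights > 0) / 2,
    f_free = dominant_frequency(sp_free),
    f_network = dominant_frequency(sp_net),
    rel_freq_diff = hm$rel_diff[1L],
    clarity = attr(hm, "clarity_score_b"),
    sync_error = stats$sync_error)
  list(summary = summary, tables = list(harmonics = as_tibble(hm)),
       graph = graph, spectra = list(free = sp_free, network = sp_net))
}

window_sd <- function(series, from, to) {
  v <- series$value[series$time >= from & series$time < to]
  stats::sd(v)
}

# Hindmarsh-Rose units under a common step input: the synchronized
# population mean preserves the input-driven regime change, the uncoupled
# mean blurs it out.
exp_fig5 <- function(p, seed) {
  model <- hr_model()
  input <- make_input_signal("step", list(t0 = p$step_time,
                                          before = p$input_before,
                                          after = p$input_after))
  x0 <- sample_initial_conditions(model, p$n, derive_seed(seed, 21L))
  cfg <- sim_config(p$dt, p$t_end, seed = derive_seed(seed, 22L),
                    transient = p$transient, record_stride = p$record_stride)
  uncoupled <- euler_maruyama(model, NULL, p$sigma, input, x0, cfg)
  sync <- euler_maruyama(model, build_all_to_all(p$n, p$k), p$sigma,
                         input, x0, cfg)
  free <- simulate_noise_free(model, input, x0 = x0[1L, ], config = sim_config(
    p$dt, p$t_end, transient = p$transient, record_stride = p$record_stride))

  mean_unc <- spatial_mean_series(uncoupled)
  mean_sync <- spatial_mean_series(sync)
  # oscillation amplitude of the population mean in each input regime
  pre <- c(p$transient, p$step_time)
  post <- c(p$step_time + p$transient / 2, p$t_end)
  summary <- tibble(
    n = p$n, k = p$k, sigma = p$sigma,
    amp_sync_pre = window_sd(mean_sync, pre[1L], pre[2L]),
    amp_sync_post = window_sd(mean_sync, post[1L], post[2L]),
    amp_uncoupled_pre = window_sd(mean_unc, pre[1L], pre[2L]),
    amp_uncoupled_post = window_sd(mean_unc, post[1L], post[2L]),
    amp_free_pre = window_sd(spatial_mean_series(free), pre[1L], pre[2L]),
    amp_free_post = window_sd(spatial_mean_series(free), post[1L], post[2L]))
  summary$tracking_sync <- summary$amp_sync_post / summary$amp_sync_pre
  summary$tracking_uncoupled <-
    summary$amp_uncoupled_post / summary$amp_uncoupled_pre
  list(summary = summary,
       tables = list(mean_uncoupled = mean_unc, mean_sync = mean_sync),
       trajectories = list(free = free))
}

# Linear (Ornstein-Uhlenbeck) ensembles: the impact of noise on the mean
# follows the classical 1/sqrt(N) averaging law.  Units have correlation
# time 1/a; the variance window var_t_end is thousands of correlation
# times so the ergodic variance estimate resolves the closed form well
# inside 5%.
exp_linear_sqrtn <- function(p, seed) {
  model <- linear_model(A = -p$a, state_dim = 1L)
  mean_sq <- function(n, t_end, tag) {
    traj <- euler_maruyama(
      model, NULL, p$sigma, x0 = matrix(0, n, 1L),
      config = sim_config(p$dt, t_end, seed = derive_seed(seed, 31L + n + tag),
                          transient = p$transient,
                          record_stride = p$record_stride))
    m <- spatial_mean_series(traj)
    keep <- post_transient_index(traj$times, p$transient)
    mean(m$value[keep]^2)
  }
  rows <- purrr::map(p$n_grid, function(n) {
    n <- as.integer(n)
    v <- mean_sq(n, p$slope_t_end, 0L)
    tibble(n = n, mean_sq_deviation = v, rms_deviation = sqrt(v),
           theory = p$sigma^2 / (2 * p$a * n))
  })
  summary <- dplyr::bind_rows(rows)
  fit <- lm(log(rms_deviation) ~ log(n), data = summary)
  var_n <- as.integer(p$var_n)
  v10 <- mean_sq(var_n, p$var_t_end, 1000L)
  list(summary = summary,
       tables = list(sqrtn = summary),
       slope = unname(coef(fit)[2L]),
       variance_ratio = summary$mean_sq_deviation / summary$theory,
       var_check = tibble(
         n = var_n, mean_sq_deviation = v10,
         theory = p$sigma^2 / (2 * p$a * var_n),
         ratio = v10 / (p$sigma^2 / (2 * p$a * var_n))))
}
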