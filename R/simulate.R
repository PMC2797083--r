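#' Simulation configuration
#'
#' @param dt positive integration step (model time units).
#' @param t_end positive time horizon.
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @param transient nonnegative time window discarded before statistics
#'   (recorded but flagged); must be < `t_end`.
#' @param record_stride positive integer: keep every `record_stride`-th step.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(dt, t_end, seed = NULL, transient = 0,
                       record_stride = 1L) {
  check_number(dt, "dt", min = 0, strict_min = TRUE)
  check_number(t_end, "t_end", min = 0, strict_min = TRUE)
  if (dt > t_end) abort_invalid("`dt` must be <= `t_end`.")
  check_number(transient, "transient", min = 0)
  if (transient >= t_end) abort_invalid("`transient` must be < `t_end`.")
  record_stride <- as.integer(record_stride)
  if (is.na(record_stride) || record_stride < 1L) {
    abort_invalid("`record_stride` must be a positive integer.")
  }
  structure(list(dt = dt, t_end = t_end, seed = seed, transient = transient,
                 record_stride = record_stride),
            class = "sim_config")
}

# Run expr with the RNG seeded at `seed`, restoring the caller's RNG state
# afterwards so simulations do not disturb the session stream.
with_preserved_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  if (!is.null(seed)) set.seed(as.integer(seed))
  expr
}

#' Reproducible Gaussian noise streams
#'
#' A noise stream is a self-contained generator of standard-normal
#' increments with private RNG state: two streams built from the same
#' `(seed, stream)` yield bitwise-identical sequences regardless of what
#' else the session draws, which is how matched-noise comparisons (e.g. the
#' all-to-all vs. quorum-star equivalence, or same-initial-conditions
#' contrasts) are wired.  Different `stream` ids give independent
#' substreams, e.g. one per oscillator.
#'
#' @param seed integer base seed.
#' @param stream integer substream identifier.
#' @return a function `f(n)` returning `n` standard-normal draws.
#' @export
noise_stream <- function(seed, stream = 0L) {
  priv <- new.env(parent = emptyenv())
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(as.integer((as.numeric(seed) + 1000003 * stream) %%
                        .Machine$integer.max))
  priv$state <- get(".Random.seed", envir = globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  function(n) {
    old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
    assign(".Random.seed", priv$state, envir = globalenv())
    z <- rnorm(n)
    priv$state <- get(".Random.seed", envir = globalenv())
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
    z
  }
}

#' Euler-Maruyama integration of a coupled noisy network
#'
#' Integrates \eqn{dx_i = [f(x_i, t) + u(t)\,e_{in} +
#' \sum_j w_{ij}(x_j - x_i)]\,dt + \sigma\,dW_i} with the explicit
#' Euler-Maruyama scheme: per step, the drift (model + diffusive coupling +
#' common input) times `dt`, plus `sigma * sqrt(dt)` times independent
#' standard-normal increments on the noise-masked components of each unit.
#' Identical `(seed, config, model, graph, input)` give bitwise-identical
#' output.  Integration aborts with a divergence error when any state
#' component leaves \eqn{[-10^6, 10^6]} or becomes non-finite (cubic drifts
#' explode under too-large steps).
#'
#' @param model an [oscillator_model()].
#' @param graph a [coupling_graph()], a `quorum_star`, or `NULL` for
#'   uncoupled units.
#' @param noise a [noise_spec()] or a nonnegative number `sigma`.
#' @param input common input signal: `NULL` (zero), a constant, or a
#'   function of time; identical for all units.
#' @param x0 initial conditions: N x dim matrix (or a vector for one unit).
#' @param config a [sim_config()].
#' @param noise_fun optional generator from [noise_stream()]; when supplied
#'   it replaces the seeded global RNG as the source of increments.
#' @return an `ensemble_traj`: times, a (time x unit x component) state
#'   array, and full provenance (config, model name, graph digest, sigma).
#'   Convert to a long tibble with [as_tibble()].
#' @export
euler_maruyama <- function(model, graph = NULL, noise = 0, input = NULL,
                           x0, config, noise_fun = NULL) {
  stopifnot(inherits(model, "oscillator_model"), inherits(config, "sim_config"))
  sigma <- as_sigma(noise)
  if (is.null(dim(x0))) x0 <- matrix(x0, nrow = 1L)
  x0 <- as.matrix(x0)
  if (ncol(x0) != model$state_dim) {
    abort_invalid("`x0` must have `state_dim` columns.")
  }
  if (!all(is.finite(x0))) abort_invalid("`x0` must be finite.")
  n_osc <- nrow(x0)
  if (!is.null(graph) && graph$n_nodes != n_osc) {
    abort_invalid("`graph` and `x0` disagree on the number of units.")
  }

  input_fun <-
    if (is.null(input)) function(t) 0
    else if (is.function(input)) input
    else {
      check_number(input, "input")
      local({v <- input; function(t) v})
    }

  dt <- config$dt
  n_steps <- as.integer(round(config$t_end / dt))
  stride <- config$record_stride
  rec_steps <- seq.int(0L, n_steps, by = stride)
  n_rec <- length(rec_steps)
  states <- array(NA_real_, c(n_rec, n_osc, model$state_dim))

  ncols <- which(model$noise_mask)
  ccols <- which(model$coupling_mask)
  params <- model$params
  is_star <- inherits(graph, "quorum_star")
  if (!is.null(graph) && !is_star) {
    W <- graph$weights
    rs <- rowSums(W)
  }
  sig_sqdt <- sigma * sqrt(dt)
  draw <- noise_fun %||% rnorm

  run <- function() {
    x <- x0
    states[1L, , ] <<- x
    ri <- 1L
    for (s in seq_len(n_steps)) {
      t <- (s - 1L) * dt
      u <- input_fun(t)
      dx <- model$drift(x, t, u, params)
      if (!is.null(graph)) {
        xs <- x[, ccols, drop = FALSE]
        if (is_star) {
          dx[, ccols] <- dx[, ccols] +
            graph$damping * sweep(-xs, 2L, colMeans(xs), "+")
        } else {
          dx[, ccols] <- dx[, ccols] + W %*% xs - rs * xs
        }
      }
      x <- x + dt * dx
      if (sig_sqdt > 0 && length(ncols)) {
        x[, ncols] <- x[, ncols] +
          sig_sqdt * matrix(draw(n_osc * length(ncols)), n_osc)
      }
      if (anyNA(x) || max(abs(x)) > 1e6) {
        bad <- which(!is.finite(x) | abs(x) > 1e6, arr.ind = TRUE)
        abort_divergence(sprintf(
          "simulation diverged at step %d (t = %.6g), unit %d.",
          s, s * dt, bad[1L, 1L]))
      }
      if (ri < n_rec && s == rec_steps[ri + 1L]) {
        ri <- ri + 1L
        states[ri, , ] <<- x
      }
    }
  }
  if (is.null(noise_fun) && !is.null(config$seed)) {
    with_preserved_seed(config$seed, run())
  } else {
    run()
  }

  structure(
    list(times = rec_steps * dt, states = states,
         model_name = model$name, params = params,
         coupling_mask = model$coupling_mask,
         sigma = sigma, graph_digest = graph_digest(graph),
         config = config, transient = config$transient,
         seed = config$seed),
    class = "ensemble_traj")
}

#' Noise-free reference trajectory
#'
#' Deterministic single-unit integration (`sigma = 0`, no coupling), the
#' reference against which noisy units, population means and observers are
#' compared.
#'
#' @inheritParams euler_maruyama
#' @param x0 initial state vector of one unit.
#' @return an `ensemble_traj` with one unit.
#' @export
simulate_noise_free <- function(model, input = NULL, x0, config) {
  euler_maruyama(model, graph = NULL, noise = 0, input = input,
                 x0 = matrix(x0, nrow = 1L), config = config)
}

#' Random initial conditions
#'
#' Draws unit states uniformly from a per-component box covering the
#' noise-free attractor (with margin).  The box defaults to the model
#' preset's `ic_box`.
#'
#' @param model an [oscillator_model()] (built-in presets carry a box) or a
#'   preset name (`"fn"`, `"hr"`).
#' @param n number of units.
#' @param seed integer seed.
#' @param box optional list of `c(lo, hi)` per component.
#' @return an `n` x dim matrix.
#' @export
sample_initial_conditions <- function(model, n, seed, box = NULL) {
  name <- if (inherits(model, "oscillator_model")) model$name else model
  if (is.null(box)) {
    preset <- model_presets()[[name]]
    if (is.null(preset)) {
      abort_invalid(sprintf("no initial-condition box known for model `%s`; supply `box`.", name))
    }
    box <- preset$ic_box
  }
  with_preserved_seed(seed, {
    vapply(box, function(b) runif(n, b[[1]], b[[2]]), numeric(n))
  })
}

#' @export
print.ensemble_traj <- function(x, ...) {
  d <- dim(x$states)
  cat("<ensemble_traj> model ", x$model_name, ": ", d[2L], " unit(s) x ",
      d[3L], " component(s), ", d[1L], " time points over [0, ",
      format(max(x$times)), "], sigma = ", x$sigma, "\n", sep = "")
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.ensemble_traj <- function(x, ...) {
  d <- dim(x$states)
  tibble(
    time = rep(x$times, times = d[2L] * d[3L]),
    oscillator = rep(rep(seq_len(d[2L]), each = d[1L]), times = d[3L]),
    component = rep(seq_len(d[3L]), each = d[1L] * d[2L]),
    value = as.vector(x$states))
}

#' Plain-text trajectory serialization
#'
#' Writes `<path>.csv` (long format: time, oscillator, component, value)
#' and `<path>.json` (provenance: config, model, graph digest, sigma,
#' seed).  `read_trajectory()` reconstructs the `ensemble_traj`.
#'
#' @param traj an `ensemble_traj`.
#' @param path path prefix (no extension).
#' @return the path prefix, invisibly; `read_trajectory()` returns the
#'   trajectory.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "ensemble_traj"))
  write.csv(as_tibble(traj), paste0(path, ".csv"), row.names = FALSE)
  meta <- list(model_name = traj$model_name, params = traj$params,
               coupling_mask = traj$coupling_mask, sigma = traj$sigma,
               graph_digest = traj$graph_digest,
               config = unclass(traj$config), seed = traj$seed)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  long <- read.csv(paste0(path, ".csv"))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  times <- sort(unique(long$time))
  n_osc <- max(long$oscillator)
  n_comp <- max(long$component)
  states <- array(NA_real_, c(length(times), n_osc, n_comp))
  long <- long[order(long$component, long$oscillator, long$time), ]
  states[] <- long$value
  cfg <- meta$config
  structure(
    list(times = times, states = states, model_name = meta$model_name,
         params = as.list(meta$params),
         coupling_mask = as.logical(meta$coupling_mask),
         sigma = meta$sigma, graph_digest = meta$graph_digest,
         config = sim_config(cfg$dt, cfg$t_end, seed = cfg$seed,
                             transient = cfg$transient,
                             record_stride = cfg$record_stride),
         transient = cfg$transient, seed = meta$seed),
    class = "ensemble_traj")
}

# Extract one unit as a single-unit trajectory (shares grid + provenance).
#' Extract a single unit from an ensemble
#'
#' @param traj an `ensemble_traj`.
#' @param oscillator unit index.
#' @return an `ensemble_traj` with one unit.
#' @export
extract_oscillator <- function(traj, oscillator = 1L) {
  stopifnot(inherits(traj, "ensemble_traj"))
  d <- dim(traj$states)
  if (oscillator < 1L || oscillator > d[2L]) {
    abort_invalid("`oscillator` index out of range.")
  }
  out <- traj
  out$states <- traj$states[, oscillator, , drop = FALSE]
  out
}
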