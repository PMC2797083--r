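#' Model-based nonlinear state observer
#'
#' Integrates the observer
#' \deqn{\dot{\hat x} = f(\hat x, t) + k_e\,(v(t) - \hat v)\,e_v,}
#' a copy of the model dynamics with output injection of the measured
#' voltage \eqn{v(t)} into the voltage equation.  The injection gives the
#' observer error system the same contracting two-mode structure as a
#' coupled pair, so when the measured signal follows a noise-free
#' trajectory the observer state converges to the true state
#' exponentially, from any initial condition.  The squared distance
#' between a *noisy* unit and its observer therefore certifies how close
#' that unit is to noise-free behavior.
#'
#' The measured signal is held constant over each integration step
#' (zero-order hold on the recorded grid), so the observer integrates on
#' exactly the grid the trajectory was recorded on; record with
#' `record_stride = 1` for observer work.
#'
#' @param traj an `ensemble_traj` containing the measured unit.
#' @param model the [oscillator_model()] the observer copies.
#' @param init observer initial state (defaults to the zero vector).
#' @param oscillator which unit of `traj` is measured.
#' @param gains named list; `ke` is the positive injection gain.
#' @param input the same common input signal the network received
#'   (`NULL`, constant, or function of time).
#' @return an `observer_run`: `observer` (tibble: time, one column per
#'   component), `distance_sq` (tibble: time, squared distance between
#'   observer and the measured unit's full state), `init`, `gains`.
#' @export
run_observer <- function(traj, model, init = NULL, oscillator = 1L,
                         gains = list(ke = 30), input = NULL) {
  stopifnot(inherits(traj, "ensemble_traj"), inherits(model, "oscillator_model"))
  ke <- gains$ke %||% 30
  check_number(ke, "ke", min = 0, strict_min = TRUE)
  d <- dim(traj$states)
  if (oscillator < 1L || oscillator > d[2L]) {
    abort_invalid("`oscillator` index out of range.")
  }
  measured <- matrix(traj$states[, oscillator, ], nrow = d[1L])
  times <- traj$times
  steps <- diff(times)
  if (length(steps) < 1L ||
      max(abs(steps - steps[1L])) > 1e-9 * max(steps)) {
    abort_invalid("measured trajectory must be on a uniform time grid.")
  }
  dt <- steps[1L]
  input_fun <-
    if (is.null(input)) function(t) 0
    else if (is.function(input)) input
    else local({v <- input; function(t) v})

  vcol <- which(model$coupling_mask)
  vcol <- if (length(vcol)) vcol[1L] else 1L
  init <- init %||% numeric(model$state_dim)
  if (length(init) != model$state_dim || !all(is.finite(init))) {
    abort_invalid("`init` must be a finite state vector.")
  }

  xhat <- matrix(NA_real_, d[1L], model$state_dim)
  xhat[1L, ] <- init
  x <- init
  for (s in seq_len(d[1L] - 1L)) {
    t <- times[s]
    dx <- drop(model$drift(matrix(x, 1L), t, input_fun(t), model$params))
    dx[vcol] <- dx[vcol] + ke * (measured[s, vcol] - x[vcol])
    x <- x + dt * dx
    if (anyNA(x) || max(abs(x)) > 1e6) {
      abort_divergence(sprintf("observer diverged at step %d (t = %.6g).",
                               s, times[s + 1L]))
    }
    xhat[s + 1L, ] <- x
  }
  dist_sq <- rowSums((xhat - measured)^2)
  structure(
    list(observer = dplyr::bind_cols(
           tibble(time = times),
           as_tibble(setNames(as.data.frame(xhat),
                              paste0("c", seq_len(model$state_dim))))),
         distance_sq = tibble(time = times, distance_sq = dist_sq),
         init = init, gains = list(ke = ke), dt = dt),
    class = "observer_run")
}

#' @export
print.observer_run <- function(x, ...) {
  cat("<observer_run> ", nrow(x$observer), " steps, ke = ", x$gains$ke,
      ", final squared distance ", format(tail(x$distance_sq$distance_sq, 1L)),
      "\n", sep = "")
  invisible(x)
}

#' Ergodic observer-distance statistic
#'
#' Time average, after the transient, of the squared distance between the
#' observer and the measured unit: small values certify that the unit
#' behaves like a noise-free oscillator.  For a synchronized unit in a
#' strongly coupled network this statistic is far smaller than for an
#' uncoupled unit at the same noise intensity.
#'
#' @param run an `observer_run`.
#' @param transient nonnegative time discarded before averaging; must be
#'   shorter than the run.
#' @return nonnegative scalar.
#' @export
observer_distance_stat <- function(run, transient = 0) {
  stopifnot(inherits(run, "observer_run"))
  keep <- post_transient_index(run$distance_sq$time, transient)
  mean(run$distance_sq$distance_sq[keep])
}
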