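#' Oscillator model objects
#'
#' An `oscillator_model` bundles the drift field of a single unit together
#' with its differential structure: which state components receive intrinsic
#' noise, which are diffusively coupled to the rest of the network, which
#' receive the common external input, and (when available) a closed-form
#' bound on the curvature (Hessian) of the drift.  The built-in constructors
#' [fn_model()], [hr_model()] and [linear_model()] cover the reduced neuron
#' models and the time-varying linear systems used throughout the package;
#' [oscillator_model()] accepts an arbitrary user-supplied drift.
#'
#' @param name identifier for the model.
#' @param state_dim number of state components of one unit.
#' @param drift function `(states, t, input, params) -> matrix` evaluating the
#'   uncoupled drift for a whole ensemble at once: `states` is an
#'   N x `state_dim` matrix (one row per unit) and the return value has the
#'   same shape.  The common input (a scalar) must be added by the drift to
#'   the components flagged by `input_mask`.
#' @param params named list of model parameters.
#' @param noise_mask,coupling_mask,input_mask logical vectors of length
#'   `state_dim`: which components receive additive intrinsic noise, which
#'   enter the diffusive coupling, and which receive the common input.  The
#'   defaults put all three on the first ("membrane potential") component,
#'   the gap-junction convention.
#' @param hessian_sup optional function `(radius, params) -> Q` returning an
#'   upper bound on the largest absolute Hessian eigenvalue of every drift
#'   component over the ball of the given radius; used by [hessian_bound()].
#'   When absent a finite-difference fallback is used.
#'
#' @return an object of class `oscillator_model`.
#' @seealso [fn_drift()], [hr_drift()], [linear_drift()], [hessian_bound()]
#' @export
oscillator_model <- function(name, state_dim, drift, params = list(),
                             noise_mask = NULL, coupling_mask = NULL,
                             input_mask = NULL, hessian_sup = NULL) {
  if (!is.function(drift)) abort_invalid("`drift` must be a function.")
  state_dim <- as.integer(state_dim)
  if (is.na(state_dim) || state_dim < 1L) {
    abort_invalid("`state_dim` must be a positive integer.")
  }
  default_mask <- c(TRUE, rep(FALSE, state_dim - 1L))
  noise_mask <- noise_mask %||% default_mask
  coupling_mask <- coupling_mask %||% default_mask
  input_mask <- input_mask %||% default_mask
  for (m in list(noise_mask, coupling_mask, input_mask)) {
    if (!is.logical(m) || length(m) != state_dim) {
      abort_invalid("masks must be logical vectors of length `state_dim`.")
    }
  }
  structure(
    list(name = name, state_dim = state_dim, drift = drift, params = params,
         noise_mask = noise_mask, coupling_mask = coupling_mask,
         input_mask = input_mask, hessian_sup = hessian_sup),
    class = "oscillator_model")
}

#' @export
print.oscillator_model <- function(x, ...) {
  cat("<oscillator_model> ", x$name, " (dim ", x$state_dim, ")\n", sep = "")
  if (length(x$params)) {
    cat("  params: ",
        paste(names(x$params), unlist(x$params), sep = " = ", collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

preset_cache <- new.env(parent = emptyenv())

#' Built-in model presets
#'
#' Model parameter values, masks, default noise intensity and initial
#' condition boxes live in a single YAML file shipped with the package
#' (`inst/extdata/model_presets.yaml`), so every experiment can be re-run
#' against one source of truth and amended values propagate everywhere.
#'
#' @param path path to a presets YAML file; defaults to the shipped one.
#' @return a named list of presets (`fn`, `hr`).
#' @export
model_presets <- function(path = NULL) {
  if (is.null(path)) {
    if (is.null(preset_cache$presets)) {
      path <- system.file("extdata", "model_presets.yaml", package = "oscnet")
      preset_cache$presets <- yaml::read_yaml(path)
    }
    return(preset_cache$presets)
  }
  yaml::read_yaml(path)
}

#' @rdname model_presets
#' @export
fn_params <- function() model_presets()$fn$params

#' @rdname model_presets
#' @export
hr_params <- function() model_presets()$hr$params

check_params <- function(params, required, model) {
  missing <- setdiff(required, names(params))
  if (length(missing)) {
    abort_invalid(sprintf("%s drift is missing parameter(s): %s",
                          model, paste(missing, collapse = ", ")))
  }
  bad <- required[!vapply(params[required],
                          function(p) is.numeric(p) && is.finite(p), TRUE)]
  if (length(bad)) {
    abort_invalid(sprintf("%s parameter `%s` must be a finite number.",
                          model, bad[[1L]]))
  }
  invisible(params)
}

check_state <- function(state, dim, model) {
  if (!is.numeric(state) || length(state) != dim || !all(is.finite(state))) {
    abort_invalid(sprintf("`state` for %s must be a finite %d-vector.",
                          model, dim))
  }
  invisible(state)
}

fn_drift_matrix <- function(states, t, input, params) {
  v <- states[, 1L]
  w <- states[, 2L]
  cc <- params$c
  cbind(cc * (v + w - v^3 / 3) + input,
        -(v - params$a + params$b * w) / cc)
}

hr_drift_matrix <- function(states, t, input, params) {
  x <- states[, 1L]
  y <- states[, 2L]
  z <- states[, 3L]
  cbind(y - params$a * x^3 + params$b * x^2 - z + input,
        params$c - params$d * x^2 - y,
        params$r * (params$s * (x - params$x_r) - z))
}

#' FitzHugh-Nagumo drift
#'
#' Right-hand side of one uncoupled FitzHugh-Nagumo oscillator in the
#' classical (FitzHugh) parameterization,
#' \deqn{\dot v = c\,(v + w - v^3/3) + I(t), \qquad
#'       \dot w = -(v - a + b\,w)/c,}
#' where \eqn{v} is the membrane-potential-like fast variable, \eqn{w} the
#' recovery variable and \eqn{I(t)} the common external input (entering the
#' voltage equation only).  With the shipped preset (`a = 0.3`, `b = 0.8`,
#' `c = 3`) the unit has a stable limit cycle at zero input.
#'
#' @param state numeric 2-vector `(v, w)`.
#' @param t time (the drift is autonomous; kept for interface uniformity).
#' @param input scalar external input.
#' @param params named list with entries `a`, `b`, `c`.
#' @return numeric 2-vector, the instantaneous derivative.
#' @export
fn_drift <- function(state, t = 0, input = 0, params = fn_params()) {
  check_params(params, c("a", "b", "c"), "FitzHugh-Nagumo")
  check_state(state, 2L, "FitzHugh-Nagumo")
  drop(fn_drift_matrix(matrix(state, 1L), t, input, params))
}

#' Hindmarsh-Rose drift
#'
#' Right-hand side of one uncoupled three-dimensional Hindmarsh-Rose
#' neuron,
#' \deqn{\dot x = y - a x^3 + b x^2 - z + I(t), \quad
#'       \dot y = c - d x^2 - y, \quad
#'       \dot z = r\,(s\,(x - x_r) - z),}
#' with membrane potential \eqn{x}, fast recovery \eqn{y} and slow
#' adaptation \eqn{z}.  The common input \eqn{I(t)} enters the first
#' equation and may be time-varying, provided it is identical for all units
#' of a network.
#'
#' @param state numeric 3-vector `(x, y, z)`.
#' @param t time.
#' @param input scalar external input (possibly evaluated from a
#'   time-varying signal).
#' @param params named list with entries `a`, `b`, `c`, `d`, `r`, `s`, `x_r`.
#' @return numeric 3-vector.
#' @export
hr_drift <- function(state, t = 0, input = 0, params = hr_params()) {
  check_params(params, c("a", "b", "c", "d", "r", "s", "x_r"), "Hindmarsh-Rose")
  check_state(state, 3L, "Hindmarsh-Rose")
  drop(hr_drift_matrix(matrix(state, 1L), t, input, params))
}

#' Time-varying linear drift
#'
#' Evaluates \eqn{A(t)\,x + b(t)}.  `A` and `b` may be constants or
#' functions of time; scalars are promoted, so `linear_drift(x, t, A = -a)`
#' is the Ornstein-Uhlenbeck drift \eqn{-a x}.
#'
#' @param state numeric n-vector.
#' @param t time.
#' @param A n x n matrix (or scalar, or a function of `t` returning one).
#' @param b n-vector (or scalar, or function of `t`); defaults to zero.
#' @return numeric n-vector.
#' @export
linear_drift <- function(state, t = 0, A, b = NULL) {
  At <- if (is.function(A)) A(t) else A
  bt <- if (is.function(b)) b(t) else b %||% 0
  n <- length(state)
  if (length(At) == 1L) At <- diag(as.numeric(At), n)
  At <- as.matrix(At)
  if (!all(dim(At) == c(n, n)) || !all(is.finite(At))) {
    abort_invalid("`A(t)` must be a finite matrix matching the state dimension.")
  }
  if (length(bt) == 1L) bt <- rep(as.numeric(bt), n)
  if (length(bt) != n) abort_invalid("`b(t)` must match the state dimension.")
  drop(At %*% state + bt)
}

#' @param sigma_default unused; see Description.
#' @describeIn oscillator_model FitzHugh-Nagumo model from the shipped preset.
#' @export
fn_model <- function(params = fn_params()) {
  check_params(params, c("a", "b", "c"), "FitzHugh-Nagumo")
  p <- model_presets()$fn
  oscillator_model(
    name = "fn", state_dim = 2L, drift = fn_drift_matrix, params = params,
    noise_mask = as.logical(p$noise_mask),
    coupling_mask = as.logical(p$coupling_mask),
    input_mask = as.logical(p$input_mask),
    hessian_sup = function(radius, params) 2 * params$c * radius)
}

#' @describeIn oscillator_model Hindmarsh-Rose model from the shipped preset.
#' @export
hr_model <- function(params = hr_params()) {
  check_params(params, c("a", "b", "c", "d", "r", "s", "x_r"), "Hindmarsh-Rose")
  p <- model_presets()$hr
  oscillator_model(
    name = "hr", state_dim = 3L, drift = hr_drift_matrix, params = params,
    noise_mask = as.logical(p$noise_mask),
    coupling_mask = as.logical(p$coupling_mask),
    input_mask = as.logical(p$input_mask),
    hessian_sup = function(radius, params) {
      # x-eq: |d2/dx2 (-a x^3 + b x^2)| = |6 a x - 2 b| <= 6|a| r + 2|b|
      # y-eq: |d2/dx2 (-d x^2)| = 2|d|; z-eq linear.
      max(6 * abs(params$a) * radius + 2 * abs(params$b), 2 * abs(params$d))
    })
}

#' @param A,b system matrix and offset for [linear_model()]; constants or
#'   functions of time.
#' @param state_dim state dimension for [linear_model()].
#' @describeIn oscillator_model time-varying linear model \eqn{A(t)x + b(t)};
#'   its Hessian bound is exactly zero.
#' @export
linear_model <- function(A, b = NULL, state_dim = NULL) {
  if (is.null(state_dim)) {
    A0 <- if (is.function(A)) A(0) else A
    state_dim <- if (length(A0) == 1L) 1L else nrow(as.matrix(A0))
  }
  drift <- function(states, t, input, params) {
    At <- if (is.function(A)) A(t) else A
    bt <- if (is.function(b)) b(t) else b %||% 0
    n <- ncol(states)
    if (length(At) == 1L) At <- diag(as.numeric(At), n)
    out <- states %*% t(as.matrix(At))
    out <- sweep(out, 2L, rep_len(as.numeric(bt), n), "+")
    out[, 1L] <- out[, 1L] + input
    out
  }
  oscillator_model(
    name = "linear", state_dim = state_dim, drift = drift,
    params = list(),
    noise_mask = rep(TRUE, state_dim),
    coupling_mask = rep(TRUE, state_dim),
    input_mask = c(TRUE, rep(FALSE, state_dim - 1L)),
    hessian_sup = function(radius, params) 0)
}

#' Intrinsic noise specification
#'
#' Intrinsic noise is additive white noise of constant intensity `sigma`,
#' independent across units (and across the noise-masked components of one
#' unit).  The intensity does not depend on the inputs, matching the notion
#' of noise intrinsic to each dynamical element.
#'
#' @param sigma nonnegative noise intensity.
#' @return an object of class `noise_spec`.
#' @export
noise_spec <- function(sigma = 0) {
  check_number(sigma, "sigma", min = 0)
  structure(list(sigma = sigma, per_oscillator_independent = TRUE),
            class = "noise_spec")
}

as_sigma <- function(noise) {
  if (inherits(noise, "noise_spec")) return(noise$sigma)
  check_number(noise, "sigma", min = 0)
  noise
}

#' Curvature (Hessian) bound of a drift field
#'
#' Returns a constant `Q` bounding, over the ball of the given radius, the
#' largest absolute eigenvalue of the Hessian of every component of the
#' model's drift.  `Q` quantifies how nonlinear the dynamics are: a linear
#' system has `Q = 0` exactly, while for FitzHugh-Nagumo the cubic voltage
#' term gives `Q = 2 c R` over \eqn{|v| \le R}.  `Q` feeds the
#' Taylor-remainder bound of [taylor_mismatch()] and the mean-impact bound
#' of [mean_impact_bound()].
#'
#' @param model an [oscillator_model()].
#' @param radius nonnegative radius of the operating region (typically from
#'   [trajectory_radius()]).
#' @return nonnegative scalar `Q`.
#' @export
hessian_bound <- function(model, radius) {
  if (!inherits(model, "oscillator_model")) {
    abort_invalid("`model` must be an oscillator_model.")
  }
  check_number(radius, "radius", min = 0)
  if (!is.null(model$hessian_sup)) {
    return(model$hessian_sup(radius, model$params))
  }
  if (model$state_dim > 3L) {
    abort("finite-difference Hessian fallback supports state_dim <= 3 only",
          class = c("oscnet_unsupported_model", "oscnet_error"))
  }
  numeric_hessian_sup(model, radius)
}

# Grid-search fallback: largest |Hessian eigenvalue| of each drift component
# over a grid in the radius ball, central differences with step 1e-6*(1+|x|).
numeric_hessian_sup <- function(model, radius, n_grid = 9L) {
  d <- model$state_dim
  axes <- replicate(d, seq(-radius, radius, length.out = n_grid),
                    simplify = FALSE)
  grid <- as.matrix(expand.grid(axes))
  f1 <- function(x) drop(model$drift(matrix(x, 1L), 0, 0, model$params))
  q <- 0
  for (g in seq_len(nrow(grid))) {
    x <- grid[g, ]
    if (sqrt(sum(x^2)) > radius + 1e-12) next
    h <- 1e-6 * (1 + abs(x))
    for (m in seq_len(d)) {
      H <- matrix(0, d, d)
      for (i in seq_len(d)) {
        for (j in i:d) {
          ei <- ej <- numeric(d)
          ei[i] <- h[i]; ej[j] <- h[j]
          H[i, j] <- H[j, i] <-
            (f1(x + ei + ej)[m] - f1(x + ei - ej)[m] -
               f1(x - ei + ej)[m] + f1(x - ei - ej)[m]) / (4 * h[i] * h[j])
        }
      }
      q <- max(q, max(abs(eigen(H, symmetric = TRUE,
                                only.values = TRUE)$values)))
    }
  }
  q
}

#' Radius of a simulated trajectory
#'
#' Maximum absolute value, over time and units, of the coupled state
#' component(s) of an ensemble trajectory.  Instantiates the operating
#' region over which [hessian_bound()] bounds the drift curvature: limit
#' cycle oscillators stay within a common bounded region, and this function
#' measures it from the simulation itself.
#'
#' @param traj an `ensemble_traj` from [euler_maruyama()].
#' @param components which state components to scan; defaults to the
#'   coupling-masked ones recorded in the trajectory's provenance, falling
#'   back to all components.
#' @return nonnegative scalar radius.
#' @export
trajectory_radius <- function(traj, components = NULL) {
  if (!inherits(traj, "ensemble_traj") || length(traj$times) == 0L) {
    abort_invalid("`traj` must be a non-empty ensemble_traj.")
  }
  components <- components %||% which(traj$coupling_mask) %||%
    seq_len(dim(traj$states)[3L])
  if (length(components) == 0L) components <- seq_len(dim(traj$states)[3L])
  max(abs(traj$states[, , components, drop = FALSE]))
}
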