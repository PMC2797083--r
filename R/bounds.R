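#' Bound reports
#'
#' All theoretical quantities are returned as `bound_report` objects:
#' the bound value, the exponential transient rate after which it applies,
#' the inputs that produced it, and auxiliary derived quantities
#' (`details`).  Use [tidy()] / [glance()] to get tibbles.
#'
#' @param kind one of `"A4_all_to_all"`, `"pair"`, `"mean_impact"`,
#'   `"taylor"`, `"observer"`.
#' @param bound_value nonnegative bound.
#' @param transient_rate positive exponential rate (NA when not applicable).
#' @param inputs named list of the parameters that produced the bound.
#' @param details named list of auxiliary quantities.
#' @return an object of class `bound_report`.
#' @keywords internal
bound_report <- function(kind, bound_value, transient_rate = NA_real_,
                         inputs = list(), details = list()) {
  structure(list(kind = kind, bound_value = bound_value,
                 transient_rate = transient_rate, inputs = inputs,
                 details = details),
            class = "bound_report")
}

#' @export
print.bound_report <- function(x, ...) {
  cat("<bound_report> ", x$kind, ": ", format(x$bound_value), sep = "")
  if (is.finite(x$transient_rate)) {
    cat("  (after transients of rate ", format(x$transient_rate), ")",
        sep = "")
  }
  cat("\n")
  scalars <- purrr::keep(x$inputs, ~ is.numeric(.x) && length(.x) == 1L)
  if (length(scalars)) {
    cat("  inputs: ",
        paste(names(scalars), vapply(scalars, format, ""),
              sep = " = ", collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

fn_param_scale <- function(params) max(params$c, 1 / params$c,
                                       params$b / params$c)

warn_weak_coupling <- function(kappa, params) {
  if (kappa < 10 * fn_param_scale(params)) {
    warn(sprintf(
      "effective coupling %.3g is below 10x the largest system parameter scale (%.3g); the large-coupling bound derivation may not apply.",
      kappa, fn_param_scale(params)),
      class = "oscnet_weak_coupling")
  }
}

# Expected squared pair distance E[(v_i-v_j)^2 + (w_i-w_j)^2] under total
# diffusive damping `kappa` on the voltage difference, from the two-mode
# stochastic-contraction analysis (see the methods vignette):
#   fast voltage mode: rate >= kappa - c, driven at intensity sigma*sqrt(2)
#   slow recovery mode: rate b/c, driven through the mode mixing at
#     intensity sigma*sqrt(2)/(c*kappa)
# each mode contributing (intensity^2) / (2 * rate).
pair_sq_expectation_bound <- function(kappa, sigma, params) {
  if (sigma == 0) return(0)
  if (kappa <= params$c) return(Inf)
  sigma^2 * (1 / (kappa - params$c) +
               1 / (params$b * params$c * kappa^2))
}

#' Synchronization bound for an all-to-all FitzHugh-Nagumo network
#'
#' Theoretical bound `C` on the stationary sum over ordered pairs of
#' expected squared state distances, \eqn{\sum_{i,j} E\|x_i - x_j\|^2 \le
#' C}, for `n` FitzHugh-Nagumo units all-to-all coupled at strength `k`
#' under intrinsic noise `sigma`.  Each pairwise difference feels total
#' voltage damping \eqn{\kappa = n k}; the two-mode contraction analysis
#' gives
#' \deqn{C = n (n - 1)\,\sigma^2 \left[\frac{1}{n k - c} +
#'   \frac{1}{b\,c\,(n k)^2}\right],}
#' which is zero for `sigma = 0` (noise-free networks synchronize
#' completely), strictly decreasing in `k`, proportional to
#' \eqn{\sigma^2}, and for large `k` behaves as \eqn{(n-1)\sigma^2/k},
#' converging to 0 as \eqn{k \to \infty}.  The derivation assumes the
#' coupling dominates the system parameters; a warning is raised when
#' \eqn{n k} is less than ten times the largest parameter scale.
#'
#' @param n number of units (>= 2).
#' @param k positive per-connection coupling strength.
#' @param sigma nonnegative noise intensity.
#' @param params FitzHugh-Nagumo parameters (`a`, `b`, `c`).
#' @return a `bound_report` of kind `"A4_all_to_all"`; `details` carries
#'   the large-`k` asymptote, the distance-to-center forms
#'   (`sum_sq_to_com_bound` \eqn{= C/(2n)} and `avg_sq_to_com_bound`
#'   \eqn{= C/(2n^2)}, the quantity plotted in coupling sweeps).
#' @export
sync_bound_all_to_all <- function(n, k, sigma, params = fn_params()) {
  n <- as.integer(n)
  if (is.na(n) || n < 2L) abort_invalid("`n` must be an integer >= 2.")
  check_number(k, "k", min = 0, strict_min = TRUE)
  check_number(sigma, "sigma", min = 0)
  check_params(params, c("a", "b", "c"), "FitzHugh-Nagumo")
  kappa <- n * k
  warn_weak_coupling(kappa, params)
  per_pair <- pair_sq_expectation_bound(kappa, sigma, params)
  C <- n * (n - 1) * per_pair
  bound_report(
    "A4_all_to_all", C,
    transient_rate = min(kappa - params$c, params$b / params$c),
    inputs = list(n = n, k = k, sigma = sigma, params = params),
    details = list(
      per_pair = per_pair,
      asymptotic = (n - 1) * sigma^2 / k,
      sum_sq_to_com_bound = C / (2 * n),
      avg_sq_to_com_bound = C / (2 * n^2)))
}

#' Two-oscillator synchronization bound
#'
#' Bound on \eqn{E[\|x_1 - x_2\|^2]} for two mutually coupled noisy
#' FitzHugh-Nagumo units (total voltage damping \eqn{2k}), the building
#' block of the general all-to-all bound: in an `n`-unit all-to-all
#' network each pairwise difference is uncoupled from every other pair, so
#' summing the pair bound (at damping \eqn{n k}) over the `n (n - 1)`
#' ordered pairs reproduces [sync_bound_all_to_all()].
#'
#' @inheritParams sync_bound_all_to_all
#' @return a `bound_report` of kind `"pair"`.
#' @export
pair_bound <- function(k, sigma, params = fn_params()) {
  check_number(k, "k", min = 0, strict_min = TRUE)
  check_number(sigma, "sigma", min = 0)
  check_params(params, c("a", "b", "c"), "FitzHugh-Nagumo")
  kappa <- 2 * k
  warn_weak_coupling(kappa, params)
  bound_report(
    "pair", pair_sq_expectation_bound(kappa, sigma, params),
    transient_rate = min(kappa - params$c, params$b / params$c),
    inputs = list(k = k, sigma = sigma, params = params))
}

pair_evolution_matrix <- function(params, kappa, alpha = 0) {
  cc <- params$c
  matrix(c(cc * (1 - alpha) - kappa, -1 / cc,
           cc, -params$b / cc), 2L)
}

#' Eigenmodes of the pairwise difference system
#'
#' Eigen-decomposition of the evolution matrix of the voltage/recovery
#' difference of a coupled pair,
#' \eqn{\dot V = [c(1-\alpha) - \kappa] V + c W}, \eqn{\dot W = -V/c - bW/c},
#' where \eqn{\alpha(t) = (v_1^2 + v_1 v_2 + v_2^2)/3 \ge 0} collects the
#' cubic nonlinearity and \eqn{\kappa = n k} is the total diffusive
#' damping.  In the strong-coupling regime the modes split into a fast
#' voltage mode (rate \eqn{\approx \kappa}) and a slow recovery mode (rate
#' \eqn{\approx b/c}).
#'
#' @param params FitzHugh-Nagumo parameters.
#' @param k per-connection coupling strength.
#' @param n network size the pair is embedded in (default 2).
#' @param alpha nonnegative cubic term value (default 0, the worst case for
#'   contraction).
#' @return list with `values`, `vectors` (columns), and the matrix `M`.
#' @export
pair_modes <- function(params = fn_params(), k, n = 2L, alpha = 0) {
  check_number(k, "k", min = 0, strict_min = TRUE)
  check_number(alpha, "alpha", min = 0)
  M <- pair_evolution_matrix(params, n * k, alpha)
  e <- eigen(M)
  list(values = e$values, vectors = e$vectors, M = M)
}

eigenmode_matrix <- function(params, kappa) {
  cc <- params$c
  matrix(c(1, 1 / (cc * kappa), cc / kappa, 1), 2L)
}

#' Eigenmode change of variables for a coupled pair
#'
#' Maps a pair of unit states to the (approximately) decoupled coordinates
#' of the strong-coupling regime: the mean coordinates and the two
#' difference modes \eqn{y_1 = V - (c/\kappa) W} (fast) and
#' \eqn{y_2 = W - V/(c \kappa)} (slow), with \eqn{V, W} the voltage and
#' recovery differences and \eqn{\kappa = 2k}.  In these coordinates the
#' difference dynamics decouple to leading order and each mode can be
#' bounded independently.  The transform is invertible away from
#' \eqn{\kappa = 1} (round trip exact to machine precision) and identical
#' pair states map to zero difference modes.
#'
#' @param pair_states 2 x dim matrix: rows are the two unit states
#'   `(v, w)`.
#' @param params FitzHugh-Nagumo parameters.
#' @param k positive coupling strength.
#' @return an `eigenmode_coords` object: `y` (the two difference-mode
#'   coordinates), `mean` (the pair mean state), `P` (mode matrix such that
#'   `(V, W) = P %*% y`).
#' @export
eigenmode_transform <- function(pair_states, params = fn_params(), k) {
  pair_states <- as.matrix(pair_states)
  if (!all(dim(pair_states) == c(2L, 2L))) {
    abort_invalid("`pair_states` must be a 2 x 2 matrix (two units, two components).")
  }
  check_number(k, "k", min = 0, strict_min = TRUE)
  kappa <- 2 * k
  P <- eigenmode_matrix(params, kappa)
  if (abs(det(P)) < 1e-8) {
    abort("eigenmode transform is singular at this coupling strength (outside the strong-coupling validity regime).",
          class = c("oscnet_degenerate_transform", "oscnet_error"))
  }
  diffs <- pair_states[1L, ] - pair_states[2L, ]
  structure(
    list(y = drop(solve(P, diffs)), mean = colMeans(pair_states),
         P = P, params = params, k = k),
    class = "eigenmode_coords")
}

#' @param coords an `eigenmode_coords` object.
#' @rdname eigenmode_transform
#' @return `eigenmode_inverse()` returns the reconstructed 2 x 2 state
#'   matrix.
#' @export
eigenmode_inverse <- function(coords) {
  stopifnot(inherits(coords, "eigenmode_coords"))
  diffs <- drop(coords$P %*% coords$y)
  rbind(coords$mean + diffs / 2, coords$mean - diffs / 2)
}

#' Taylor-remainder mismatch of the mean drift
#'
#' The population mean does not follow the noise-free dynamics exactly:
#' averaging the drift over units differs from the drift at the center of
#' mass by a Taylor remainder controlled by the curvature bound `Q`.  This
#' function evaluates both sides of that inequality on a snapshot:
#' `mismatch` \eqn{= \|\frac1N \sum_i f(x_i) - f(\bar x)\|} and `bound`
#' \eqn{= (Q/2) \cdot \frac1N \sum_i \|x_i - \bar x\|^2}.  The guarantee
#' `mismatch <= bound` holds whenever all states lie inside the region
#' over which `Q` bounds the Hessian; a state outside it raises a
#' precondition error.  For a linear model (`Q = 0`) the mismatch is
#' identically zero: linear components of the dynamics, inputs included,
#' do not distort the population mean.
#'
#' @param model an [oscillator_model()].
#' @param states N x dim state matrix.
#' @param Q curvature bound from [hessian_bound()] at a radius covering
#'   the states.
#' @return one-row tibble with `mismatch` and `bound`.
#' @export
taylor_mismatch <- function(model, states, Q) {
  stopifnot(inherits(model, "oscillator_model"))
  states <- as.matrix(states)
  check_number(Q, "Q", min = 0)
  radius <- max(abs(states[, model$coupling_mask, drop = FALSE]))
  if (hessian_bound(model, radius) > Q * (1 + 1e-9) + 1e-12) {
    abort(sprintf(
      "states reach radius %.4g where the curvature exceeds Q = %.4g; recompute Q with hessian_bound() at that radius.",
      radius, Q),
      class = c("oscnet_precondition", "oscnet_error"))
  }
  xbar <- colMeans(states)
  f_mean <- colMeans(model$drift(states, 0, 0, model$params))
  f_at_mean <- drop(model$drift(matrix(xbar, 1L), 0, 0, model$params))
  msd <- mean(rowSums(sweep(states, 2L, xbar)^2))
  tibble(mismatch = sqrt(sum((f_mean - f_at_mean)^2)),
         bound = Q / 2 * msd)
}

#' Bound on the impact of noise on the mean trajectory
#'
#' Combines the two ways noise reaches the population mean: the nonlinear
#' distortion term \eqn{Q C / (4 n^2)} (the Taylor remainder fed by the
#' synchronization error `C`) and the averaged-noise term
#' \eqn{\sigma / \sqrt{n}} (the `n` intrinsic noises are mutually
#' independent, so their average has intensity \eqn{\sigma/\sqrt n}).
#' With `Q = 0` (linear dynamics) only the inverse-square-root-of-`n` term
#' remains -- the classical averaging law -- and the whole bound tends to
#' zero as \eqn{n \to \infty} with \eqn{C \to 0}: synchronization plus
#' averaging cancels the impact of noise on the mean.
#'
#' @param Q nonnegative curvature bound ([hessian_bound()]).
#' @param C nonnegative synchronization error constant, either theoretical
#'   ([sync_bound_all_to_all()]) or an ergodic estimate ([sync_error()],
#'   `"sum"` convention); `details$C_source` records which.
#' @param sigma nonnegative noise intensity.
#' @param n number of units (>= 1).
#' @param C_source `"theoretical"` or `"empirical"`.
#' @return a `bound_report` of kind `"mean_impact"`.
#' @export
mean_impact_bound <- function(Q, C, sigma, n, C_source = "theoretical") {
  check_number(Q, "Q", min = 0)
  check_number(C, "C", min = 0)
  check_number(sigma, "sigma", min = 0)
  n <- as.integer(n)
  if (is.na(n) || n < 1L) abort_invalid("`n` must be a positive integer.")
  nonlinear <- Q * C / (4 * n^2)
  noise <- sigma / sqrt(n)
  bound_report(
    "mean_impact", nonlinear + noise,
    inputs = list(Q = Q, C = C, sigma = sigma, n = n),
    details = list(nonlinear_term = nonlinear, noise_term = noise,
                   C_source = C_source))
}

#' Observer-distance bound for a synchronized oscillator
#'
#' Assembles, via the squared triangle inequality through the population
#' mean, a bound on the expected squared distance between a noisy
#' synchronized unit and its converged observer: the per-unit share of the
#' synchronization error (\eqn{C/n^2}) plus the slow-mode response of the
#' mean to the averaged noise (\eqn{c \sigma^2 / (b n)}, intensity
#' \eqn{\sigma/\sqrt n} against contraction rate \eqn{b/c}).  Decreases
#' with both `k` (through `C`) and `n`.
#'
#' @inheritParams sync_bound_all_to_all
#' @param ke observer gain (recorded in the report inputs).
#' @return a `bound_report` of kind `"observer"`.
#' @export
observer_bound <- function(n, k, sigma, params = fn_params(), ke = NA_real_) {
  C <- sync_bound_all_to_all(n, k, sigma, params)$bound_value
  bound_report(
    "observer", C / n^2 + params$c * sigma^2 / (params$b * n),
    transient_rate = params$b / params$c,
    inputs = list(n = n, k = k, sigma = sigma, ke = ke, params = params),
    details = list(sync_term = C / n^2,
                   mean_noise_term = params$c * sigma^2 / (params$b * n)))
}
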