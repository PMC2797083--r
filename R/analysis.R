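#' Center of mass of an ensemble
#'
#' Arithmetic mean over units, per component and per time point: the
#' "population" trajectory whose dynamics the synchronization analysis
#' bounds.
#'
#' @param x an `ensemble_traj`, or an N x dim state matrix.
#' @return for a trajectory, a tibble with `time` and one `c<j>` column per
#'   component; for a matrix, the mean state vector.
#' @export
center_of_mass <- function(x) {
  if (inherits(x, "ensemble_traj")) {
    d <- dim(x$states)
    if (d[2L] < 1L) abort_invalid("empty ensemble.")
    com <- apply(x$states, c(1L, 3L), mean)
    com <- matrix(com, nrow = d[1L])
    out <- as_tibble(setNames(as.data.frame(com),
                              paste0("c", seq_len(d[3L]))))
    return(dplyr::bind_cols(tibble(time = x$times), out))
  }
  x <- as.matrix(x)
  if (nrow(x) < 1L) abort_invalid("empty ensemble.")
  colMeans(x)
}

post_transient_index <- function(times, transient) {
  check_number(transient, "transient", min = 0)
  if (transient >= max(times)) {
    abort_invalid("`transient` must be shorter than the trajectory.")
  }
  which(times >= transient)
}

#' Synchronization error (ergodic estimate)
#'
#' The synchronization error is the expected sum over ordered pairs of
#' squared distances between unit states,
#' \eqn{\sum_{i,j} E\|x_i - x_j\|^2}, estimated as a time average over the
#' post-transient window (the ergodic hypothesis: one long run stands in
#' for the ensemble expectation).  The pairwise sum is algebraically
#' identical to \eqn{2N \sum_i \|x_i - \bar x\|^2}, the distance-to-center
#' form; both are computed independently and the identity is asserted to
#' `1e-12` relative at every recorded time.
#'
#' @param traj an `ensemble_traj`.
#' @param transient time discarded before averaging; defaults to the
#'   trajectory's flagged transient.
#' @param convention `"sum"` (sum over ordered pairs, the default) or
#'   `"average"` (divide by `N (N - 1)`).
#' @return a `sync_stats` object: `sync_error` (scalar ergodic estimate),
#'   `series` (tibble: time, pairwise squared-distance quantity),
#'   `center_of_mass` (tibble), `window`, `convention`, `n_osc`.
#' @export
sync_error <- function(traj, transient = NULL, convention = c("sum", "average")) {
  stopifnot(inherits(traj, "ensemble_traj"))
  convention <- match.arg(convention)
  transient <- transient %||% traj$transient %||% 0
  keep <- post_transient_index(traj$times, transient)
  d <- dim(traj$states)
  n <- d[2L]

  pair_sum <- numeric(d[1L])
  com_sum <- numeric(d[1L])
  for (ti in seq_len(d[1L])) {
    X <- matrix(traj$states[ti, , ], nrow = n)
    sq <- rowSums(X^2)
    # full ordered-pair sum of squared distances
    pair_sum[ti] <- sum(outer(sq, sq, "+") - 2 * tcrossprod(X))
    com_sum[ti] <- sum(sweep(X, 2L, colMeans(X))^2)
  }
  pair_sum <- pmax(pair_sum, 0)
  scale_ref <- pmax(pair_sum, 1e-300)
  if (n > 1L && any(abs(pair_sum - 2 * n * com_sum) / scale_ref > 1e-12 &
                    abs(pair_sum - 2 * n * com_sum) > 1e-10)) {
    abort("pairwise/center-of-mass identity violated; trajectory data are inconsistent.",
          class = "oscnet_error")
  }
  denom <- if (convention == "average" && n > 1L) n * (n - 1) else 1
  structure(
    list(sync_error = mean(pair_sum[keep]) / denom,
         series = tibble(time = traj$times, pairwise_sq = pair_sum / denom),
         center_of_mass = center_of_mass(traj),
         mean_sq_to_com = mean(com_sum[keep]) / n,
         window = c(transient, max(traj$times)),
         convention = convention, n_osc = n),
    class = "sync_stats")
}

#' @export
print.sync_stats <- function(x, ...) {
  cat("<sync_stats> N = ", x$n_osc, ", convention = ", x$convention,
      ", window = [", x$window[1L], ", ", x$window[2L], "]\n",
      "  ergodic sync error: ", format(x$sync_error), "\n", sep = "")
  invisible(x)
}

#' Spatial mean of one component
#'
#' Per-time-point mean of a chosen component across units: the population
#' readout (e.g. the average membrane potential of the ensemble).
#'
#' @param traj an `ensemble_traj`.
#' @param component component index (default 1, the voltage).
#' @return a tibble with `time` and `value`.
#' @export
spatial_mean_series <- function(traj, component = 1L) {
  stopifnot(inherits(traj, "ensemble_traj"))
  d <- dim(traj$states)
  if (component < 1L || component > d[3L]) {
    abort_invalid("`component` index out of range.")
  }
  tibble(time = traj$times,
         value = rowMeans(matrix(traj$states[, , component], nrow = d[1L])))
}

#' One-sided FFT power spectrum
#'
#' Mean-removed, one-sided power spectrum on a uniform grid.  Without a
#' taper the spectrum is Parseval-consistent: the total power equals the
#' (population) variance of the series.  Frequencies are in cycles per
#' model time unit.
#'
#' @param series numeric vector, or a tibble with a `value` column (and
#'   optionally `time`, used to infer/check `dt`).
#' @param dt sampling interval.
#' @param window `"none"` (rectangular) or `"hann"`.
#' @return a `spectrum_est` object holding a tibble (`frequency`, `power`)
#'   and the bin width `resolution`.
#' @export
power_spectrum <- function(series, dt = NULL, window = c("none", "hann")) {
  window <- match.arg(window)
  if (is.data.frame(series)) {
    if (!is.null(series$time)) {
      steps <- diff(series$time)
      if (max(abs(steps - steps[1L])) > 1e-8 * max(abs(steps))) {
        abort_invalid("`series` must be uniformly sampled.")
      }
      dt <- dt %||% steps[1L]
    }
    series <- series$value
  }
  if (is.null(dt)) abort_invalid("`dt` is required for a bare numeric series.")
  check_number(dt, "dt", min = 0, strict_min = TRUE)
  m <- length(series)
  if (m < 16L) abort_invalid("`series` must have at least 16 samples.")
  x <- series - mean(series)
  if (window == "hann") {
    w <- 0.5 * (1 - cos(2 * pi * seq(0, m - 1) / (m - 1)))
    x <- x * w / sqrt(mean(w^2))  # preserve average power
  }
  X <- fft(x)
  p2 <- Mod(X)^2 / m^2
  half <- floor(m / 2)
  power <- numeric(half + 1L)
  power[1L] <- p2[1L]
  if (half >= 1L) {
    for_idx <- seq_len(half)
    mirror <- m - for_idx + 1L  # 1-based index of the conjugate bin
    power[for_idx + 1L] <- p2[for_idx + 1L] +
      ifelse(mirror == for_idx + 1L, 0, p2[mirror])  # Nyquist counted once
  }
  structure(
    list(table = tibble(frequency = (0:half) / (m * dt), power = power),
         resolution = 1 / (m * dt), dt = dt, n = m, window = window),
    class = "spectrum_est")
}

#' @export
print.spectrum_est <- function(x, ...) {
  cat("<spectrum_est> ", x$n, " samples, resolution ", format(x$resolution),
      " cycles/time, window = ", x$window, "\n", sep = "")
  f0 <- dominant_frequency(x)
  if (is.na(f0)) cat("  no clear spectral peak\n")
  else cat("  dominant frequency: ", format(f0), "\n", sep = "")
  invisible(x)
}

# noise floor: median power + `floor_db` decibels
spectral_floor <- function(power, floor_db = 6) {
  median(power) * 10^(floor_db / 10)
}

#' Dominant frequency of a spectrum
#'
#' Location of the largest spectral peak above the noise floor (median
#' power + `floor_db` dB), refined to sub-bin resolution by the
#' power-weighted centroid of the bins within \eqn{\pm 25\%} of the peak
#' frequency.  The centroid is robust to the peak broadening caused by
#' phase diffusion of noisy oscillators (the broadened peak stays centered
#' on the mean frequency).  Returns `NA` when no bin exceeds the floor --
#' the "no clear peak" outcome.
#'
#' @param spec a `spectrum_est`.
#' @param floor_db noise floor offset in dB above the median power.
#' @return frequency in cycles per time unit, or `NA`.
#' @export
dominant_frequency <- function(spec, floor_db = 6) {
  stopifnot(inherits(spec, "spectrum_est"))
  tbl <- spec$table
  pw <- tbl$power
  pw[1L] <- 0  # exclude DC
  j <- which.max(pw)
  if (pw[j] <= spectral_floor(tbl$power, floor_db)) return(NA_real_)
  centroid_peak(tbl$frequency, pw, tbl$frequency[j])
}

centroid_peak <- function(freq, power, f_center, half_width = 0.25) {
  band <- which(abs(freq - f_center) <= half_width * f_center & freq > 0)
  if (!length(band)) return(f_center)
  sum(freq[band] * power[band]) / sum(power[band])
}

#' Harmonic comparison of two spectra
#'
#' Extracts the dominant frequency and its first harmonics from each
#' spectrum and reports per-harmonic relative frequency differences
#' together with harmonic-clarity scores: the peak power near each
#' harmonic in dB over the local background (the median power in the
#' annulus 25--50% of the fundamental away from the harmonic).  A
#' noise-free trajectory and a noisy synchronized one match closely, with
#' clear harmonics; a noisy uncoupled unit shows degraded clarity or no
#' detectable harmonics, flagged `no_peak` rather than erroring.
#'
#' A spectrum is said to have *clear harmonics* when its fundamental is
#' detected and its first harmonic (twice the fundamental) stands at least
#' `clear_db` above the local background; `clear_db = 16` dB separates the
#' noise-free-like regime from the blurred one in the simulations shipped
#' with the package and is configurable.
#'
#' @param spec_a,spec_b `spectrum_est` objects on commensurate grids.
#' @param n_harmonics how many harmonics (including the fundamental).
#' @param floor_db noise floor offset in dB for peak detection.
#' @param clear_db clarity threshold (dB) for the clear-harmonics flag.
#' @return a `harmonic_match` object: tibble with `harmonic`, `freq_a`,
#'   `freq_b`, `rel_diff`, `clarity_a`, `clarity_b`; attributes
#'   `no_peak_a`, `no_peak_b`, `clear_a`, `clear_b`, `clarity_score_a`,
#'   `clarity_score_b` (mean clarity over harmonics, undetected harmonics
#'   counting as 0; a spectrum without a fundamental scores 0).
#' @export
harmonic_match <- function(spec_a, spec_b, n_harmonics = 3L, floor_db = 6,
                           clear_db = 16) {
  stopifnot(inherits(spec_a, "spectrum_est"), inherits(spec_b, "spectrum_est"))
  ha <- harmonic_table(spec_a, n_harmonics, floor_db)
  hb <- harmonic_table(spec_b, n_harmonics, floor_db)
  tbl <- tibble(
    harmonic = seq_len(n_harmonics),
    freq_a = ha$freq, freq_b = hb$freq,
    rel_diff = ifelse(is.na(ha$freq) | is.na(hb$freq), NA_real_,
                      abs(ha$freq - hb$freq) / pmax(ha$freq, 1e-300)),
    clarity_a = ha$clarity, clarity_b = hb$clarity)
  score <- function(h) {
    if (is.na(h$freq[1L])) return(0)
    mean(pmax(ifelse(is.na(h$clarity), 0, h$clarity), 0))
  }
  clear <- function(h) {
    !is.na(h$freq[1L]) && length(h$clarity) >= 2L &&
      !is.na(h$clarity[2L]) && h$clarity[2L] >= clear_db
  }
  structure(tbl, class = c("harmonic_match", class(tbl)),
            no_peak_a = is.na(ha$freq[1L]), no_peak_b = is.na(hb$freq[1L]),
            clear_a = clear(ha), clear_b = clear(hb),
            clarity_score_a = score(ha), clarity_score_b = score(hb))
}

harmonic_table <- function(spec, n_harmonics, floor_db) {
  tbl <- spec$table
  f0 <- dominant_frequency(spec, floor_db)
  freq <- rep(NA_real_, n_harmonics)
  clarity <- rep(NA_real_, n_harmonics)
  if (is.na(f0)) return(list(freq = freq, clarity = clarity))
  for (m in seq_len(n_harmonics)) {
    target <- m * f0
    peak_band <- which(abs(tbl$frequency - target) <= 0.25 * f0)
    bg_band <- which(abs(tbl$frequency - target) > 0.25 * f0 &
                       abs(tbl$frequency - target) <= 0.5 * f0)
    if (!length(peak_band)) next
    j <- peak_band[which.max(tbl$power[peak_band])]
    bg_power <- if (length(bg_band)) median(tbl$power[bg_band])
                else median(tbl$power)
    cl <- 10 * log10(tbl$power[j] / pmax(bg_power, 1e-300))
    if (m == 1L || cl > floor_db) {
      freq[m] <- centroid_peak(tbl$frequency, tbl$power, tbl$frequency[j])
      clarity[m] <- cl
    }
  }
  list(freq = freq, clarity = clarity)
}

#' Time-averaged squared distance between two trajectories
#'
#' Mean over the common post-transient grid of the squared Euclidean
#' distance between two single-unit trajectories (all components).  No
#' phase re-alignment is attempted: slow phase diffusion of a noisy
#' oscillator can dominate this raw distance, which is why spectral
#' comparisons ([harmonic_match()]) accompany it.
#'
#' @param a,b `ensemble_traj` objects with one unit each (or unit matrices
#'   time x components on a common grid).
#' @param transient time discarded before averaging.
#' @return nonnegative scalar.
#' @export
trajectory_distance <- function(a, b, transient = 0) {
  ga <- traj_as_matrix(a)
  gb <- traj_as_matrix(b)
  if (length(ga$times) != length(gb$times) ||
      max(abs(ga$times - gb$times)) > 1e-9 * max(1, max(abs(ga$times)))) {
    abort_invalid("`a` and `b` must share the same time grid.")
  }
  keep <- post_transient_index(ga$times, transient)
  mean(rowSums((ga$states[keep, , drop = FALSE] -
                  gb$states[keep, , drop = FALSE])^2))
}

traj_as_matrix <- function(x) {
  if (inherits(x, "ensemble_traj")) {
    d <- dim(x$states)
    if (d[2L] != 1L) {
      abort_invalid("trajectory distance expects single-unit trajectories; use extract_oscillator().")
    }
    list(times = x$times, states = matrix(x$states[, 1L, ], nrow = d[1L]))
  } else {
    x <- as.matrix(x)
    list(times = seq_len(nrow(x)), states = x)
  }
}

#' Period estimate by threshold crossings
#'
#' Mean interval between successive upward crossings of a threshold, with
#' linear interpolation at the crossing.  Used to check convergence to a
#' periodic orbit and to size transient windows.
#'
#' @param series numeric series (e.g. the voltage of a unit).
#' @param dt sampling interval.
#' @param level crossing threshold (default 0).
#' @return list with `period` (mean), `sd`, and `crossings`.
#' @export
estimate_period <- function(series, dt, level = 0) {
  n <- length(series)
  below <- series[-n] < level & series[-1L] >= level
  idx <- which(below)
  if (length(idx) < 3L) return(list(period = NA_real_, sd = NA_real_,
                                    crossings = length(idx)))
  frac <- (level - series[idx]) / (series[idx + 1L] - series[idx])
  tc <- (idx - 1 + frac) * dt
  list(period = mean(diff(tc)), sd = stats::sd(diff(tc)),
       crossings = length(idx))
}
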