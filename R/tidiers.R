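#' Tidy methods for oscnet result objects
#'
#' broom-style accessors: `tidy()` returns the object's main table,
#' `glance()` a one-row summary.
#'
#' @param x a `bound_report`, `sync_stats`, `observer_run` or
#'   `spectrum_est`.
#' @param ... unused.
#' @return a tibble.
#' @name oscnet-tidiers
NULL

#' @rdname oscnet-tidiers
#' @exportS3Method generics::tidy
tidy.bound_report <- function(x, ...) {
  base <- tibble(kind = x$kind, bound_value = x$bound_value,
                 transient_rate = x$transient_rate)
  scalars <- purrr::keep(x$inputs, ~ is.numeric(.x) && length(.x) == 1L)
  dplyr::bind_cols(base, as_tibble(scalars))
}

#' @rdname oscnet-tidiers
#' @exportS3Method generics::glance
glance.bound_report <- function(x, ...) {
  tibble(kind = x$kind, bound_value = x$bound_value,
         transient_rate = x$transient_rate)
}

#' @rdname oscnet-tidiers
#' @exportS3Method generics::tidy
tidy.sync_stats <- function(x, ...) x$series

#' @rdname oscnet-tidiers
#' @exportS3Method generics::glance
glance.sync_stats <- function(x, ...) {
  tibble(sync_error = x$sync_error, mean_sq_to_com = x$mean_sq_to_com,
         n_osc = x$n_osc, convention = x$convention,
         window_start = x$window[1L], window_end = x$window[2L])
}

#' @rdname oscnet-tidiers
#' @exportS3Method generics::tidy
tidy.observer_run <- function(x, ...) {
  dplyr::left_join(x$observer, x$distance_sq, by = "time")
}

#' @rdname oscnet-tidiers
#' @exportS3Method generics::glance
glance.observer_run <- function(x, ...) {
  tibble(ke = x$gains$ke,
         initial_distance_sq = x$distance_sq$distance_sq[1L],
         final_distance_sq = tail(x$distance_sq$distance_sq, 1L),
         n_steps = nrow(x$observer))
}

#' @rdname oscnet-tidiers
#' @exportS3Method generics::tidy
tidy.spectrum_est <- function(x, ...) x$table

#' @rdname oscnet-tidiers
#' @exportS3Method generics::glance
glance.spectrum_est <- function(x, ...) {
  tibble(dominant_frequency = dominant_frequency(x),
         resolution = x$resolution, n = x$n, window = x$window)
}
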