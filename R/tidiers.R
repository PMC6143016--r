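#' Broom-style tidiers
#'
#' `tidy()` and `glance()` methods for the package's result objects so they
#' drop into dplyr pipelines.
#'
#' @name tidiers
NULL

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname tidiers
#' @param x A result object.
#' @param ... Unused.
#' @export
tidy.oe_result <- function(x, ...) {
  tibble::tibble(
    term = "oe_ratio", estimate = x$ratio,
    conf.low = x$ci_low, conf.high = x$ci_high,
    observed = x$observed, expected = x$expected
  )
}

#' @rdname tidiers
#' @export
tidy.calibration_fit <- function(x, ...) {
  tibble::tibble(
    term = "beta", estimate = x$beta,
    conf.low = x$ci[1], conf.high = x$ci[2]
  )
}

#' @rdname tidiers
#' @export
glance.calibration_fit <- function(x, ...) {
  tibble::tibble(
    beta = x$beta, conf.low = x$ci[1], conf.high = x$ci[2],
    scale = x$scale, n_women = x$n_women, n_records = x$n_records,
    n_events = x$n_events
  )
}

#' @rdname tidiers
#' @export
tidy.decile_hr <- function(x, ...) {
  tibble::tibble(
    term = x$term, estimate = x$hr,
    conf.low = x$ci_low, conf.high = x$ci_high
  )
}
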