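#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an exponential decay fit
#' @param x A `glu_expfit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter (`term`, `estimate`).
#' @export
tidy.glu_expfit <- function(x, ...) {
  tibble::tibble(term = c("amplitude", "tau", "offset"),
                 estimate = c(x$amplitude, x$tau, x$offset))
}

#' @rdname tidy.glu_expfit
#' @export
glance.glu_expfit <- function(x, ...) {
  tibble::tibble(rmse = x$rmse, converged = x$converged,
                 window_start = x$window[1], window_end = x$window[2])
}

#' Tidy an affine fit
#' @param x A `glu_affinefit`.
#' @param ... Unused.
#' @export
tidy.glu_affinefit <- function(x, ...) {
  tibble::tibble(term = c("slope", "intercept"),
                 estimate = c(x$slope, x$intercept))
}

#' Tidy a deconvolved release-rate trace
#' @param x A `deconvolved_trace`.
#' @param ... Unused.
#' @return A tibble with `time_s`, `release_rate`, `sigma`.
#' @export
tidy.deconvolved_trace <- function(x, ...) {
  tibble::tibble(time_s = x$t0 + (seq_along(x$values) - 1) * x$dt,
                 release_rate = x$values, sigma = x$sigma)
}

#' @rdname tidy.deconvolved_trace
#' @export
glance.deconvolved_trace <- function(x, ...) {
  tibble::tibble(method = x$method, tau_used = x$tau_used,
                 snr_used = x$snr_used, n = length(x$values))
}
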