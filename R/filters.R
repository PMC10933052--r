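#' Zero-phase Gaussian filter specified by corner frequency
#'
#' Smooths a trace with a one-dimensional Gaussian kernel whose amplitude
#' response is -3 dB (1/sqrt(2)) at the corner frequency `f_c`. The
#' time-domain standard deviation follows from the Gaussian transfer
#' function exp(-2 pi^2 sigma^2 f^2): sigma_t = sqrt(ln 2) / (2 pi f_c).
#' Edges are handled by reflection and the trace length is preserved.
#'
#' @param ts A `glu_ts`.
#' @param f_c Corner frequency in Hz; must lie below the Nyquist frequency.
#' @return A filtered `glu_ts` of the same length.
#' @export
gaussian_filter_corner <- function(ts, f_c) {
  stopifnot_ts(ts)
  check_corner(f_c, ts$dt)
  sigma_t <- sqrt(log(2)) / (2 * pi * f_c)
  sigma_n <- sigma_t / ts$dt
  half <- max(1L, ceiling(6 * sigma_n))
  k <- exp(-0.5 * ((-half:half) / sigma_n)^2)
  k <- k / sum(k)
  ts_with(ts, conv_reflect(ts$values, k))
}

#' Iterated binomial filter specified by corner frequency
#'
#' Applies `n` passes of the three-point binomial kernel (1, 2, 1)/4, where
#' the pass count is chosen so the combined amplitude response
#' cos(pi f dt)^(2 n) is -3 dB at `f_c`:
#' n = max(1, round(ln(2^(-1/2)) / (2 ln cos(pi f_c dt)))).
#'
#' @inheritParams gaussian_filter_corner
#' @return A filtered `glu_ts` of the same length.
#' @export
binomial_filter_corner <- function(ts, f_c) {
  stopifnot_ts(ts)
  check_corner(f_c, ts$dt)
  n <- binomial_passes(f_c, ts$dt)
  k <- c(1, 2, 1) / 4
  v <- ts$values
  for (i in seq_len(n)) v <- conv_reflect(v, k)
  ts_with(ts, v)
}

#' @rdname binomial_filter_corner
#' @param dt Sample interval in seconds.
#' @return `binomial_passes()` returns the integer pass count.
#' @export
binomial_passes <- function(f_c, dt) {
  max(1L, as.integer(round(log(2^(-1 / 2)) / (2 * log(cos(pi * f_c * dt))))))
}

check_corner <- function(f_c, dt) {
  nyquist <- 0.5 / dt
  if (!is.numeric(f_c) || length(f_c) != 1 || !is.finite(f_c) || f_c <= 0 ||
      f_c >= nyquist) {
    stop(sprintf("corner frequency must lie in (0, %.6g) Hz (Nyquist limit for dt = %.3g s)",
                 nyquist, dt), call. = FALSE)
  }
  invisible(f_c)
}

# length-preserving convolution with reflective (mirror) edge padding
conv_reflect <- function(x, k) {
  half <- (length(k) - 1L) %/% 2L
  n <- length(x)
  if (half > 0) {
    # reflect without repeating the edge sample; recycle if kernel > trace
    left <- rev(x[seq_len(min(half, n - 1L)) + 1L])
    right <- rev(x[n - seq_len(min(half, n - 1L))])
    while (length(left) < half) left <- c(left[1], left)
    while (length(right) < half) right <- c(right, right[length(right)])
    xp <- c(left, x, right)
  } else {
    xp <- x
  }
  out <- stats::filter(xp, k, method = "convolution", sides = 2)
  as.numeric(out[(half + 1L):(half + n)])
}
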