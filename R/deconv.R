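#' Signal-to-noise ratio of a response trace
#'
#' The SNR is the squared quotient of the maximum response amplitude
#' (relative to the baseline mean) and the root-mean-square noise of the
#' baseline window.
#'
#' @param ts A `glu_ts`.
#' @param baseline_window `[t_start, t_end]` (s) of response-free baseline,
#'   preceding the response.
#' @param noise_method Passed to [rms_noise()] (`"rms"` by default here:
#'   the baseline window is event-free by assumption).
#' @return A one-row tibble: `snr` (dimensionless, `Inf` flagged when the
#'   baseline noise is zero) and `infinite`.
#' @export
estimate_snr <- function(ts, baseline_window, noise_method = "rms") {
  stopifnot_ts(ts)
  idx <- ts_window_idx(ts, baseline_window, min_samples = 10L)
  base <- mean(ts$values[idx[1]:idx[2]])
  noise <- rms_noise(ts, baseline_window, method = noise_method)
  peak <- max(abs(ts$values - base))
  if (noise <= peak * 1e-12) { # zero-noise sentinel
    return(tibble::tibble(snr = Inf, infinite = TRUE))
  }
  tibble::tibble(snr = (peak / noise)^2, infinite = FALSE)
}

# unit-integral instant-rise exponential kernel sampled on the trace grid
sampled_kernel <- function(tau, dt, n) {
  h <- exp(-(seq_len(n) - 1) * dt / tau)
  h / (sum(h) * dt)
}

#' Wiener deconvolution of a reporter trace
#'
#' Frequency-domain release-rate estimate: with the reporter modeled as a
#' linear time-invariant system with impulse response `h(t)` (unit-integral
#' instant-rise exponential with decay `tau`), the Fourier transform of the
#' release rate is estimated as
#' `X(f) = S(f) H*(f) / (H(f) H*(f) + 1/SNR)`,
#' a constant-regularizer Wiener filter. The trace is zero-padded to at
#' least twice its length (next power of two) and the real part of the
#' inverse transform is returned. `snr = Inf` (the zero-noise sentinel of
#' [estimate_snr()]) degrades gracefully to the plain inverse filter.
#'
#' @param ts A `glu_ts` (typically delta-F/F on the 100 Hz frame grid).
#' @param kernel A [kernel_model()]; `kernel$tau` must exceed the sample
#'   interval.
#' @param snr Scalar signal-to-noise ratio (> 0, may be `Inf`).
#' @return A `deconvolved_trace`: a `glu_ts`-like list with `values`
#'   (release rate, units of input per second), `sigma` (NA for this
#'   method), `tau_used`, `snr_used`, `method`.
#' @export
wiener_deconvolve <- function(ts, kernel, snr) {
  stopifnot_ts(ts)
  stopifnot(inherits(kernel, "kernel_model"))
  if (kernel$tau <= ts$dt) {
    stop("kernel tau must exceed the sample interval", call. = FALSE)
  }
  if (!is.numeric(snr) || length(snr) != 1 || is.na(snr) || snr <= 0) {
    stop("`snr` must be a positive scalar (possibly Inf)", call. = FALSE)
  }
  n <- length(ts$values)
  nfft <- 2^ceiling(log2(2 * n))
  s <- c(ts$values, numeric(nfft - n))
  h <- sampled_kernel(kernel$tau, ts$dt, nfft)
  S <- stats::fft(s)
  H <- stats::fft(h) * ts$dt # approximate continuous transform
  denom <- Mod(H)^2 + if (is.finite(snr)) 1 / snr else 0
  X <- S * Conj(H) / denom
  x <- Re(stats::fft(X, inverse = TRUE)) / nfft
  new_deconvolved(ts, x[seq_len(n)], sigma = rep(NA_real_, n),
                  tau = kernel$tau, method = "wiener", snr = snr)
}

#' Linear-kernel deconvolution with error propagation
#'
#' Direct release-rate estimate from the reporter differential equation:
#' for a monoexponential reporter, `r(t) = ds/dt + s(t)/tau` recovers
#' `s0 * x(t)`. The derivative is the forward difference
#' `(s(t + dt) - s(t))/dt`; at the final sample the forward difference is
#' undefined, so the penultimate value is copied and flagged.
#'
#' The forward difference is naturally centered at `t + dt/2`, so by
#' default the `s/tau` term is evaluated there too, as the two-sample
#' average (`s_eval = "midpoint"`); this reduces the discretisation bias of
#' the operator from O(dt/tau) to O((dt/tau)^2), which matters when the
#' frame interval is an appreciable fraction of the reporter decay.
#' `s_eval = "sample"` evaluates `s/tau` at the left sample verbatim.
#'
#' The per-sample uncertainty defaults to first-order Gaussian quadrature,
#' `sigma_r^2 = 2 sigma_s^2/dt^2 + sigma_s^2/tau^2 + (s/tau^2)^2 sigma_tau^2`.
#' `error_form = "printed"` instead evaluates the linear combination
#' `2 sigma_s/dt - sigma_s/tau - s(t) sigma_tau/tau^2` for comparison with
#' prior descriptions of this estimator.
#'
#' @param ts A `glu_ts`.
#' @param tau Reporter decay constant in seconds (> `dt`).
#' @param sigma_s Per-sample noise SD of the trace (signal units).
#' @param sigma_tau Uncertainty of `tau` in seconds.
#' @param error_form `"quadrature"` (default) or `"printed"`.
#' @param s_eval Evaluation point of the `s/tau` term: `"midpoint"`
#'   (default, two-sample average) or `"sample"` (left sample).
#' @return A `deconvolved_trace` (see [wiener_deconvolve()]); `sigma` holds
#'   the per-sample uncertainty, and `last_sample_copied = TRUE` flags the
#'   final sample.
#' @export
linear_deconvolve <- function(ts, tau, sigma_s = 0, sigma_tau = 0,
                              error_form = c("quadrature", "printed"),
                              s_eval = c("midpoint", "sample")) {
  stopifnot_ts(ts)
  error_form <- match.arg(error_form)
  s_eval <- match.arg(s_eval)
  if (tau <= ts$dt) stop("`tau` must exceed the sample interval", call. = FALSE)
  s <- ts$values
  n <- length(s)
  dt <- ts$dt
  s_term <- if (s_eval == "midpoint") c((s[-1] + s[-n]) / 2, NA_real_) else s
  r <- c((s[-1] - s[-n]) / dt, NA_real_) + s_term / tau
  r[n] <- r[n - 1]
  sigma <- if (error_form == "quadrature") {
    sqrt(2 * sigma_s^2 / dt^2 + sigma_s^2 / tau^2 + (s / tau^2)^2 * sigma_tau^2)
  } else {
    2 * sigma_s / dt - sigma_s / tau - s * sigma_tau / tau^2
  }
  out <- new_deconvolved(ts, r, sigma = sigma, tau = tau,
                         method = "linear_kernel", snr = NA_real_)
  out$last_sample_copied <- TRUE
  out
}

new_deconvolved <- function(ts, values, sigma, tau, method, snr) {
  structure(
    list(t0 = ts$t0, dt = ts$dt, values = values, sigma = sigma,
         tau_used = tau, method = method, snr_used = snr,
         units = "rate", label = ts$label),
    class = c("deconvolved_trace", "glu_ts")
  )
}

#' @export
print.deconvolved_trace <- function(x, ...) {
  cat(sprintf("<deconvolved_trace> %s, %d samples @ %.6g Hz, tau = %.4g s\n",
              x$method, length(x$values), 1 / x$dt, x$tau_used))
  invisible(x)
}

#' Estimate the reporter decay constant from a trace
#'
#' Single-exponential fit through the decay phase (typically after the last
#' stimulus). When release has not fully stopped at the window start, the
#' estimate is an upper bound for the true time constant; the result is
#' flagged accordingly.
#'
#' @param ts A `glu_ts`.
#' @param decay_window `[t_start, t_end]` in seconds.
#' @return A one-row tibble: `tau` (s), `rmse`, `converged`,
#'   `upper_bound` (always TRUE: the estimator's bias direction).
#' @export
estimate_tau <- function(ts, decay_window) {
  fit <- fit_exp_decay(ts, decay_window)
  tibble::tibble(tau = fit$tau, rmse = fit$rmse, converged = fit$converged,
                 upper_bound = TRUE)
}

#' Per-stimulus release from a deconvolved trace
#'
#' Splits a deconvolved release-rate trace into inter-stimulus windows and
#' reports the per-stimulus release as the window peak (default, matching
#' how deconvolved responses are usually read out) or the window integral;
#' the running cumulative sum feeds [y1_over_intercept()] unchanged.
#'
#' Each window starts one sample before the first sample at or after its
#' stimulus: when a stimulus (plus synaptic delay) falls inside a frame,
#' the forward-difference derivative at the preceding frame already carries
#' part of that stimulus' release, so windows aligned naively to the
#' stimulus grid would leak release into the previous window.
#'
#' @param dec A `deconvolved_trace`.
#' @param protocol A [stim_protocol()] covered by the trace.
#' @param statistic `"peak"` or `"integral"`.
#' @return A tibble with one row per stimulus: `stimulus`, `release`,
#'   `cumulative`.
#' @export
cumulative_release <- function(dec, protocol,
                               statistic = c("peak", "integral")) {
  stopifnot(inherits(dec, "deconvolved_trace"),
            inherits(protocol, "stim_protocol"))
  statistic <- match.arg(statistic)
  dt <- dec$dt
  n <- length(dec$values)
  frame_start <- dec$t0 + (seq_len(n) - 1) * dt
  isis <- diff(protocol$times)
  isi <- if (length(isis)) mean(isis) else 10 * dt
  bounds <- c(protocol$times, protocol$times[protocol$n] + isi)
  # window i = [a_i - 1, a_{i+1} - 2], a_i = first sample at/after stimulus i
  a <- vapply(bounds, function(b) {
    i <- which(frame_start >= b - 1e-12)[1]
    if (is.na(i)) n + 1L else i
  }, numeric(1))
  release <- numeric(protocol$n)
  for (i in seq_len(protocol$n)) {
    lo <- max(1L, a[i] - 1L)
    hi <- min(n, a[i + 1] - 2L)
    if (hi < lo) next
    win <- lo:hi
    release[i] <- if (statistic == "peak") max(dec$values[win])
      else sum(dec$values[win]) * dt
  }
  tibble::tibble(stimulus = seq_len(protocol$n), release = release,
                 cumulative = cumsum(release))
}
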