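#' Single-exponential decay fit
#'
#' Least-squares fit of `A * exp(-(t - t_start)/tau) + offset` over a time
#' window, used both for event decay kinetics and for estimating the
#' fluorescence reporter time constant. Initialisation is log-linear
#' (regression of log(|y - baseline|) on t), refined by Levenberg-Marquardt
#' nonlinear least squares (tolerance 1e-8, at most 200 iterations).
#'
#' @param ts A `glu_ts`.
#' @param window `[t_start, t_end]` in seconds; must contain >= 5 samples.
#' @return A `glu_expfit` with fields `amplitude`, `tau` (s), `offset`,
#'   `rmse`, `window`, and `converged`. Non-convergence is flagged, never a
#'   silent NaN.
#' @export
#'
#' @examples
#' t <- seq(0, 1, by = 0.001)
#' ts <- glu_ts(2 * exp(-t / 0.1), dt = 0.001)
#' fit_exp_decay(ts, c(0, 1))
fit_exp_decay <- function(ts, window) {
  stopifnot_ts(ts)
  idx <- ts_window_idx(ts, window, min_samples = 5L)
  i <- idx[1]:idx[2]
  t <- (i - idx[1]) * ts$dt
  y <- ts$values[i]

  off0 <- y[length(y)]
  a0 <- y[1] - off0
  if (a0 == 0) a0 <- max(abs(y - off0)) * sign(stats::median(y - off0) + 1e-300)
  pos <- (y - off0) / a0
  ok <- pos > 1e-6
  tau0 <- if (sum(ok) >= 2) {
    sl <- stats::coef(stats::lm(log(pos[ok]) ~ t[ok]))[2]
    if (is.finite(sl) && sl < 0) -1 / sl else diff(range(t)) / 3
  } else diff(range(t)) / 3
  tau0 <- max(tau0, ts$dt)

  # fit in rescaled units (y in units of a0, t in units of tau0): current
  # traces live at 1e-10 A and 1e-4 s scales, which makes the raw gradient
  # matrix numerically singular
  ys <- (y - off0) / a0
  tns <- t / tau0
  fit <- tryCatch(
    minpack.lm::nlsLM(
      ys ~ A * exp(-tns / tau) + C,
      start = list(A = 1, tau = 1, C = 0),
      control = minpack.lm::nls.lm.control(ftol = 1e-8, ptol = 1e-8,
                                           maxiter = 200)
    ),
    error = function(e) NULL
  )
  # tau must come out positive to count as a decay fit
  if (!is.null(fit) && stats::coef(fit)["tau"] <= 0) fit <- NULL

  if (is.null(fit)) {
    out <- list(amplitude = a0, tau = tau0, offset = off0,
                rmse = sqrt(mean((y - (a0 * exp(-t / tau0) + off0))^2)),
                window = window, converged = FALSE,
                diagnostics = "nonlinear fit failed; log-linear initial values returned")
  } else {
    p <- stats::coef(fit)
    out <- list(amplitude = unname(p["A"]) * a0, tau = unname(p["tau"]) * tau0,
                offset = unname(p["C"]) * a0 + off0,
                rmse = sqrt(mean(stats::residuals(fit)^2)) * abs(a0),
                window = window, converged = TRUE, diagnostics = NULL)
  }
  class(out) <- "glu_expfit"
  out
}

#' @export
print.glu_expfit <- function(x, ...) {
  cat(sprintf("<glu_expfit> amplitude = %.4g, tau = %.4g s, offset = %.4g, rmse = %.3g%s\n",
              x$amplitude, x$tau, x$offset, x$rmse,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  invisible(x)
}

#' Evaluate an exponential fit on a time grid
#' @param fit A `glu_expfit`.
#' @param t Times in seconds, relative to the fit window start.
#' @export
predict_expfit <- function(fit, t) {
  fit$amplitude * exp(-t / fit$tau) + fit$offset
}

#' Affine (straight-line) fit over a window
#'
#' Ordinary least squares `y = slope * t + intercept` over the window; used
#' for the rising phase of quantal events.
#'
#' @inheritParams fit_exp_decay
#' @param window `[t_start, t_end]` in seconds; must contain >= 2 samples.
#' @return A `glu_affinefit` with `slope` (signal units / s), `intercept`
#'   (value at window start) and `window`.
#' @export
fit_affine <- function(ts, window) {
  stopifnot_ts(ts)
  idx <- ts_window_idx(ts, window, min_samples = 2L)
  i <- idx[1]:idx[2]
  t <- (i - idx[1]) * ts$dt
  co <- stats::coef(stats::lm(ts$values[i] ~ t))
  structure(list(slope = unname(co[2]), intercept = unname(co[1]),
                 window = window),
            class = "glu_affinefit")
}

#' Amplitude, charge, width and rise slope of a deflection
#'
#' Measures a single event between `onset` and `end`. The local baseline is
#' the mean over a short pre-onset window (falling back to the onset sample
#' at the trace edge). Amplitude is the maximal absolute deviation from that
#' baseline; charge the time integral (trapezoidal) of the
#' baseline-subtracted signal over `[onset, end]`; FWHM the total time the
#' deviation exceeds half its maximum, with sub-sample interpolation at the
#' crossings. Inward currents are stored negative; all summary quantities
#' are reported as positive magnitudes.
#'
#' @param ts A `glu_ts`.
#' @param onset,end Event window in seconds (`onset < end`, >= 3 samples).
#' @param baseline_s Pre-onset baseline window length in seconds.
#' @return A one-row tibble with `amplitude`, `charge`, `fwhm`, `rise_slope`.
#' @export
event_measures <- function(ts, onset, end, baseline_s = 5e-4) {
  stopifnot_ts(ts)
  idx <- ts_window_idx(ts, c(onset, end), min_samples = 3L)
  i <- idx[1]:idx[2]
  y <- ts$values[i]

  b0 <- max(1L, idx[1] - max(1L, round(baseline_s / ts$dt)))
  base <- if (b0 < idx[1]) mean(ts$values[b0:(idx[1] - 1L)]) else y[1]
  dev <- y - base
  sgn <- if (max(dev) >= -min(dev)) 1 else -1
  d <- sgn * dev # positive-going deviation

  pk <- which.max(d)
  amplitude <- d[pk]
  charge <- abs(trapz_sum(d, ts$dt))
  fwhm <- time_above(d, amplitude / 2, ts$dt)

  # 10-90% rise slope on the leading edge, reported as magnitude
  rise_slope <- 0
  if (amplitude > 0 && pk > 1) {
    r10 <- crossing_before(d, pk, 0.1 * amplitude)
    r90 <- crossing_before(d, pk, 0.9 * amplitude)
    if (is.finite(r10) && is.finite(r90) && r90 > r10) {
      rise_slope <- 0.8 * amplitude / ((r90 - r10) * ts$dt)
    } else {
      rise_slope <- amplitude / ts$dt # quantization-limited instant rise
    }
  }
  tibble::tibble(amplitude = amplitude, charge = charge,
                 fwhm = fwhm, rise_slope = rise_slope)
}

# trapezoidal integral of uniformly sampled values
trapz_sum <- function(y, dt) {
  n <- length(y)
  if (n < 2) return(0)
  dt * (sum(y) - (y[1] + y[n]) / 2)
}

# Total time y > thr, interpolating the crossings linearly. An entry whose
# preceding sample sits far below the threshold (< thr/5) is treated as an
# unresolved instantaneous rise: the crossing is placed at the first
# above-threshold sample, which is where instant-rise events actually start.
time_above <- function(y, thr, dt) {
  if (thr <= 0 || !any(y > thr)) return(0)
  above <- y > thr
  total <- 0
  n <- length(y)
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  for (r in which(runs$values)) {
    i0 <- starts[r]; i1 <- ends[r]
    seg <- (i1 - i0) * dt
    if (i0 > 1 && y[i0 - 1] >= thr / 5) { # resolved entry crossing
      seg <- seg + dt * (y[i0] - thr) / (y[i0] - y[i0 - 1])
    }
    if (i1 < n) { # exit crossing between i1 and i1+1
      seg <- seg + dt * (y[i1] - thr) / (y[i1] - y[i1 + 1])
    }
    total <- total + seg
  }
  total
}

# fractional index (relative to start of d) of last upward crossing of `lev`
# before peak index pk; NA if never below lev
crossing_before <- function(d, pk, lev) {
  below <- which(d[1:pk] < lev)
  if (!length(below)) return(NA_real_)
  i <- max(below)
  if (i == pk) return(NA_real_)
  i + (lev - d[i]) / (d[i + 1] - d[i]) - 1 # 0-based fractional sample
}

#' Robust baseline noise estimate
#'
#' Estimates the root-mean-square noise of a (possibly event-containing)
#' window as 1.4826 x the median absolute deviation of the window after
#' removing an affine trend. The MAD is used instead of the raw RMS because
#' detection windows contain events; set `method = "rms"` for the plain
#' root-mean-square about the trend.
#'
#' @param ts A `glu_ts`.
#' @param window `[t_start, t_end]` in seconds; must contain >= 10 samples.
#'   Defaults to the whole trace.
#' @param method `"mad"` (default) or `"rms"`.
#' @return Noise sigma in signal units.
#' @export
rms_noise <- function(ts, window = NULL, method = c("mad", "rms")) {
  stopifnot_ts(ts)
  method <- match.arg(method)
  if (is.null(window)) {
    window <- c(ts$t0, ts$t0 + (length(ts$values) - 1) * ts$dt)
  }
  idx <- ts_window_idx(ts, window, min_samples = 10L)
  i <- idx[1]:idx[2]
  t <- (i - idx[1]) * ts$dt
  resid <- stats::residuals(stats::lm(ts$values[i] ~ t))
  if (method == "mad") stats::mad(resid, center = 0) else sqrt(mean(resid^2))
}
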