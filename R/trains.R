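#' Per-stimulus metrics of an evoked response train
#'
#' Measures each evoked response of a stimulus train. For stimulus `i` the
#' local baseline is the mean over the 1 ms window preceding the stimulus;
#' the amplitude is the peak deviation from that baseline within
#' `[stimulus_i, stimulus_{i+1})` (a 50 ms tail is used after the final
#' stimulus); the synaptic delay is the time from the stimulus to the trace
#' crossing 10% of that peak. A tail-overlap correction subtracts the
#' fitted single-exponential continuation of the previous response before
#' measuring, which matters when the inter-stimulus interval is not large
#' against the decay time constant. Rise time (10-90%), decay time
#' constant and FWHM come from the shared kinetic fits.
#'
#' @param ts A `glu_ts` (ampere traces measure inward-negative currents).
#' @param protocol A [stim_protocol()]; the trace must cover the protocol
#'   plus a 50 ms tail (otherwise the last stimulus is flagged).
#' @param baseline_s Pre-stimulus baseline window (s).
#' @param tail_correct Subtract fitted exponential tails of earlier
#'   responses (default TRUE).
#' @return A `train_metrics` tibble with one row per stimulus: `stimulus`,
#'   `amplitude` (magnitude), `charge`, `rise_time`, `tau_decay`, `fwhm`,
#'   `syn_delay`, `cumulative_amplitude`, `flagged`.
#' @export
measure_train <- function(ts, protocol, baseline_s = 1e-3, tail_correct = TRUE) {
  stopifnot_ts(ts)
  stopifnot(inherits(protocol, "stim_protocol"))
  dt <- ts$dt
  n <- length(ts$values)
  t_end <- ts$t0 + (n - 1) * dt
  sgn <- if (ts$units == "ampere") -1 else 1 # direction of the response

  v <- ts$values
  work <- v # running copy with earlier tails subtracted
  out <- vector("list", protocol$n)
  for (i in seq_len(protocol$n)) {
    t_stim <- protocol$times[i]
    w_end <- if (i < protocol$n) protocol$times[i + 1] else
      min(t_end, t_stim + 0.05)
    flagged <- (i == protocol$n) && (t_end < t_stim + 0.05)

    i0 <- ts_index(ts, t_stim)
    i1 <- max(i0 + 2L, ts_index(ts, w_end) - (i < protocol$n))
    b0 <- max(1L, i0 - max(1L, round(baseline_s / dt)))
    base <- mean(work[b0:max(b0, i0 - 1L)])
    seg <- sgn * (work[i0:i1] - base)

    pk_rel <- which.max(seg)
    amplitude <- max(seg[pk_rel], 0)
    pk <- i0 + pk_rel - 1L

    # synaptic delay and 10-90% rise time from threshold crossings
    c10 <- crossing_before(seg, pk_rel, 0.1 * amplitude)
    c90 <- crossing_before(seg, pk_rel, 0.9 * amplitude)
    syn_delay <- if (is.finite(c10)) c10 * dt else NA_real_
    rise_time <- if (is.finite(c10) && is.finite(c90) && c90 > c10)
      (c90 - c10) * dt else dt

    charge <- abs(trapz_sum(seg, dt))
    fwhm <- time_above(seg, amplitude / 2, dt)

    # decay fit from the peak
    tau_decay <- NA_real_
    fit <- NULL
    if (i1 - pk >= 4L) {
      fit <- fit_exp_decay(ts_with(ts, work),
                           ts$t0 + c(pk - 1, i1 - 1) * dt)
      if (fit$converged && fit$tau > 0) tau_decay <- fit$tau
    }

    # subtract this response's fitted continuation beyond its window
    if (tail_correct && !is.null(fit) && fit$converged && i1 < n) {
      tt <- (seq.int(i1 + 1L, n) - pk) * dt
      work[(i1 + 1L):n] <- work[(i1 + 1L):n] -
        (predict_expfit(fit, tt) - fit$offset)
    }

    out[[i]] <- tibble::tibble(
      stimulus = i, amplitude = amplitude, charge = charge,
      rise_time = rise_time, tau_decay = tau_decay, fwhm = fwhm,
      syn_delay = syn_delay, flagged = flagged
    )
  }
  res <- dplyr::bind_rows(out)
  res$cumulative_amplitude <- cumsum(res$amplitude)
  class(res) <- c("train_metrics", class(res))
  res
}

#' Paired-pulse ratio
#'
#' Ratio of the second to the first evoked response amplitude at a given
#' inter-stimulus interval: the standard short-term plasticity measure
#' (depressing synapses give PPR < 1).
#'
#' @param metrics A `train_metrics` tibble from [measure_train()] (any
#'   tibble with `amplitude` ordered by stimulus works).
#' @return A one-row tibble with `ppr` and `defined` (FALSE when the first
#'   amplitude is zero).
#' @export
paired_pulse_ratio <- function(metrics) {
  a <- metrics$amplitude
  if (length(a) < 2) stop("need at least 2 stimuli for a PPR", call. = FALSE)
  if (a[1] == 0) {
    return(tibble::tibble(ppr = NA_real_, defined = FALSE))
  }
  tibble::tibble(ppr = a[2] / a[1], defined = TRUE)
}

#' Cumulative (SMN-style) vesicle pool analysis
#'
#' Plots (conceptually) the cumulative evoked amplitude against stimulus
#' number for a constant-rate train, fits an ordinary least-squares line
#' through the last `fit_last_k` points, and back-extrapolates to stimulus
#' index 0 (the ordinate). The intercept estimates the readily releasable
#' pool in response units; the slope divided by the inter-stimulus interval
#' estimates the replenishment rate (response units per ms); the first
#' response divided by the intercept is the uncorrected apparent release
#' probability. No depletion correction is applied; the ratio
#' `y1/y_intercept` is reported as-is, so that optical and electrical
#' readouts remain directly comparable.
#'
#' @param metrics A `train_metrics` tibble (or any tibble with `amplitude`).
#' @param protocol The constant-rate [stim_protocol()] that evoked it.
#' @param fit_last_k Number of final points in the steady-state fit.
#' @return A `pool_estimate` tibble (one row): `rrp`, `refill_rate`
#'   (units/ms), `p_apparent`, `y_intercept`, `slope`, `fit_first`,
#'   `fit_last`, `reliable`.
#' @export
smn_analysis <- function(metrics, protocol, fit_last_k = 10) {
  stopifnot(inherits(protocol, "stim_protocol"))
  isis <- diff(protocol$times)
  if (length(isis) && (max(isis) - min(isis)) > 1e-6 * mean(isis)) {
    stop("`smn_analysis()` needs a constant-rate train", call. = FALSE)
  }
  est <- back_extrapolate(metrics$amplitude, fit_last_k)
  isi_ms <- if (length(isis)) mean(isis) * 1e3 else NA_real_
  out <- tibble::tibble(
    rrp = est$y_intercept,
    refill_rate = est$slope / isi_ms,
    p_apparent = est$p_apparent,
    y_intercept = est$y_intercept,
    slope = est$slope,
    fit_first = est$fit_first,
    fit_last = est$fit_last,
    reliable = est$reliable
  )
  class(out) <- c("pool_estimate", class(out))
  out
}

#' Back-extrapolated first-response / intercept ratio
#'
#' The shared estimator behind the pool analysis: cumulative sums of any
#' per-stimulus response sequence (evoked amplitudes, per-pulse fluorescence
#' AUC, deconvolved release peaks), an affine fit through the last
#' `fit_last_k` cumulative points against stimulus index, intercept
#' evaluated at index 0, and the ratio of the first response to that
#' intercept. Scale-invariant by construction.
#'
#' @param responses Per-stimulus response values (not yet cumulative).
#' @param fit_last_k Number of final cumulative points in the fit (>= 2).
#' @return A one-row tibble: `p_apparent`, `y_intercept`, `slope`,
#'   `fit_first`, `fit_last`, `reliable` (FALSE when the intercept is not
#'   positive, e.g. for non-depressing sequences).
#' @export
y1_over_intercept <- function(responses, fit_last_k = 10) {
  back_extrapolate(responses, fit_last_k)
}

back_extrapolate <- function(responses, fit_last_k) {
  n <- length(responses)
  if (fit_last_k < 2) stop("`fit_last_k` must be >= 2", call. = FALSE)
  if (n < fit_last_k) {
    stop("need at least `fit_last_k` responses", call. = FALSE)
  }
  cum <- cumsum(responses)
  idx <- seq.int(n - fit_last_k + 1L, n)
  co <- stats::coef(stats::lm(cum[idx] ~ idx))
  y_int <- unname(co[1]) # value at stimulus index 0
  slope <- unname(co[2])
  reliable <- is.finite(y_int) && y_int > .Machine$double.eps^0.5 *
    max(abs(cum))
  tibble::tibble(
    p_apparent = if (reliable) responses[1] / y_int else NA_real_,
    y_intercept = y_int, slope = slope,
    fit_first = idx[1], fit_last = idx[length(idx)],
    reliable = reliable
  )
}
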