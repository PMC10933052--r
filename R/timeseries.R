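#' Uniformly sampled time series
#'
#' `glu_ts()` builds the package's basic signal container: a uniformly
#' sampled trace with a start time, sample interval and physical units.
#' Currents are stored signed (inward currents negative, in ampere);
#' fluorescence traces are dimensionless delta-F/F.
#'
#' @param values Numeric vector of samples (length >= 2, all finite).
#' @param dt Sample interval in seconds (> 0).
#' @param t0 Time of the first sample in seconds.
#' @param units One of `"ampere"`, `"dff"`, `"arbitrary"`.
#' @param label Free-text label carried through analyses.
#'
#' @return An object of class `glu_ts`.
#' @export
#'
#' @examples
#' ts <- glu_ts(sin(seq(0, 1, by = 0.01)), dt = 0.01, units = "arbitrary")
#' ts_duration(ts)
glu_ts <- function(values, dt, t0 = 0, units = c("arbitrary", "ampere", "dff"),
                   label = "") {
  units <- match.arg(units)
  values <- as.numeric(values)
  if (length(values) < 2) {
    stop("a `glu_ts` needs at least 2 samples", call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("all samples of a `glu_ts` must be finite", call. = FALSE)
  }
  if (!is.numeric(dt) || length(dt) != 1 || !is.finite(dt) || dt <= 0) {
    stop("`dt` must be a single positive number (seconds)", call. = FALSE)
  }
  structure(
    list(t0 = as.numeric(t0), dt = dt, values = values,
         units = units, label = as.character(label)),
    class = "glu_ts"
  )
}

#' @export
print.glu_ts <- function(x, ...) {
  cat(sprintf("<glu_ts> %d samples @ %.6g Hz, t0 = %.6g s, units = %s%s\n",
              length(x$values), 1 / x$dt, x$t0, x$units,
              if (nzchar(x$label)) paste0(", label = '", x$label, "'") else ""))
  invisible(x)
}

is_glu_ts <- function(x) inherits(x, "glu_ts")

stopifnot_ts <- function(x, arg = "ts") {
  if (!is_glu_ts(x)) stop(sprintf("`%s` must be a `glu_ts`", arg), call. = FALSE)
  invisible(x)
}

#' Time axis, duration and indexing helpers for `glu_ts`
#'
#' @param ts A `glu_ts`.
#' @return `ts_time()` returns the vector of sample times (s); `ts_duration()`
#'   the spanned duration (s); `ts_index()` the sample index closest to a time.
#' @export
ts_time <- function(ts) {
  stopifnot_ts(ts)
  ts$t0 + (seq_along(ts$values) - 1) * ts$dt
}

#' @rdname ts_time
#' @export
ts_duration <- function(ts) {
  stopifnot_ts(ts)
  length(ts$values) * ts$dt
}

#' @rdname ts_time
#' @param t Time in seconds.
#' @export
ts_index <- function(ts, t) {
  stopifnot_ts(ts)
  i <- round((t - ts$t0) / ts$dt) + 1
  pmin(pmax(i, 1L), length(ts$values))
}

# window [t_start, t_end] -> integer sample range, validated
ts_window_idx <- function(ts, window, min_samples = 2L) {
  if (length(window) != 2 || !all(is.finite(window)) || window[2] <= window[1]) {
    stop("`window` must be a finite, increasing [t_start, t_end] pair (s)",
         call. = FALSE)
  }
  tmin <- ts$t0
  tmax <- ts$t0 + (length(ts$values) - 1) * ts$dt
  if (window[1] < tmin - ts$dt / 2 || window[2] > tmax + ts$dt / 2) {
    stop(sprintf("window [%.6g, %.6g] s lies outside the trace extent [%.6g, %.6g] s",
                 window[1], window[2], tmin, tmax), call. = FALSE)
  }
  i0 <- max(1L, ceiling((window[1] - ts$t0) / ts$dt - 1e-9) + 1L)
  i1 <- min(length(ts$values), floor((window[2] - ts$t0) / ts$dt + 1e-9) + 1L)
  if (i1 - i0 + 1L < min_samples) {
    stop(sprintf("window contains %d samples, need at least %d",
                 max(0L, i1 - i0 + 1L), min_samples), call. = FALSE)
  }
  c(i0, i1)
}

#' @export
as_tibble.glu_ts <- function(x, ...) {
  tibble::tibble(time_s = ts_time(x), value = x$values)
}

#' Read and write traces in the package CSV dialect
#'
#' The on-disk dialect is a UTF-8 CSV with header `time_s,value` and '.' as
#' decimal separator. On read, uniform sampling is validated to 1 ppm of the
#' median sample interval.
#'
#' @param path File path.
#' @param units,label Passed to [glu_ts()].
#' @return `read_trace_csv()` returns a `glu_ts`; `write_trace_csv()` returns
#'   `path` invisibly.
#' @export
read_trace_csv <- function(path, units = c("arbitrary", "ampere", "dff"),
                           label = basename(path)) {
  units <- match.arg(units)
  df <- utils::read.csv(path, header = TRUE)
  if (!all(c("time_s", "value") %in% names(df))) {
    stop("trace CSV must have columns `time_s,value`", call. = FALSE)
  }
  dts <- diff(df$time_s)
  dt <- stats::median(dts)
  if (any(abs(dts - dt) > 1e-6 * dt)) {
    stop("trace CSV is not uniformly sampled (tolerance 1 ppm)", call. = FALSE)
  }
  glu_ts(df$value, dt = dt, t0 = df$time_s[1], units = units, label = label)
}

#' @rdname read_trace_csv
#' @param ts A `glu_ts`.
#' @export
write_trace_csv <- function(ts, path) {
  stopifnot_ts(ts)
  utils::write.csv(
    data.frame(time_s = ts_time(ts), value = ts$values),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

# clone a ts with new values
ts_with <- function(ts, values, units = ts$units) {
  glu_ts(values, dt = ts$dt, t0 = ts$t0, units = units, label = ts$label)
}
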