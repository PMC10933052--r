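#' Origin-constrained linear regression
#'
#' Fits `y = slope * x` (no intercept): `slope = sum(xy)/sum(x^2)`. The
#' coefficient of determination is reported as `1 - SS_res/SS_tot` with
#' `SS_tot` about the mean of `y`; for an origin-constrained model this can
#' be negative for poor fits and is then reported as-is and flagged. The
#' p-value comes from the t statistic of the slope with `n - 1` degrees of
#' freedom. `d_identity` is the mean squared distance of the points to the
#' identity line, the summary used to judge agreement between two readouts
#' of the same quantity.
#'
#' @param x,y Equal-length numeric vectors (n >= 3); `x` must not be all
#'   zero.
#' @return A `regression_result` tibble (one row): `slope`, `se_slope`,
#'   `r_squared`, `r_squared_flagged`, `p_value`, `d_identity`, `n_points`.
#' @export
regress_through_origin <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("`x` and `y` must be equal-length with n >= 3", call. = FALSE)
  }
  if (all(x == 0)) stop("`x` must not be all zero", call. = FALSE)
  sxx <- sum(x^2)
  slope <- sum(x * y) / sxx
  resid <- y - slope * x
  ss_res <- sum(resid^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  n <- length(x)
  sigma2 <- ss_res / (n - 1)
  se <- sqrt(sigma2 / sxx)
  tval <- if (se > 0) slope / se else Inf
  p <- 2 * stats::pt(-abs(tval), df = n - 1)
  out <- tibble::tibble(
    slope = slope, se_slope = se, r_squared = r2,
    r_squared_flagged = is.na(r2) || r2 < 0,
    p_value = p, d_identity = mean((y - x)^2), n_points = n
  )
  class(out) <- c("regression_result", class(out))
  out
}

#' Compare optical and electrical readouts of the same release sequence
#'
#' Pairs per-stimulus optical responses (fluorescence AUC or deconvolved
#' release peaks) with the corresponding electrical responses (evoked EPSC
#' amplitudes), optionally normalizes each sequence to its first element,
#' and fits an origin-constrained regression of optical on electrical.
#' A slope near 1 with a small `d_identity` indicates the two readouts are
#' linearly related through the underlying glutamate release; saturation of
#' either readout drives the slope away from 1.
#'
#' @param optical,electrical Equal-length per-stimulus response vectors.
#' @param normalize Normalize each sequence to its first element (default
#'   TRUE); rejected when a first element is zero.
#' @return A list: `regression` (a `regression_result`) and `pairs`, a
#'   tibble of the (possibly normalized) paired values.
#' @export
compare_readouts <- function(optical, electrical, normalize = TRUE) {
  if (length(optical) != length(electrical)) {
    stop("readouts must have equal train lengths", call. = FALSE)
  }
  if (normalize) {
    if (optical[1] == 0 || electrical[1] == 0) {
      stop("cannot normalize: a first response is zero", call. = FALSE)
    }
    optical <- optical / optical[1]
    electrical <- electrical / electrical[1]
  }
  list(
    regression = regress_through_origin(electrical, optical),
    pairs = tibble::tibble(stimulus = seq_along(optical),
                           electrical = electrical, optical = optical)
  )
}

#' Two-sided Wilcoxon rank sum test
#'
#' Thin wrapper around the standard rank-sum test with the sample-size
#' policy used throughout the package: exact enumeration when the combined
#' sample size is at most 12 and there are no ties, the normal
#' approximation with tie correction otherwise.
#'
#' @param a,b Numeric samples, each of length >= 3.
#' @return A one-row tibble: `p_value`, `statistic` (rank-sum W of `a`),
#'   `exact`.
#' @export
wilcoxon_rank_sum <- function(a, b) {
  if (length(a) < 3 || length(b) < 3) {
    stop("each group needs at least 3 observations", call. = FALSE)
  }
  ties <- anyDuplicated(c(a, b)) > 0
  use_exact <- (length(a) + length(b)) <= 12 && !ties
  wt <- stats::wilcox.test(a, b, alternative = "two.sided",
                           exact = use_exact, correct = !use_exact)
  tibble::tibble(p_value = wt$p.value, statistic = unname(wt$statistic),
                 exact = use_exact)
}

#' Bonferroni-adjusted significance level
#'
#' `alpha* = alpha / m` for `m` comparisons; summaries display it at three
#' decimals.
#'
#' @param alpha Family-wise level (default 0.05).
#' @param m Number of comparisons (>= 1).
#' @return A one-row tibble: `alpha_adjusted` (exact) and `display`
#'   (rounded to 3 decimals).
#' @export
bonferroni_alpha <- function(alpha = 0.05, m) {
  if (m < 1) stop("`m` must be >= 1", call. = FALSE)
  adj <- alpha / m
  tibble::tibble(alpha_adjusted = adj, display = round(adj, 3))
}

#' Mixed-effects condition contrast with a random cell intercept
#'
#' Maximum-likelihood estimate of a fixed two-level condition effect in
#' `y = beta0 + beta1 * condition + b_cell + e`, with a single Gaussian
#' random intercept per cell, for clustered data (repeated measurements of
#' the same cell). The variance ratio is profiled and optimised
#' numerically; the p-value is a Wald test of the condition effect. On
#' balanced data with zero cell-level variance this collapses to the
#' difference of condition means.
#'
#' @param values Numeric response vector.
#' @param cell_ids Cluster identifiers, one per value.
#' @param condition_labels Two-level condition factor, one per value
#'   (constant within each cell).
#' @return A one-row tibble: `effect` (second level minus first), `se`,
#'   `p_value`, `sigma_cell`, `sigma_resid`, `loglik`.
#' @export
random_intercept_effect <- function(values, cell_ids, condition_labels) {
  y <- as.numeric(values)
  cell <- as.factor(cell_ids)
  cond <- as.factor(condition_labels)
  if (nlevels(cond) != 2) {
    stop("`condition_labels` must have exactly two levels", call. = FALSE)
  }
  if (nlevels(cell) < 2) {
    stop("effect unidentifiable with a single cell", call. = FALSE)
  }
  per_cond <- table(unique(data.frame(cell, cond))$cond)
  if (any(per_cond < 2)) {
    stop("need at least 2 cells per condition", call. = FALSE)
  }
  X <- cbind(1, as.numeric(cond == levels(cond)[2]))
  g <- as.integer(cell)
  N <- length(y)

  # profiled ML: for lambda = sigma_cell^2 / sigma_resid^2,
  # W = (I + lambda Z Z')^{-1} applied through per-cell sums
  quad <- function(lambda, a, b) {
    sa <- rowsum(a, g); sb <- rowsum(b, g)
    ni <- tabulate(g)
    sum(a * b) - sum(lambda / (1 + ni * lambda) * rowSums(sa * sb))
  }
  profile_fit <- function(lambda) {
    xtx <- matrix(c(quad(lambda, X[, 1], X[, 1]), quad(lambda, X[, 1], X[, 2]),
                    quad(lambda, X[, 2], X[, 1]), quad(lambda, X[, 2], X[, 2])),
                  2, 2)
    xty <- c(quad(lambda, X[, 1], y), quad(lambda, X[, 2], y))
    beta <- solve(xtx, xty)
    r <- y - X %*% beta
    rss <- quad(lambda, r[, 1], r[, 1])
    sigma2 <- rss / N
    ni <- tabulate(g)
    ll <- -N / 2 * log(2 * pi * sigma2) - sum(log(1 + ni * lambda)) / 2 - N / 2
    list(beta = beta, sigma2 = sigma2, loglik = ll, xtx = xtx)
  }
  obj <- function(loglam) -profile_fit(exp(loglam))$loglik
  opt <- stats::optimize(obj, interval = c(-25, 15))
  lambda <- exp(opt$minimum)
  # compare against the boundary lambda -> 0 (no cell variance)
  fit0 <- profile_fit(1e-12)
  fit <- profile_fit(lambda)
  if (fit0$loglik > fit$loglik) {
    lambda <- 0
    fit <- profile_fit(1e-12)
  }
  vb <- fit$sigma2 * solve(fit$xtx)
  effect <- fit$beta[2]
  se <- sqrt(vb[2, 2])
  tibble::tibble(
    effect = effect, se = se,
    p_value = 2 * stats::pnorm(-abs(effect / se)),
    sigma_cell = sqrt(lambda * fit$sigma2),
    sigma_resid = sqrt(fit$sigma2),
    loglik = fit$loglik
  )
}

#' First-order Gaussian error propagation
#'
#' Standard error of a derived quantity `f(x_1, ..., x_k)` with independent
#' inputs: `sqrt(sum((df/dx_i)^2 * se_i^2))`, with the gradient supplied
#' analytically at the point of interest.
#'
#' @param gradient Numeric vector of partial derivatives `df/dx_i`.
#' @param se Numeric vector of input standard errors, same length.
#' @return The propagated standard error (scalar).
#' @export
#'
#' @examples
#' # f = x / y at x = 1 +/- 0.1, y = 2 +/- 0
#' propagate_se(gradient = c(1 / 2, -1 / 4), se = c(0.1, 0))
propagate_se <- function(gradient, se) {
  if (length(gradient) != length(se)) {
    stop("`gradient` and `se` must have equal length", call. = FALSE)
  }
  sqrt(sum(gradient^2 * se^2))
}
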