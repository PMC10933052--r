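# Shared fixtures and oracles, all built in code.

# greedy one-to-one matching of detected onsets to ground-truth onsets
match_events <- function(detected_onsets, truth_onsets, tol_s = 1e-3) {
  used <- rep(FALSE, length(detected_onsets))
  hits <- 0L
  for (o in truth_onsets) {
    d <- abs(detected_onsets - o)
    j <- which(d < tol_s & !used)
    if (length(j)) {
      used[j[which.min(d[j])]] <- TRUE
      hits <- hits + 1L
    }
  }
  list(recall = hits / length(truth_onsets),
       precision = if (length(detected_onsets)) hits / length(detected_onsets) else NA_real_)
}

jaccard <- function(a, b) sum(a & b) / sum(a | b)

# morphological dilation of a logical mask by a disc (radius px)
dilate_mask <- function(mask, radius) {
  br <- EBImage::makeBrush(2 * radius + 1, "disc")
  as.matrix(EBImage::imageData(
    EBImage::dilate(EBImage::Image(mask * 1), br))) > 0
}

# instant-rise exponential current trace with events planted at known times
plant_events <- function(onsets, amps, tau, fs = 40000, duration = NULL,
                         noise = 0, seed = NULL) {
  dt <- 1 / fs
  if (is.null(duration)) duration <- max(onsets) + 0.05
  n <- round(duration / dt)
  t <- (seq_len(n) - 1) * dt
  v <- numeric(n)
  onsets <- round(onsets / dt) * dt
  for (j in seq_along(onsets)) {
    k0 <- which(t >= onsets[j] - 1e-12)[1]
    kk <- k0:min(n, k0 + ceiling(12 * tau / dt))
    v[kk] <- v[kk] - amps[j] * exp(-(t[kk] - onsets[j]) / tau)
  }
  if (noise > 0) {
    if (!is.null(seed)) set.seed(seed)
    v <- v + rnorm(n, 0, noise)
  }
  list(ts = glu_ts(v, dt, units = "ampere"), onsets = onsets)
}

# brute-force two-sided exact Wilcoxon rank-sum p-value by enumerating all
# C(m + n, m) assignments of the pooled observations to group one
wilcoxon_enumerate <- function(a, b) {
  m <- length(a); n <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  combs <- utils::combn(m + n, m)
  u_all <- apply(combs, 2, function(idx) sum(r[idx])) - m * (m + 1) / 2
  p <- 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))
  min(1, p)
}
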