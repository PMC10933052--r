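test_that("SNR estimate follows its definition and flags zero noise", {
  dt <- 0.01
  v <- c(rep(0, 500), 0.3 * exp(-(0:99) * dt / 0.038))
  bw <- c(0, 4.99)
  set.seed(13)
  noisy <- v + rnorm(length(v), 0, 0.005)
  s <- estimate_snr(glu_ts(noisy, dt, units = "dff"), bw)
  expect_equal(s$snr, 3600, tolerance = 0.2) # (0.3/0.005)^2 up to sampling
  expect_false(s$infinite)

  clean <- estimate_snr(glu_ts(v + 1e-30, dt, units = "dff"), bw)
  expect_true(clean$infinite)

  # the estimate is consistent over seeds (slight upward bias is inherent:
  # the maximum response amplitude rides on the noise)
  set.seed(17)
  snrs <- replicate(50, {
    y <- v + rnorm(length(v), 0, 0.005)
    estimate_snr(glu_ts(y, dt, units = "dff"), bw)$snr
  })
  expect_equal(mean(snrs), 3600, tolerance = 0.1)
})

test_that("Wiener deconvolution inverts its own kernel", {
  dt <- 0.01
  tau <- 38.43e-3
  h <- exp(-(0:299) * dt / tau)
  h <- h / (sum(h) * dt)
  km <- kernel_model(tau = tau)

  # the kernel itself maps to a unit impulse at t0
  w <- wiener_deconvolve(glu_ts(h, dt, units = "dff"), km, snr = Inf)
  expect_equal(which.max(w$values), 1L)
  expect_lt(max(abs(w$values[-1])) / max(w$values), 1e-6)

  # shift theorem: a delayed kernel maps to a delayed impulse
  h50 <- c(rep(0, 5), h[1:295])
  w50 <- wiener_deconvolve(glu_ts(h50, dt, units = "dff"), km, snr = Inf)
  expect_equal(which.max(w50$values), 6L)

  expect_error(wiener_deconvolve(glu_ts(h, dt), km, snr = -1), "positive")
})

test_that("linear deconvolution zeroes matched decays and handles constants", {
  dt <- 1e-3
  tau <- 38.43e-3
  t <- (0:999) * dt
  s <- exp(-t / tau)
  r <- linear_deconvolve(glu_ts(s, dt, units = "dff"), tau)
  # after the onset sample the release rate is ~0 relative to the onset spike
  expect_lt(max(abs(r$values[3:998])), 1e-3 * 1 / dt)
  expect_gt(r$values[1], 0)
  expect_true(r$last_sample_copied)

  # constant signal: r = c / tau everywhere
  rc <- linear_deconvolve(glu_ts(rep(0.2, 100), dt, units = "dff"), tau)
  expect_equal(rc$values, rep(0.2 / tau, 100), tolerance = 1e-12)
})

test_that("deconvolution error propagation behaves as specified", {
  dt <- 0.01
  tau <- 38.43e-3
  s <- 0.3 * exp(-(0:99) * dt / tau)
  d <- linear_deconvolve(glu_ts(s, dt, units = "dff"), tau,
                         sigma_s = 0.01, sigma_tau = 1e-3)
  expect_true(all(d$sigma >= 0))
  expect_equal(d$sigma[1],
               sqrt(2 * 0.01^2 / dt^2 + 0.01^2 / tau^2 +
                      (s[1] / tau^2)^2 * (1e-3)^2),
               tolerance = 1e-12)

  # sigma decreases with dt at fixed sigma_s (2 sigma_s^2/dt^2 dominates)
  d2 <- linear_deconvolve(glu_ts(s[seq(1, 99, by = 2)], 2 * dt,
                                 units = "dff"), tau, sigma_s = 0.01)
  expect_lt(d2$sigma[1], d$sigma[1])

  # the printed linear form is available verbatim behind a flag
  dp <- linear_deconvolve(glu_ts(s, dt, units = "dff"), tau,
                          sigma_s = 0.01, sigma_tau = 1e-3,
                          error_form = "printed")
  expect_equal(dp$sigma[1],
               2 * 0.01 / dt - 0.01 / tau - s[1] * 1e-3 / tau^2,
               tolerance = 1e-12)
})

test_that("both deconvolution methods are linear operators", {
  dt <- 0.01
  tau <- 38.43e-3
  set.seed(19)
  s1 <- abs(stats::filter(rnorm(128), rep(1, 8), sides = 1)); s1[is.na(s1)] <- 0
  s2 <- abs(stats::filter(rnorm(128), rep(1, 4), sides = 1)); s2[is.na(s2)] <- 0
  mix <- glu_ts(as.numeric(2 * s1 + 5 * s2), dt, units = "dff")
  km <- kernel_model(tau = tau)

  wmix <- wiener_deconvolve(mix, km, snr = 100)$values
  w1 <- wiener_deconvolve(glu_ts(as.numeric(s1), dt, units = "dff"), km, 100)$values
  w2 <- wiener_deconvolve(glu_ts(as.numeric(s2), dt, units = "dff"), km, 100)$values
  expect_equal(wmix, 2 * w1 + 5 * w2, tolerance = 1e-9)

  lmix <- linear_deconvolve(mix, tau)$values
  l1 <- linear_deconvolve(glu_ts(as.numeric(s1), dt, units = "dff"), tau)$values
  l2 <- linear_deconvolve(glu_ts(as.numeric(s2), dt, units = "dff"), tau)$values
  expect_equal(lmix, 2 * l1 + 5 * l2, tolerance = 1e-9)
})

test_that("round trip recovers per-pulse impulse weights from the forward model", {
  prot <- stim_protocol(0.2 + (0:3) * 0.1)
  quanta <- c(12, 6, 4, 3)
  cfg <- synth_config(noise_frames = 0)
  fl <- render_fluorescence(quanta, prot, cfg)

  dec <- linear_deconvolve(fl$dff, cfg$kernel$tau)
  rel <- cumulative_release(dec, prot, statistic = "integral")$release
  expect_equal(rel / rel[1] * 12, quanta, tolerance = 0.02)

  w <- wiener_deconvolve(fl$dff, cfg$kernel, snr = Inf)
  relw <- cumulative_release(w, prot, statistic = "integral")$release
  expect_equal(relw / relw[1] * 12, quanta, tolerance = 0.05)

  # the two families agree on relative release (both applied in practice)
  expect_equal(rel / rel[1], relw / relw[1], tolerance = 0.1)

  # 10% at 1% frame noise for the linear method
  cfgn <- synth_config(noise_frames = 0.01 * 0.3 * 1000)
  fln <- render_fluorescence(quanta, prot, cfgn, seed = 23)
  decn <- linear_deconvolve(fln$dff, cfg$kernel$tau)
  reln <- cumulative_release(decn, prot, statistic = "integral")$release
  expect_equal(reln / reln[1] * 12, quanta, tolerance = 0.1)
})

test_that("tau estimation is exact noiseless and an upper bound with late release", {
  cfg <- synth_config(noise_frames = 0)
  prot <- stim_protocol(0.2)
  fl <- render_fluorescence(12, prot, cfg, tail_s = 0.6)
  est <- estimate_tau(fl$dff, c(0.25, 0.7))
  expect_equal(est$tau, cfg$kernel$tau, tolerance = 1e-6)
  expect_true(est$upper_bound)

  # 1% noise: within 5% of 38.43 ms
  cfgn <- synth_config(noise_frames = 0.01 * 0.3 * 1000)
  fln <- render_fluorescence(12, prot, cfgn, tail_s = 0.6, seed = 29)
  estn <- estimate_tau(fln$dff, c(0.25, 0.7))
  expect_equal(estn$tau, 38.43e-3, tolerance = 0.05)

  # residual late release biases the estimate upward, never downward
  late <- stim_protocol(c(0.2, 0.26, 0.32, 0.38))
  fll <- render_fluorescence(c(12, 2, 1, 1), late, cfg, tail_s = 0.6)
  estl <- estimate_tau(fll$dff, c(0.25, 0.9))
  expect_gte(estl$tau, cfg$kernel$tau - 1e-9)
})

test_that("deconvolved cumulative release feeds the shared pool estimator", {
  prot <- stim_train(25, 100, t_start = 0.2)
  sim <- simulate_pool_train(prot, pool_model(100, 0.3, 0),
                             mode = "deterministic")
  cfg <- synth_config(noise_frames = 0)
  fl <- render_fluorescence(sim$released, prot, cfg)
  dec <- linear_deconvolve(fl$dff, cfg$kernel$tau)
  cr <- cumulative_release(dec, prot)
  est <- y1_over_intercept(cr$release, 10)
  expect_equal(est$p_apparent, 0.3, tolerance = 0.02 / 0.3)

  # homogeneity: scaling the rate scales cumulative release linearly
  dec2 <- dec
  dec2$values <- dec$values * 4
  cr2 <- cumulative_release(dec2, prot)
  expect_equal(cr2$cumulative, 4 * cr$cumulative, tolerance = 1e-9)

  # all-equal release: affine cumulative, intercept flagged
  eq <- y1_over_intercept(rep(1, 25), 10)
  expect_false(eq$reliable)
})
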