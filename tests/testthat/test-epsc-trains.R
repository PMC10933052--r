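test_that("single evoked response round-trips through measure_train", {
  cfg <- synth_config(noise_ephys = 0,
                      pool = pool_model(quantal_amp = 125e-12,
                                        quantal_tau = 0.33e-3))
  prot <- stim_protocol(0.02)
  ep <- render_epsc(12, prot, cfg) # 1.5 nA response, 0.9 ms delay
  tm <- measure_train(ep$ts, prot)
  expect_equal(tm$amplitude, 12 * 125e-12, tolerance = 1e-6)
  expect_lt(abs(tm$syn_delay - 0.9e-3), 2 / cfg$ephys_fs)
  expect_equal(tm$tau_decay, 0.33e-3, tolerance = 0.02)
})

test_that("deterministic depressing train amplitudes match the forward model", {
  prot <- stim_train(25, 100)
  sim <- simulate_pool_train(prot, pool_model(100, 0.3, 0),
                             mode = "deterministic")
  cfg <- synth_config(noise_ephys = 0,
                      pool = pool_model(quantal_amp = 127e-12,
                                        quantal_tau = 0.33e-3))
  ep <- render_epsc(sim$released, prot, cfg)
  tm <- measure_train(ep$ts, prot)
  expect_equal(tm$amplitude, sim$released * 127e-12, tolerance = 0.01)
  expect_true(all(diff(tm$cumulative_amplitude) >= 0))
})

test_that("paired-pulse ratio: arithmetic, depletion closed form, edge cases", {
  m <- tibble::tibble(amplitude = c(2.0e-9, 1.64e-9))
  expect_equal(paired_pulse_ratio(m)$ppr, 0.82)
  expect_equal(paired_pulse_ratio(tibble::tibble(amplitude = c(1, 1)))$ppr, 1)
  expect_false(paired_pulse_ratio(tibble::tibble(amplitude = c(0, 1)))$defined)

  # depletion-only pool, p_r = 0.3: PPR = 1 - p_r exactly
  prot <- stim_protocol(c(0.05, 0.06))
  sim <- simulate_pool_train(prot, pool_model(100, 0.3, 0),
                             mode = "deterministic")
  cfg <- synth_config(noise_ephys = 0,
                      pool = pool_model(quantal_tau = 0.33e-3))
  tm <- measure_train(render_epsc(sim$released, prot, cfg)$ts, prot)
  expect_equal(paired_pulse_ratio(tm)$ppr, 0.7, tolerance = 1e-6)
})

test_that("SMN back-extrapolation recovers deterministic pool parameters", {
  prot <- stim_train(25, 100)
  sim <- simulate_pool_train(prot, pool_model(100, 0.3, 0),
                             mode = "deterministic")
  # work in units of the pool (quantal amplitude 0.1 units for concreteness)
  est <- y1_over_intercept(sim$released * 0.1, fit_last_k = 10)
  expect_true(est$reliable)
  # the geometric approach to steady state leaves a ~0.3% residual in the
  # intercept and a small positive slope at p_r = 0.3 over 25 stimuli
  expect_equal(est$y_intercept, 10, tolerance = 0.01)
  expect_equal(est$p_apparent, 0.3, tolerance = 0.005 / 0.3)
  expect_lt(abs(est$slope) / est$y_intercept, 1e-3)

  # constant amplitudes: intercept 0, flagged unreliable
  flat <- y1_over_intercept(rep(2, 25), fit_last_k = 10)
  expect_false(flat$reliable)

  # depletion + constant refill R per ISI: slope ~ R, intercept ~ effective pool
  pool <- pool_model(100, 0.3, refill_rate = 500) # 5 vesicles per 10 ms ISI
  simr <- simulate_pool_train(stim_train(40, 100), pool,
                              mode = "deterministic")
  estr <- y1_over_intercept(simr$released, fit_last_k = 10)
  # steady state of N' = (N - 0.3 N) + 5: N_ss = 5/0.3, release 5 per stimulus
  expect_equal(estr$slope, 5, tolerance = 0.01)
  expect_gt(estr$y_intercept, 0)

  # full smn_analysis wrapper: refill rate in units/ms
  tm <- tibble::tibble(amplitude = sim$released * 0.1)
  pe <- smn_analysis(tm, prot, fit_last_k = 10)
  expect_equal(pe$rrp, 10, tolerance = 0.01)
  expect_equal(pe$refill_rate, pe$slope / 10, tolerance = 1e-9)
  expect_error(smn_analysis(tm, stim_protocol(c(0, 0.01, 0.05))), "constant-rate")
})

test_that("p_apparent converges to p_r for depletion-only pools", {
  # at 25 stimuli the steady-state residual is below 0.005 for p_r >= 0.3;
  # weaker depression needs longer trains for the same accuracy
  for (p in c(0.3, 0.5, 0.7)) {
    sim <- simulate_pool_train(stim_train(25, 100), pool_model(100, p, 0),
                               mode = "deterministic")
    est <- y1_over_intercept(sim$released, fit_last_k = 10)
    expect_lt(abs(est$p_apparent - p), 0.005)
  }
  sim20 <- simulate_pool_train(stim_train(40, 100), pool_model(100, 0.2, 0),
                               mode = "deterministic")
  expect_lt(abs(y1_over_intercept(sim20$released, 10)$p_apparent - 0.2), 0.005)

  # error shrinks monotonically with train length at fixed p_r
  errs <- vapply(c(25, 30, 40), function(n) {
    sim <- simulate_pool_train(stim_train(n, 100), pool_model(100, 0.2, 0),
                               mode = "deterministic")
    abs(y1_over_intercept(sim$released, 10)$p_apparent - 0.2)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("pool estimators are scale invariant", {
  sim <- simulate_pool_train(stim_train(25, 100), pool_model(100, 0.3, 0),
                             mode = "deterministic")
  base <- y1_over_intercept(sim$released, 10)
  for (c in c(1e-9, 0.37, 120)) {
    scaled <- y1_over_intercept(sim$released * c, 10)
    expect_equal(scaled$p_apparent, base$p_apparent, tolerance = 1e-9)
  }
  m1 <- tibble::tibble(amplitude = c(2, 1.4))
  m2 <- tibble::tibble(amplitude = c(2, 1.4) * 3.7)
  expect_equal(paired_pulse_ratio(m1)$ppr, paired_pulse_ratio(m2)$ppr)
})

test_that("stochastic binomial trains recover p_r within 0.05", {
  prot <- stim_train(25, 100)
  pool <- pool_model(100, 0.3, 0)
  cfg <- synth_config(pool = pool_model(quantal_amp = 127e-12,
                                        quantal_tau = 0.33e-3))
  ps <- vapply(1:20, function(k) {
    sim <- simulate_pool_train(prot, pool, mode = "stochastic", seed = 100 + k)
    ep <- render_epsc(sim$released, prot, cfg, seed = 200 + k)
    smn_analysis(measure_train(ep$ts, prot), prot)$p_apparent
  }, numeric(1))
  expect_lt(abs(mean(ps) - 0.3), 0.05)
})
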