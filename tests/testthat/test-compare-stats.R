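test_that("origin-constrained regression matches closed forms", {
  x <- c(1, 2, 3, 4)
  r <- regress_through_origin(x, 2 * x)
  expect_equal(r$slope, 2, tolerance = 1e-12)
  expect_equal(r$r_squared, 1, tolerance = 1e-12)
  expect_equal(r$d_identity, mean(x^2), tolerance = 1e-12)
  expect_lt(r$p_value, 0.01)

  ident <- regress_through_origin(x, x)
  expect_equal(ident$slope, 1, tolerance = 1e-12)
  expect_equal(ident$d_identity, 0)

  # d_identity estimates the residual variance about the identity
  set.seed(31)
  xs <- runif(100, 1, 3)
  ys <- xs + rnorm(100, 0, 0.2)
  rr <- regress_through_origin(xs, ys)
  expect_equal(rr$d_identity, 0.04, tolerance = 0.2)

  expect_error(regress_through_origin(rep(0, 5), 1:5), "zero")

  # scale equivariance: (cx, y) -> slope / c
  base <- regress_through_origin(xs, ys)$slope
  expect_equal(regress_through_origin(3 * xs, ys)$slope, base / 3,
               tolerance = 1e-12)
})

test_that("readout comparison flags agreement and detects saturation", {
  q <- 100 * 0.25 * 0.75^(0:9) # depressing release sequence
  same <- compare_readouts(q, q)
  expect_equal(same$regression$slope, 1, tolerance = 1e-12)
  expect_equal(same$regression$d_identity, 0)

  # rescaling either readout changes nothing under normalization
  resc <- compare_readouts(q * 3.7, q * 0.02)
  expect_equal(resc$regression$slope, 1, tolerance = 1e-12)

  # a saturating optical readout is detected as nonlinearity:
  # in absolute (linear-regime-calibrated) units the slope drops below 1,
  # while under first-pulse normalization of a depressing train the same
  # concave transform inflates later points (slope above 1)
  k <- 0.5 * max(q)
  sat <- q / (1 + q / k)
  cal <- compare_readouts(sat, q, normalize = FALSE)
  expect_lt(cal$regression$slope, 1)
  expect_gt(cal$regression$d_identity, 0)
  norm <- compare_readouts(sat, q, normalize = TRUE)
  expect_gt(norm$regression$slope, 1)

  expect_error(compare_readouts(c(0, 1), c(1, 2)), "zero")
})

test_that("full optical/electrical pipeline agrees linearly on shared quanta", {
  prot <- stim_protocol(0.2 + (0:9) * 0.1)
  sim <- simulate_pool_train(prot, pool_model(100, 0.25, 0),
                             mode = "deterministic")
  cfgf <- synth_config(noise_frames = 0)
  cfge <- synth_config(noise_ephys = 0,
                       pool = pool_model(quantal_tau = 0.33e-3))
  fl <- render_fluorescence(sim$released, prot, cfgf)
  dec <- linear_deconvolve(fl$dff, cfgf$kernel$tau)
  optical <- cumulative_release(dec, prot)$release
  electrical <- measure_train(render_epsc(sim$released, prot, cfge)$ts,
                              prot)$amplitude
  cmp <- compare_readouts(optical, electrical)
  expect_equal(cmp$regression$slope, 1, tolerance = 0.03)
  expect_lt(cmp$regression$d_identity, 1e-4)
})

test_that("Wilcoxon wrapper reproduces brute-force exact enumeration", {
  # frozen example: two fully separated groups of four
  w <- wilcoxon_rank_sum(1:4, 5:8)
  expect_true(w$exact)
  expect_equal(w$p_value, 2 / 70, tolerance = 1e-12)

  # identical multisets give p = 1
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$p_value, 1)

  # full oracle sweep over random small samples without ties
  set.seed(37)
  for (rep in 1:20) {
    m <- sample(3:5, 1); n <- sample(3:5, 1)
    vals <- sample(1000, m + n) / 10
    a <- vals[seq_len(m)]; b <- vals[-seq_len(m)]
    expect_equal(wilcoxon_rank_sum(a, b)$p_value, wilcoxon_enumerate(a, b),
                 tolerance = 1e-12)
  }

  # power under a 2 sigma shift at n = 20/20
  set.seed(41)
  rej <- mean(replicate(300, {
    wilcoxon_rank_sum(rnorm(20), rnorm(20, 2))$p_value < 0.05
  }))
  expect_gt(rej, 0.9)

  expect_error(wilcoxon_rank_sum(1:2, 1:5), "at least 3")
})

test_that("Bonferroni-adjusted levels reproduce the published table values", {
  expect_equal(bonferroni_alpha(0.05, 1)$alpha_adjusted, 0.05)
  # five mEPSC comparisons -> 0.010; four PPR comparisons -> displays 0.013
  expect_equal(bonferroni_alpha(0.05, 5)$alpha_adjusted, 0.010)
  expect_equal(bonferroni_alpha(0.05, 4)$alpha_adjusted, 0.0125)
  expect_equal(bonferroni_alpha(0.05, 4)$display, 0.013)
  expect_error(bonferroni_alpha(0.05, 0), ">= 1")
})

test_that("random-intercept model matches lme4 ML and collapses correctly", {
  skip_if_not_installed("lme4")
  set.seed(5)
  cells <- rep(1:12, each = 25)
  cond <- rep(rep(c("a", "b"), each = 6), each = 25)
  y <- 0.5 * (cond == "b") + rep(rnorm(12, 0, 1), each = 25) + rnorm(300)
  mine <- random_intercept_effect(y, cells, cond)
  ref <- lme4::lmer(y ~ cond + (1 | cells), REML = FALSE)
  expect_equal(mine$effect, unname(lme4::fixef(ref)[2]), tolerance = 1e-4)
  expect_equal(mine$se, sqrt(as.numeric(lme4::vcov.merMod(ref)[2, 2])),
               tolerance = 1e-3)
  expect_equal(mine$loglik, as.numeric(stats::logLik(ref)), tolerance = 1e-6)

  # zero cell variance: effect equals the difference of condition means
  set.seed(43)
  y0 <- 2 * (cond == "b") + rnorm(300)
  m0 <- random_intercept_effect(y0, cells, cond)
  expect_equal(m0$effect, mean(y0[cond == "b"]) - mean(y0[cond == "a"]),
               tolerance = 1e-6)

  expect_error(random_intercept_effect(1:10, rep(1, 10), rep(c("a", "b"), 5)),
               "single cell")
})

test_that("random-intercept Wald test holds its nominal size", {
  set.seed(11)
  rej <- 0L
  for (s in 1:50) {
    cells <- rep(1:12, each = 20)
    cond <- rep(rep(c("a", "b"), 6), each = 20)
    y <- rep(rnorm(12), each = 20) + rnorm(240)
    p <- random_intercept_effect(y, cells, cond)$p_value
    rej <- rej + (p < 0.05)
  }
  expect_lt(abs(rej / 50 - 0.05), 0.03 + 1e-9)
})

test_that("parameter recovery of a true condition effect", {
  set.seed(47)
  cells <- rep(1:24, each = 50)
  cond <- rep(rep(c("a", "b"), each = 12), each = 50)
  y <- 1 * (cond == "b") + rep(rnorm(24, 0, 1), each = 50) + rnorm(1200)
  m <- random_intercept_effect(y, cells, cond)
  expect_lt(abs(m$effect - 1), 2 * m$se)
})

test_that("Gaussian error propagation matches closed forms and Monte-Carlo", {
  # f = x/y with x = 1 +/- 0.1, y = 2 exactly
  expect_equal(propagate_se(c(1 / 2, -1 / 4), c(0.1, 0)), 0.05)
  # f = x + y with equal sigma
  expect_equal(propagate_se(c(1, 1), c(0.3, 0.3)), 0.3 * sqrt(2))
  # ratio against a large Monte-Carlo at CV <= 0.1
  set.seed(53)
  x <- 1; y <- 2; sx <- 0.08; sy <- 0.1
  mc <- stats::sd(rnorm(1e5, x, sx) / rnorm(1e5, y, sy))
  an <- propagate_se(c(1 / y, -x / y^2), c(sx, sy))
  expect_equal(an, mc, tolerance = 0.1)
})
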