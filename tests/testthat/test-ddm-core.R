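test_that("parameter validation enforces the model invariants", {
  expect_s3_class(ref_params(), "ddm_params")
  expect_error(ddm_params(v = 0.2, a = -0.1), "a")
  expect_error(ddm_params(v = 0.2, a = 0.1, z_rel = 1.2), "z_rel")
  expect_error(ddm_params(v = 0.2, a = 0.1, z_rel = 0.5, sz = 0.2), "sz")
  expect_error(ddm_params(v = 0.2, a = 0.1, ter = 0.1, st = 0.3), "st")
})

test_that("choice probabilities are stable and sum to one", {
  p <- ref_params()
  pu <- ddm_choice_prob(p, "upper")
  pl <- ddm_choice_prob(p, "lower")
  expect_equal(pu + pl, 1, tolerance = 1e-12)
  # closed form at central start with no variability: logistic in va/s^2
  p0 <- ref_params(eta = 0, sz = 0, st = 0)
  expect_equal(ddm_choice_prob(p0, "upper"),
               plogis(p0$v * p0$a / p0$s^2), tolerance = 1e-9)
  # near-zero drift limit is continuous
  peps <- ref_params(v = 1e-12, z_rel = 0.3, eta = 0)
  expect_equal(ddm_choice_prob(peps, "upper"), 0.3, tolerance = 1e-6)
})

test_that("density integrates to the choice probability on both boundaries", {
  p <- ref_params(v = 0.15, z_rel = 0.45)
  for (b in c("upper", "lower")) {
    expect_equal(density_mass(p, 0, Inf, b), ddm_choice_prob(p, b),
                 tolerance = 1e-6)
  }
})

test_that("CDF matches the integral of the density across regimes", {
  p <- ref_params(v = 0.25, z_rel = 0.4)
  for (t1 in c(0.36, 0.45, 0.8, 2)) {   # spans small- and large-time series
    expect_equal(ddm_fpt_cdf(t1, p, "upper"),
                 density_mass(p, 0, t1, "upper"), tolerance = 1e-6)
  }
  expect_equal(ddm_fpt_cdf(50, p, "lower"), ddm_choice_prob(p, "lower"),
               tolerance = 1e-7)
})

test_that("reflection symmetry: upper(v, z) equals lower(-v, 1 - z)", {
  p1 <- ref_params(v = 0.18, z_rel = 0.42)
  p2 <- ref_params(v = -0.18, z_rel = 0.58)
  tg <- c(0.4, 0.6, 1, 2)
  expect_equal(ddm_fpt_density(tg, p1, "upper"),
               ddm_fpt_density(tg, p2, "lower"), tolerance = 1e-12)
  expect_equal(ddm_fpt_cdf(tg, p1, "upper"),
               ddm_fpt_cdf(tg, p2, "lower"), tolerance = 1e-12)
})

test_that("the diffusion coefficient is a pure scale parameter", {
  p1 <- ref_params(s = 0.1)
  p2 <- ddm_params(v = p1$v * 10, a = p1$a * 10, z_rel = p1$z_rel,
                   ter = p1$ter, eta = p1$eta * 10, sz = p1$sz * 10,
                   st = p1$st, s = 1)
  tg <- c(0.4, 0.7, 1.5)
  expect_equal(ddm_fpt_density(tg, p1, "upper"),
               ddm_fpt_density(tg, p2, "upper"), tolerance = 1e-9)
  expect_equal(ddm_choice_prob(p1, "lower"), ddm_choice_prob(p2, "lower"),
               tolerance = 1e-12)
})

test_that("quantiles are monotone and invert the conditional CDF", {
  p <- ref_params()
  probs <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  q <- ddm_fpt_quantiles(p, probs, "upper")
  expect_true(all(diff(q) > 0))
  pb <- ddm_choice_prob(p, "upper")
  expect_equal(ddm_fpt_cdf(q, p, "upper") / pb, probs, tolerance = 1e-6)
})

test_that("a vanishing boundary mass raises the degenerate-cell condition", {
  p <- ref_params(v = 1.9, eta = 0, sz = 0, st = 0)  # P(lower) ~ 0
  expect_error(ddm_fpt_quantiles(p, 0.5, "lower"),
               class = "siddm_degenerate_cell")
})

test_that("bin probabilities partition the choice probabilities", {
  p <- ref_params(v = 0.1)
  eu <- c(0.45, 0.55, 0.7, 0.9, 1.3)
  el <- c(0.5, 0.8)
  bp <- ddm_bin_probs(p, eu, el)
  expect_length(bp, length(eu) + length(el) + 2)
  expect_true(all(bp >= 0))
  expect_equal(sum(bp), 1, tolerance = 1e-7)
  expect_equal(unname(sum(bp[seq_along(c(eu, 0))])),
               ddm_choice_prob(p, "upper"), tolerance = 1e-7)
  # first bin equals the CDF at the first edge
  expect_equal(unname(bp[1]), ddm_fpt_cdf(eu[1], p, "upper"),
               tolerance = 1e-9)
})

test_that("drift variability mixes the no-variability solution correctly", {
  # eta-mixture density equals Gauss-Hermite mixing of eta = 0 densities
  p <- ref_params(eta = 0.08, sz = 0, st = 0)
  tg <- c(0.45, 0.8, 1.6)
  gh <- 32
  # high-order explicit mixture of eta = 0 densities as the reference
  q <- siddm:::gauss_hermite_prob(gh)
  nodes <- q$x * sqrt(2)
  w <- q$w
  mix <- rowSums(sapply(seq_len(gh), function(k) {
    pk <- ref_params(v = p$v + p$eta * nodes[k], eta = 0, sz = 0, st = 0)
    w[k] * ddm_fpt_density(tg, pk, "upper")
  }))
  expect_equal(ddm_fpt_density(tg, p, "upper"), mix, tolerance = 1e-6)
})

test_that("the simulator is seed-deterministic and matches the analytics", {
  p <- ref_params()
  ctl <- ddm_control(dt = 1e-3)
  s1 <- simulate_ddm(p, 500, seed = 9, control = ctl)
  s2 <- simulate_ddm(p, 500, seed = 9, control = ctl)
  s3 <- simulate_ddm(p, 500, seed = 10, control = ctl)
  expect_identical(s1, s2)
  expect_false(identical(s1, s3))
  expect_error(simulate_ddm(p, 10), "seed")
  # choice fractions near the analytic value at moderate n
  s <- simulate_ddm(p, 20000, seed = 3, control = ctl)
  expect_lt(abs(mean(s$boundary == "upper") -
                  ddm_choice_prob(p, "upper")), 0.015)
  expect_true(all(s$rt[s$terminated] >= p$ter - p$st / 2))
})
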