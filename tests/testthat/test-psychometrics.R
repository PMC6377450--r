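test_that("normalization maps the largest magnitude to +-1 and keeps sign", {
  d <- c(-0.03, -0.02, -0.01, 0, 0.01, 0.02, 0.03)
  nd <- normalize_disparity(d)
  expect_equal(range(nd), c(-1, 1))
  expect_equal(sign(nd), sign(d))
  expect_equal(nd, d / 0.03)
})

test_that("a single psychometric fit recovers mu and sigma", {
  pts <- psych_fixture(mu = 0.15, sigma = 0.4, n_per = 400)
  fit <- fit_psychometric(pts)
  expect_true(fit$converged)
  expect_lt(abs(fit$mu - 0.15), 0.05)
  expect_lt(abs(fit$sigma - 0.4), 0.06)
  expect_equal(unname(coef(fit)[["mu"]]), fit$mu)
  # predictions live in [0, 1] and increase with disparity
  pr <- predict(fit, disparity = seq(-1, 1, 0.25), type = "response")
  expect_true(all(pr >= 0 & pr <= 1))
  expect_true(all(diff(pr) > 0))
})

test_that("shift equals the horizontal separation under a shared slope", {
  pl <- psych_fixture(mu = -0.2, sigma = 0.35, n_per = 500, seed = 21)
  pr <- psych_fixture(mu = 0.2, sigma = 0.35, n_per = 500, seed = 22)
  fit <- fit_paired_psychometric(pl, pr, shared_slope = TRUE)
  expect_lt(abs(fit$shift - 0.4), 0.06)
  expect_equal(fit$shift, fit$mu_right - fit$mu_left, tolerance = 1e-10)
})

test_that("shift is equivariant under a common disparity translation", {
  pl <- psych_fixture(mu = -0.1, n_per = 300, seed = 31)
  pr <- psych_fixture(mu = 0.1, n_per = 300, seed = 32)
  s0 <- fit_paired_psychometric(pl, pr)$shift
  pl2 <- pl; pr2 <- pr
  pl2$disparity <- pl$disparity + 0.3
  pr2$disparity <- pr$disparity + 0.3
  s1 <- fit_paired_psychometric(pl2, pr2)$shift
  expect_equal(s0, s1, tolerance = 1e-8)
})

test_that("bootstrap CI covers the shift and requires a seed", {
  pl <- psych_fixture(mu = -0.2, n_per = 200, seed = 41)
  pr <- psych_fixture(mu = 0.2, n_per = 200, seed = 42)
  expect_error(fit_paired_psychometric(pl, pr, n_boot = 10), "seed")
  fit <- fit_paired_psychometric(pl, pr, n_boot = 200, seed = 1)
  expect_length(fit$ci, 2)
  expect_true(fit$ci[1] < fit$shift && fit$shift < fit$ci[2])
  fit2 <- fit_paired_psychometric(pl, pr, n_boot = 200, seed = 1)
  expect_identical(fit$ci, fit2$ci)
})

test_that("two-curve comparison detects a real shift and not a null one", {
  pl <- psych_fixture(mu = -0.25, n_per = 150, seed = 51)
  pr <- psych_fixture(mu = 0.25, n_per = 150, seed = 52)
  cc <- compare_curve_counts(pl, pr, n_perm = 500, seed = 2)
  expect_gt(cc$adj_r2_two, cc$adj_r2_one)
  expect_lt(cc$p_value, 0.01)
  p0 <- psych_fixture(mu = 0, n_per = 150, seed = 53)
  p1 <- psych_fixture(mu = 0, n_per = 150, seed = 54)
  cc0 <- compare_curve_counts(p0, p1, n_perm = 500, seed = 2)
  expect_gt(cc0$p_value, 0.05)
  # seeded determinism of the permutation p-value
  cc0b <- compare_curve_counts(p0, p1, n_perm = 500, seed = 2)
  expect_identical(cc0$p_value, cc0b$p_value)
})

test_that("empty or degenerate advice cells fail loudly", {
  pl <- psych_fixture(n_per = 50)
  empty <- pl[0, ]
  expect_error(fit_paired_psychometric(empty, pl), "advice-left")
  two_lev <- pl[1:2, ]
  expect_error(fit_paired_psychometric(two_lev, pl), "disparity")
})

test_that("per-disparity rank-sum table flags a strong advice effect", {
  prof_k <- 0.3026
  prof <- group_profile("strong", k_v = prof_k,
                        dv_advice = 0.6 * prof_k / 2, n_participants = 8)
  coh <- simulate_cohort(prof, seed = 77, control = ddm_control(dt = 2e-3))
  tab <- advice_effect_by_disparity(apply_exclusions(coh$trials)$trials)
  expect_equal(nrow(tab), 7)
  expect_true(all(c("p", "p_bonf", "significant") %in% names(tab)))
  expect_true(any(tab$significant))
  expect_true(all(tab$direction[tab$significant] == "toward"))
})

test_that("the per-participant fits table has the canonical columns", {
  prof <- group_profile("g", k_v = 0.3026, dv_advice = 0.05,
                        n_participants = 2)
  coh <- simulate_cohort(prof, seed = 5, control = ddm_control(dt = 2e-3))
  fits <- psychometric_summary(apply_exclusions(coh$trials)$trials,
                               n_boot = 50, n_perm = 50, seed = 3)
  expect_equal(nrow(fits), 2)
  expect_true(all(c("participant", "group", "mu_left", "mu_right",
                    "sigma", "shift", "adj_r2_one", "adj_r2_two",
                    "p_two_vs_one", "ci_low", "ci_high", "converged")
                  %in% names(fits)))
})

test_that("threshold recovery: median fitted sigma near the generating one", {
  # cumulative-Gaussian generator at the degree scale, 30 trials/level
  lev <- c(-0.03, -0.02, -0.01, 0, 0.01, 0.02, 0.03)
  sig <- vapply(seq_len(60), function(r) {
    set.seed(1000 + r)
    d <- rep(lev, each = 30)
    resp <- ifelse(stats::rbinom(length(d), 1,
                                 pnorm(d, 0, 0.02)) == 1, "left", "right")
    fit_psychometric(psych_points(d, resp))$sigma
  }, numeric(1))
  expect_lt(abs(stats::median(sig) - 0.02), 0.15 * 0.02)
})
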