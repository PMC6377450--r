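make_fixture_trials <- function(n_per_cell = 60, dv = 0.06, dz = 0.04,
                                seed = 99) {
  siddm:::make_cell_trials(n_per_cell, k_v = 0.3026, dv_advice = dv,
                           z_advice = dz, seed = seed,
                           control = ddm_control(dt = 2e-3))
}

# one medium fixture and one Model-4 fit shared by several tests below
tr_shared <- make_fixture_trials(60, dv = 0.08, dz = 0.04)
fit4_shared <- suppressWarnings(fit_ddm(tr_shared, model = 4,
                                        restarts = 1, seed = 6,
                                        max_iter = 90))

test_that("model specifications have the documented parameter counts", {
  d7 <- seq(-1, 1, length.out = 7)
  ks <- vapply(1:5, function(m) ddm_model_spec(m, d7)$k, numeric(1))
  expect_equal(ks, c(13, 14, 20, 21, 26))
  # strict tying frees the five nuisance parameters per disparity
  expect_equal(ddm_model_spec(1, d7, strict = TRUE)$k, 13 + 5 * 6)
  expect_error(ddm_model_spec(6, d7), "unknown model")
})

test_that("BIC follows k*ln(n) - 2*logLik", {
  expect_equal(bic_score(-100, 3, 50), 3 * log(50) + 200)
})

test_that("a small Model-1 fit runs end to end with working methods", {
  tr <- make_fixture_trials(40, dv = 0, dz = 0)
  fit <- suppressWarnings(fit_ddm(tr, model = 1, restarts = 1, seed = 2,
                                  max_iter = 60))
  expect_s3_class(fit, "ddm_fit")
  expect_equal(fit$k, 13)
  expect_equal(fit$n, nrow(tr[!tr$excluded, ]))
  expect_equal(unname(attr(logLik(fit), "df")), 13)
  expect_equal(fit$bic, bic_score(fit$loglik, fit$k, fit$n))
  cf <- coef(fit)
  expect_length(cf, 13)
  expect_true(all(c("a", "ter", "eta") %in% substr(names(cf), 1, 3)))
  pc <- predict(fit, type = "choice")
  expect_equal(nrow(pc), 14)
  expect_true(all(pc$p_left > 0 & pc$p_left < 1))
  # P(left) must increase with disparity at fixed advice
  left <- pc[pc$advice == "left", ]
  expect_true(all(diff(left$p_left[order(left$disparity)]) > 0))
  sim <- simulate(fit, nsim = 1, seed = 4)
  expect_equal(nrow(sim), fit$n)
  expect_error(simulate(fit), "seed")
  expect_output(print(summary(fit)), "Per-cell estimates")
})

test_that("fits are deterministic given the seed", {
  tr <- make_fixture_trials(25, dv = 0, dz = 0)
  f1 <- suppressWarnings(fit_ddm(tr, model = 1, restarts = 2, seed = 5,
                                 max_iter = 30))
  f2 <- suppressWarnings(fit_ddm(tr, model = 1, restarts = 2, seed = 5,
                                 max_iter = 30))
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$loglik, f2$loglik)
})

test_that("advice-split structure matches each model's tying", {
  f2 <- suppressWarnings(fit_ddm(tr_shared, model = 2, restarts = 1,
                                 seed = 3, max_iter = 60))
  s2 <- siddm:::advice_split_summary(f2)
  expect_true(all(s2$dv_advice == 0))        # drift tied in Model 2
  expect_false(isTRUE(all.equal(s2$z_left[1], s2$z_right[1])))
  f3 <- suppressWarnings(fit_ddm(tr_shared, model = 3, restarts = 1,
                                 seed = 3, max_iter = 60))
  s3 <- siddm:::advice_split_summary(f3)
  expect_equal(s3$z_left, s3$z_right)        # start point tied in Model 3
  # Model 4 frees both; on this generator both effects appear
  s4 <- siddm:::advice_split_summary(fit4_shared)
  expect_gt(mean(s4$dv_advice), 0)
  expect_gt(s4$z_left[1], s4$z_right[1])
})

test_that("warm-chained fits respect nesting in log-likelihood", {
  fits <- suppressWarnings(fit_ddm_set(tr_shared, models = c(1, 3),
                                       restarts = 1, seed = 11,
                                       max_iter = 60))
  expect_s3_class(fits, "ddm_fit_list")
  # the richer nested model cannot fit worse when warm-started
  expect_gte(fits[["3"]]$loglik, fits[["1"]]$loglik - 0.5)
  cmp <- compare_ddm(c(fits, list(`4` = fit4_shared)))
  expect_s3_class(cmp, "ddm_comparison")
  expect_equal(nrow(cmp$table), 3)
  expect_equal(cmp$best, 4)  # the generator has both advice effects
})

test_that("comparing fits of different data errors out", {
  tr1 <- make_fixture_trials(20, seed = 1)
  f1 <- suppressWarnings(fit_ddm(tr1, 1, restarts = 1, seed = 1,
                                 max_iter = 20))
  expect_error(compare_ddm(list(f1, fit4_shared)), "same trial set")
})

test_that("empty cells and missing data are rejected or handled", {
  gone <- tr_shared[!(tr_shared$disparity_norm == 1 &
                        tr_shared$advice == "left"), ]
  expect_error(suppressWarnings(fit_ddm(gone, 1, restarts = 1, seed = 1)),
               "empty disparity-by-advice cell")
})

test_that("bootstrap CIs are seed-deterministic and cover the truth", {
  ci <- suppressWarnings(ddm_param_cis(fit4_shared, tr_shared,
                                       n_boot = 30, seed = 9,
                                       max_iter = 15))
  ci2 <- suppressWarnings(ddm_param_cis(fit4_shared, tr_shared,
                                        n_boot = 30, seed = 9,
                                        max_iter = 15))
  expect_identical(ci$table, ci2$table)
  expect_true(all(c("param", "estimate", "lower", "upper", "flag")
                  %in% names(ci$table)))
  dv_row <- ci$table[ci$table$param == "dv_mean", ]
  # true advice drift difference is 2 * 0.08 = 0.16
  expect_true(dv_row$lower <= 0.16 * 1.4 && dv_row$upper >= 0.16 * 0.6)
})

test_that("diagnostics report calibrated choice and CDF tables", {
  dg <- ddm_diagnostics(fit4_shared, tr_shared, grid_n = 20)
  expect_s3_class(dg, "ddm_diagnostics")
  expect_equal(nrow(dg$choice), 14)
  expect_lt(dg$max_choice_gap, 0.1)
  expect_true(all(dg$cdf$predicted >= -1e-9 & dg$cdf$predicted <= 1))
  # observed and expected bin counts total the same trials
  expect_equal(sum(dg$bins$observed), sum(!tr_shared$excluded))
  expect_equal(sum(dg$bins$expected), sum(!tr_shared$excluded),
               tolerance = 0.01)
})

test_that("conformity splits carry the conditioning caveat", {
  sp <- suppressWarnings(split_by_conformity(tr_shared, model = 1,
                                             restarts = 1,
                                             max_iter = 30))
  expect_match(sp$caveat, "conditioned")
  expect_equal(sp$n_conformed + sp$n_nonconformed,
               sum(!tr_shared$excluded))
  dc <- drift_by_conformity(tr_shared, fit4_shared)
  expect_match(dc$caveat, "descriptive")
  expect_equal(nrow(dc$medians), 4)
  # conformed responses imply drift pulled toward the advice direction
  med <- dc$medians
  v_conf_left <- med$v[med$advice == "left" & med$conformed]
  v_nonconf_left <- med$v[med$advice == "left" & !med$conformed]
  expect_gt(v_conf_left, v_nonconf_left)
})
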