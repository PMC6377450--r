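test_that("disparity levels follow the 7-level symmetric design", {
  for (rng in c("high", "mid", "low")) {
    lev <- disparity_levels(rng)
    expect_length(lev, 7)
    expect_true(0 %in% lev)
    expect_equal(sort(lev), sort(-lev))
  }
  expect_equal(disparity_levels("mid"), c(-0.03, -0.02, -0.01, 0,
                                          0.01, 0.02, 0.03))
  expect_error(disparity_levels("huge"))
})

test_that("trial design: 210 trials, 30 per level, 2:1 advice validity", {
  des <- trial_design("mid", seed = 3)
  expect_equal(nrow(des), 210)
  counts <- table(des$disparity)
  expect_true(all(counts == 30))
  for (d in setdiff(unique(des$disparity), 0)) {
    sub <- des[des$disparity == d, ]
    expect_equal(mean(sub$advice_correct), 2 / 3)
  }
  zero <- des[des$disparity == 0, ]
  expect_equal(sum(zero$advice == "left"), 15)
  expect_true(all(is.na(zero$advice_correct)))
  expect_equal(as.vector(table(des$block)), rep(21L, 10))
  # 3 trials of every disparity in every block
  expect_true(all(table(des$block, des$disparity) == 3))
  # seeded determinism and seed sensitivity
  expect_identical(des, trial_design("mid", seed = 3))
  expect_false(identical(des, trial_design("mid", seed = 4)))
})

test_that("trial design does not disturb the global RNG stream", {
  set.seed(99)
  before <- .Random.seed
  invisible(trial_design("mid", seed = 3))
  expect_identical(before, .Random.seed)
})

test_that("group profiles validate their extreme parameter cells", {
  expect_s3_class(group_profile("ok", k_v = 0.3, n_participants = 2),
                  "group_profile")
  expect_error(group_profile("bad", k_v = 0.3, z_advice = 0.45,
                             n_participants = 1))
})

test_that("cohort simulation is deterministic and carries a manifest", {
  prof <- group_profile("g1", k_v = 0.3026, dv_advice = 0.05,
                        n_participants = 3)
  ctl <- ddm_control(dt = 2e-3)
  c1 <- simulate_cohort(prof, seed = 11, control = ctl)
  c2 <- simulate_cohort(prof, seed = 11, control = ctl)
  expect_identical(c1$trials, c2$trials)
  expect_equal(nrow(c1$trials), 3 * 210)
  expect_equal(length(unique(c1$trials$participant)), 3)
  expect_equal(c1$manifest$master_seed, 11)
  expect_length(c1$manifest$participant_seeds, 3)
  c3 <- simulate_cohort(prof, seed = 12, control = ctl)
  expect_false(identical(c1$trials$rt_s, c3$trials$rt_s))
})

test_that("default profiles reproduce the study's group structure", {
  profs <- default_profiles()
  labels <- vapply(profs, function(p) p$label, character(1))
  ns <- vapply(profs, function(p) p$n_participants, numeric(1))
  expect_equal(sum(ns), 20 + 18 + 26 + 9 + 11 + 10)
  # the adolescent preset carries the largest advice drift bias
  dvs <- vapply(profs, function(p) p$dv_advice, numeric(1))
  adolescent <- grepl("12_14|adolesc", labels)
  expect_true(any(adolescent))
  expect_equal(max(dvs), max(dvs[adolescent]))
})

test_that("exclusion rules: boundaries are handled exactly as stated", {
  res <- check_exclusion_rules()
  expect_true(res$pass)
  tr <- res$trials
  # rt strictly greater than 8 s excluded; exactly 8 s kept
  expect_true(tr$excluded[tr$rt_s > 8][1])
  expect_false(any(tr$excluded[tr$rt_s == 8]))
  expect_equal(unname(res$report$participants),
               c("participant_accuracy", "participant_bias"))
})

test_that("accuracy floor is inclusive and bias limit exclusive", {
  mk <- function(pid, d, resp, rt = 0.5) {
    data.frame(participant = pid, group = "t", block = 1L,
               disparity_deg = d, disparity_norm = sign(d),
               advice = "left", advice_correct = NA, response = resp,
               rt_s = rt, conformed = resp == "left", excluded = FALSE,
               exclude_reason = "", stringsAsFactors = FALSE)
  }
  # exactly 85% correct at the largest disparity (17/20): kept
  d <- rep(c(1, -1), 10)
  resp <- ifelse(d > 0, "left", "right")
  resp[1:3] <- ifelse(resp[1:3] == "left", "right", "left")
  at_floor <- mk("pf", d, resp)
  res <- apply_exclusions(at_floor)
  expect_false(any(res$trials$excluded))
  # exactly 80% same-side at zero disparity (8/10): kept
  at_bias <- mk("pb", rep(0, 10), c(rep("left", 8), "right", "right"))
  res2 <- apply_exclusions(at_bias)
  expect_false(any(res2$trials$excluded))
})

test_that("applying exclusions twice is a no-op", {
  prof <- group_profile("g", k_v = 0.3026, n_participants = 2)
  coh <- simulate_cohort(prof, seed = 8, control = ddm_control(dt = 2e-3))
  once <- apply_exclusions(coh$trials)
  twice <- apply_exclusions(once$trials)
  expect_identical(once$trials, twice$trials)
  expect_identical(once$report, twice$report)
})

test_that("drift-gain calibration hits the target accuracy", {
  k <- calibrate_drift_gain(target_acc = 0.95)
  p <- ddm_params(v = k, a = 0.11, ter = 0.35, eta = 0.08, sz = 0.02,
                  st = 0.1, s = 0.1)
  expect_equal(ddm_choice_prob(p, "upper"), 0.95, tolerance = 1e-4)
})

test_that("empty profile list yields an empty, well-formed trial table", {
  coh <- simulate_cohort(list(), seed = 1)
  expect_equal(nrow(coh$trials), 0)
  expect_true(all(c("participant", "disparity_norm", "advice", "rt_s",
                    "excluded") %in% names(coh$trials)))
})
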