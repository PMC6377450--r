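# ---------------------------------------------------------------------------
# Recovery study: the package's own end-to-end verification suite.  Each
# check_* function is self-contained, seeded, and returns a list with a
# `pass` flag plus the quantities it computed; recovery_study() runs them
# all and writes a JSON report.

# direct cell-level generator used by the null/parameter-recovery checks:
# balanced disparity-by-advice cells with drift k_v*d + s_adv*dv and
# starting point 0.5 + s_adv*z_advice (s_adv = +1 for "left" advice)
make_cell_trials <- function(n_per_cell, k_v = 0, dv_advice = 0,
                             z_advice = 0, seed = 1,
                             disparities = seq(-1, 1, length.out = 7),
                             params = ddm_params(v = 0, a = 0.11,
                                                 ter = 0.35, eta = 0.08,
                                                 sz = 0.02, st = 0.1,
                                                 s = 0.1),
                             control = ddm_control()) {
  cells <- expand.grid(disparity_norm = disparities,
                       advice = c("left", "right"),
                       stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    s_adv <- if (cells$advice[i] == "left") 1 else -1
    sim <- sim_ddm_conditions(
      v = k_v * cells$disparity_norm[i] + s_adv * dv_advice,
      z_rel = 0.5 + s_adv * z_advice, params = params, n = n_per_cell,
      seed = derive_seed(seed, i), control = control)
    data.frame(participant = "cell_gen", group = "synthetic", block = 1L,
               disparity_deg = cells$disparity_norm[i] * 0.03,
               disparity_norm = cells$disparity_norm[i],
               advice = cells$advice[i],
               advice_correct = NA,
               response = sim$response, rt_s = sim$rt,
               conformed = !is.na(sim$response) &
                 sim$response == cells$advice[i],
               excluded = !sim$terminated,
               exclude_reason = ifelse(sim$terminated, "",
                                       "non_terminated"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Check 1: first-passage-time conservation
#'
#' Over `n_sweep` random valid parameter sets, integrates the sum of the
#' upper and lower defective FPT densities and requires the total
#' probability mass to lie in `[0.9999, 1.0001]`.
#'
#' @param seed Seed for the parameter sweep.
#' @param n_sweep Number of parameter sets.
#' @param control A [ddm_control()].
#' @return List with `pass`, `masses`, `worst`.
#' @export
check_conservation <- function(seed = 1, n_sweep = 50,
                               control = ddm_control()) {
  set.seed(seed)
  masses <- vapply(seq_len(n_sweep), function(i) {
    a <- stats::runif(1, 0.06, 0.2)
    z <- stats::runif(1, 0.3, 0.7)
    ter <- stats::runif(1, 0.2, 0.5)
    p <- ddm_params(v = stats::runif(1, -0.4, 0.4), a = a, z_rel = z,
                    ter = ter, eta = stats::runif(1, 0, 0.15),
                    sz = stats::runif(1, 0, 0.9) * 2 * a * min(z, 1 - z),
                    st = stats::runif(1, 0, 0.9) * ter, s = 0.1)
    f <- function(t) ddm_fpt_density(t, p, "upper", control) +
      ddm_fpt_density(t, p, "lower", control)
    stats::integrate(f, 0, Inf, rel.tol = 1e-8,
                     subdivisions = 400L)$value
  }, numeric(1))
  worst <- masses[which.max(abs(masses - 1))]
  list(pass = all(masses >= 0.9999 & masses <= 1.0001),
       masses = masses, worst = worst, n_sweep = n_sweep)
}

#' Check 2: analytic solution vs Euler simulation oracle
#'
#' Density: at the reference parameter set, the time region where each
#' boundary's defective density exceeds 0.1 is split into 8
#' equal-probability bins and the empirical bin mass from `n_density`
#' Euler trials must match the analytic mass within 2% relative error in
#' every bin (equal-mass bins keep the per-bin sampling error well below
#' the tolerance).  CDF: Kolmogorov-Smirnov distance between the
#' empirical and analytic defective CDFs at `n_ks` trials must be below
#' 0.01 on both boundaries.
#'
#' @param seed Seed.
#' @param n_density Trials for the density comparison.
#' @param n_ks Trials for the KS comparison.
#' @param params Reference parameter set.
#' @param control A [ddm_control()].
#' @return List with `pass`, `density_rel_err`, `ks`.
#' @export
check_oracle <- function(seed = 1, n_density = 1e6, n_ks = 5e4,
                         params = ddm_params(v = 0.2, a = 0.11,
                                             ter = 0.35, eta = 0.08,
                                             sz = 0.02, st = 0.1,
                                             s = 0.1),
                         control = ddm_control()) {
  sim <- simulate_ddm(params, n_density, seed = derive_seed(seed, 1),
                      control = control)
  rel_err <- list()
  for (b in c("upper", "lower")) {
    tg <- seq(params$ter - params$st / 2, 6, length.out = 1200)
    dens <- ddm_fpt_density(tg, params, b, control)
    region <- range(tg[dens > 0.1])
    cdf_at <- function(t) ddm_fpt_cdf(t, params, b, control)
    mass <- cdf_at(region[2]) - cdf_at(region[1])
    # conditional equal-probability interior edges within the region
    targets <- cdf_at(region[1]) + mass * seq(1, 7) / 8
    edges <- vapply(targets, function(tt)
      stats::uniroot(function(t) cdf_at(t) - tt, region,
                     tol = 1e-10)$root, numeric(1))
    all_edges <- c(region[1], edges, region[2])
    analytic <- diff(vapply(all_edges, cdf_at, numeric(1)))
    rt <- sim$rt[!is.na(sim$boundary) & sim$boundary == b]
    emp <- diff(vapply(all_edges, function(e)
      sum(rt <= e), numeric(1))) / n_density  # 10 edges, linear scans
    rel_err[[b]] <- abs(emp - analytic) / analytic
  }
  sim_ks <- simulate_ddm(params, n_ks, seed = derive_seed(seed, 2),
                         control = control)
  ks <- vapply(c("upper", "lower"), function(b) {
    # defective empirical CDF steps at the sorted RTs of this boundary
    rt <- sort(sim_ks$rt[!is.na(sim_ks$boundary) & sim_ks$boundary == b])
    f_mod <- ddm_fpt_cdf(rt, params, b, control)
    steps <- seq_along(rt) / n_ks
    max(abs(f_mod - steps), abs(f_mod - (steps - 1 / n_ks)),
        abs(ddm_choice_prob(params, b, control) - length(rt) / n_ks))
  }, numeric(1))
  err <- unlist(rel_err)
  list(pass = all(err < 0.02) && all(ks < 0.01),
       density_rel_err = rel_err, max_density_rel_err = max(err),
       ks = ks)
}

#' Check 3: null recovery
#'
#' Fits Model 4 to data simulated with zero drift and unbiased starting
#' point everywhere (`n_trials` total).  Requires the fitted starting
#' points within 0.02 of 0.5 and a bootstrap CI for the mean advice drift
#' difference that covers 0.
#'
#' @param seed Seed.
#' @param n_trials Total trial count.
#' @param n_boot Bootstrap replicates for the CI.
#' @param restarts Optimisation restarts.
#' @return List with `pass`, the fit, and the CI table.
#' @export
check_null_recovery <- function(seed = 1, n_trials = 1e4, n_boot = 100,
                                restarts = 3) {
  trials <- make_cell_trials(round(n_trials / 14), k_v = 0,
                             dv_advice = 0, z_advice = 0,
                             seed = derive_seed(seed, 10))
  fit <- fit_ddm(trials, model = 4, restarts = restarts,
                 seed = derive_seed(seed, 11))
  zs <- unique(fit$estimates$z_rel)
  ci <- ddm_param_cis(fit, trials, n_boot = n_boot,
                      seed = derive_seed(seed, 12), max_iter = 30)
  dvr <- ci$table[ci$table$param == "dv_mean", ]
  list(pass = all(abs(zs - 0.5) < 0.02) &&
         dvr$lower <= 0 && dvr$upper >= 0,
       z_rel = zs, dv_mean_ci = c(dvr$lower, dvr$upper),
       max_abs_v = max(abs(fit$estimates$v)), fit = fit, ci = ci)
}

#' Check 4: Model-4 parameter recovery
#'
#' Simulates from a known Model-4 generator (advice acts on both drift
#' and starting point) and requires the fitted mean advice drift
#' difference within +-15% of truth and each starting point within
#' +-0.03.
#'
#' @param seed Seed.
#' @param n_trials Total trial count.
#' @param dv_advice,z_advice True advice effects (per-advice half-effects).
#' @param restarts Optimisation restarts.
#' @return List with `pass` and the recovered values.
#' @export
check_param_recovery <- function(seed = 1, n_trials = 1e4,
                                 dv_advice = 0.06, z_advice = 0.04,
                                 restarts = 3) {
  trials <- make_cell_trials(round(n_trials / 14), k_v = 0.3026,
                             dv_advice = dv_advice, z_advice = z_advice,
                             seed = derive_seed(seed, 20))
  fit <- fit_ddm(trials, model = 4, restarts = restarts,
                 seed = derive_seed(seed, 21))
  s4 <- advice_split_summary(fit)
  dv_hat <- mean(s4$dv_advice)
  dv_true <- 2 * dv_advice
  z_hat <- c(left = s4$z_left[1], right = s4$z_right[1])
  z_true <- c(left = 0.5 + z_advice, right = 0.5 - z_advice)
  list(pass = abs(dv_hat - dv_true) <= 0.15 * abs(dv_true) &&
         all(abs(z_hat - z_true) <= 0.03),
       dv_hat = dv_hat, dv_true = dv_true, z_hat = z_hat,
       z_true = z_true, fit = fit)
}

# shared engine for a model-recovery replicate: simulate one cohort under
# `profile`, pool trials, fit the requested models with warm chaining
recovery_cohort_fits <- function(profile, models, seed, restarts,
                                 sim_control, fit_args = list()) {
  coh <- simulate_cohort(profile, seed = seed, control = sim_control)
  trials <- apply_exclusions(coh$trials)$trials
  do.call(fit_ddm_set, c(list(trials = trials, models = models,
                              restarts = restarts,
                              seed = derive_seed(seed, 999)), fit_args))
}

#' Check 5: model-selection recovery
#'
#' Two seeded replicate studies at study-scale cohort size:
#' (i) cohorts generated under a Model-4 mechanism (advice shifts both
#' drift and starting point) must select Model 4 by minimum BIC; (ii)
#' cohorts generated under a pure drift-bias mechanism must order
#' `BIC(Model 3) < BIC(Model 2)`.  Each property must hold in at least
#' 90% of replicates.
#'
#' @param seed Seed.
#' @param n_replicates Replicates per mechanism.
#' @param n_participants Participants per cohort (210 trials each).
#' @param restarts Optimisation restarts per fit.
#' @param dv_advice,z_advice Mechanism effect sizes.
#' @param sim_control [ddm_control()] for the cohort simulations.
#' @return List with `pass`, per-replicate selections and orderings.
#' @export
check_model_recovery <- function(seed = 1, n_replicates = 10,
                                 n_participants = 17, restarts = 1,
                                 dv_advice = 0.0634, z_advice = 0.04,
                                 sim_control = ddm_control(dt = 1e-3)) {
  fit_args <- list(fit_control = ddm_control(tol = 1e-6, eta_nodes = 5,
                                             sz_nodes = 3, st_nodes = 3),
                   max_iter = 100)
  prof_m4 <- group_profile("gen_m4", k_v = 0.3026,
                           dv_advice = dv_advice, z_advice = z_advice,
                           n_participants = n_participants)
  prof_drift <- group_profile("gen_drift", k_v = 0.3026,
                              dv_advice = dv_advice,
                              n_participants = n_participants)
  sel_m4 <- logical(n_replicates)
  order_ok <- logical(n_replicates)
  for (r in seq_len(n_replicates)) {
    fits4 <- suppressWarnings(recovery_cohort_fits(
      prof_m4, models = 1:5, seed = derive_seed(seed, 100 + r),
      restarts = restarts, sim_control = sim_control,
      fit_args = fit_args))
    cmp <- compare_ddm(fits4)
    sel_m4[r] <- cmp$best == 4
    fitsd <- suppressWarnings(recovery_cohort_fits(
      prof_drift, models = 1:3, seed = derive_seed(seed, 200 + r),
      restarts = restarts, sim_control = sim_control,
      fit_args = fit_args))
    order_ok[r] <- fitsd[["3"]]$bic < fitsd[["2"]]$bic
  }
  list(pass = mean(sel_m4) >= 0.9 && mean(order_ok) >= 0.9,
       p_select_m4 = mean(sel_m4), p_m3_beats_m2 = mean(order_ok),
       sel_m4 = sel_m4, order_ok = order_ok,
       n_replicates = n_replicates)
}

#' Check 6: shift-statistic calibration and type-I rate
#'
#' (i) `n_cohorts` replicate cohorts from the adolescent preset (advice
#' drift bias calibrated to a population shift of 0.419 normalized
#' disparity): the 95% CI of the mean recovered pooled shift must cover
#' 0.419.  (ii) `n_null` single participants from the null preset, each
#' tested with the permutation test of the advice shift at alpha = 0.05:
#' the rejection rate must lie in 0.05 +- 0.02.
#'
#' @param seed Seed.
#' @param n_cohorts Replicate cohorts for the calibration CI.
#' @param n_participants Participants per replicate cohort.
#' @param n_null Null participants for the type-I rate.
#' @param n_perm Permutations per test.
#' @param sim_control [ddm_control()] for the simulations.
#' @return List with `pass`, `shift_mean`, `shift_ci`, `type1`.
#' @export
check_shift_recovery <- function(seed = 1, n_cohorts = 100,
                                 n_participants = 26, n_null = 400,
                                 n_perm = 250,
                                 sim_control = ddm_control(dt = 1e-3)) {
  k_v <- 0.3026
  prof <- default_profiles(k_v)$NT_12_14
  prof$n_participants <- n_participants
  shifts <- vapply(seq_len(n_cohorts), function(r) {
    coh <- simulate_cohort(prof, seed = derive_seed(seed, 300 + r),
                           control = sim_control)
    cohort_shift(apply_exclusions(coh$trials)$trials)
  }, numeric(1))
  m <- mean(shifts)
  half <- stats::qt(0.975, n_cohorts - 1) *
    stats::sd(shifts) / sqrt(n_cohorts)
  ci <- c(m - half, m + half)
  covered <- ci[1] <= 0.419 && 0.419 <= ci[2]
  prof_null <- group_profile("null", k_v = k_v, n_participants = 1)
  rej <- vapply(seq_len(n_null), function(r) {
    tr <- simulate_participant(prof_null,
                               seed = derive_seed(seed, 1000 + r),
                               id = "null", control = sim_control)
    tr <- tr[!is.na(tr$response), ]
    pl <- psych_points(tr$disparity_norm[tr$advice == "left"],
                       tr$response[tr$advice == "left"])
    pr <- psych_points(tr$disparity_norm[tr$advice == "right"],
                       tr$response[tr$advice == "right"])
    cc <- compare_curve_counts(pl, pr, n_perm = n_perm,
                               seed = derive_seed(seed, 5000 + r))
    cc$p_value < 0.05
  }, logical(1))
  type1 <- mean(rej)
  list(pass = covered && abs(type1 - 0.05) <= 0.02,
       shift_mean = m, shift_ci = ci, shift_sd = stats::sd(shifts),
       type1 = type1, n_cohorts = n_cohorts, n_null = n_null)
}

#' Check 7: mechanism dissociation
#'
#' Cohorts generated with a pure starting-point bias must be flagged by
#' [ddm_param_cis()] on the starting points but not on drift, and
#' cohorts with a pure drift bias the converse, in at least 90% of
#' replicates overall.
#'
#' @param seed Seed.
#' @param n_replicates Replicates per mechanism.
#' @param n_participants Participants per cohort.
#' @param n_boot Bootstrap replicates per CI.
#' @param restarts Optimisation restarts per fit.
#' @param dv_advice,z_advice Mechanism effect sizes.
#' @param sim_control [ddm_control()] for the simulations.
#' @return List with `pass` and per-replicate flag patterns.
#' @export
check_dissociation <- function(seed = 1, n_replicates = 5,
                               n_participants = 17, n_boot = 50,
                               restarts = 1, dv_advice = 0.0634,
                               z_advice = 0.05,
                               sim_control = ddm_control(dt = 1e-3)) {
  fit_control <- ddm_control(tol = 1e-6, eta_nodes = 5, sz_nodes = 3,
                             st_nodes = 3)
  mech <- list(
    drift = group_profile("mech_drift", k_v = 0.3026,
                          dv_advice = dv_advice,
                          n_participants = n_participants),
    z = group_profile("mech_z", k_v = 0.3026, z_advice = z_advice,
                      n_participants = n_participants))
  res <- list()
  correct <- logical(0)
  for (mname in names(mech)) {
    for (r in seq_len(n_replicates)) {
      sd_r <- derive_seed(seed, 400 + 50 * (mname == "z") + r)
      coh <- simulate_cohort(mech[[mname]], seed = sd_r,
                             control = sim_control)
      trials <- apply_exclusions(coh$trials)$trials
      fit <- suppressWarnings(fit_ddm(trials, model = 4,
                                      restarts = restarts,
                                      seed = derive_seed(sd_r, 1),
                                      fit_control = fit_control,
                                      max_iter = 120))
      ci <- suppressWarnings(ddm_param_cis(fit, trials, n_boot = n_boot,
                                           seed = derive_seed(sd_r, 2),
                                           max_iter = 25))
      tab <- ci$table
      drift_flag <- tab$flag[tab$param == "dv_mean"]
      z_flag <- any(tab$flag[tab$param %in% c("z_left", "z_right")])
      ok <- if (mname == "drift") drift_flag && !z_flag else
        z_flag && !drift_flag
      correct <- c(correct, ok)
      res[[paste0(mname, "_", r)]] <- list(mechanism = mname,
                                           drift_flag = drift_flag,
                                           z_flag = z_flag, correct = ok)
    }
  }
  list(pass = mean(correct) >= 0.9, p_correct = mean(correct),
       replicates = res, n_replicates = n_replicates)
}

#' Check 8: exclusion rules on a constructed toy table
#'
#' Builds a 30-trial table with known violations (one response slower
#' than 8 s, one exactly at 8 s which must be kept, a participant below
#' the 85% accuracy floor, and a participant above 80% same-side
#' responding) and verifies the exact kept/excluded partition.
#'
#' @return List with `pass`, the toy table, and the expected/observed
#'   flags.
#' @export
check_exclusion_rules <- function() {
  mk <- function(participant, disparity, response, rt) {
    data.frame(participant = participant, group = "toy", block = 1L,
               disparity_deg = disparity * 0.03,
               disparity_norm = disparity, advice = "left",
               advice_correct = NA, response = response, rt_s = rt,
               conformed = response == "left", excluded = FALSE,
               exclude_reason = "", stringsAsFactors = FALSE)
  }
  correct_resp <- function(d) if (d > 0) "left" else "right"
  # p1: all correct, one rt over the limit, one exactly at it
  d1 <- rep(c(1, -1), 5)
  p1 <- mk("p1", d1, vapply(d1, correct_resp, character(1)),
           c(8.2, 8.0, rep(0.6, 8)))
  # p2: accuracy 6/10 = 0.6 < 0.85 -> excluded as a participant
  d2 <- rep(c(1, -1), 5)
  r2 <- vapply(d2, correct_resp, character(1))
  r2[1:4] <- ifelse(r2[1:4] == "left", "right", "left")
  p2 <- mk("p2", d2, r2, rep(0.6, 10))
  # p3: 9/10 leftward on zero-disparity trials = 0.9 > 0.80 -> excluded
  p3 <- mk("p3", rep(0, 10), c(rep("left", 9), "right"), rep(0.6, 10))
  toy <- rbind(p1, p2, p3)
  res <- apply_exclusions(toy)
  obs <- res$trials$excluded
  expected <- c(c(TRUE, rep(FALSE, 9)),  # p1: only the 8.2 s trial
                rep(TRUE, 10),           # p2: accuracy floor
                rep(TRUE, 10))           # p3: bias rule
  list(pass = identical(obs, expected), observed = obs,
       expected = expected, report = res$report, trials = res$trials)
}

#' Run the full recovery study
#'
#' Executes the package's eight verification checks (conservation, oracle
#' equivalence, null recovery, parameter recovery, model-selection
#' recovery, shift calibration/type-I, mechanism dissociation, exclusion
#' rules) from one master seed, optionally at reduced replicate counts,
#' and writes a JSON report.
#'
#' @param seed Master seed; every check derives its own sub-seed.
#' @param out Optional path for the JSON report.
#' @param level `"reduced"` (default; minutes) or `"full"` (the study-scale
#'   replicate counts; much longer).
#' @param checks Which checks to run (1-8).
#' @return List of per-check results plus `pass` (all requested checks
#'   passed) and `summary` data frame.
#' @export
recovery_study <- function(seed = 1, out = NULL,
                           level = c("reduced", "full"), checks = 1:8) {
  level <- match.arg(level)
  full <- level == "full"
  runners <- list(
    `1` = function() check_conservation(derive_seed(seed, 1)),
    `2` = function() check_oracle(derive_seed(seed, 2)),
    `3` = function() check_null_recovery(derive_seed(seed, 3),
                                         n_boot = if (full) 200 else 100),
    `4` = function() check_param_recovery(derive_seed(seed, 4)),
    `5` = function() check_model_recovery(
      derive_seed(seed, 5), n_replicates = if (full) 100 else 10),
    `6` = function() check_shift_recovery(
      derive_seed(seed, 6), n_cohorts = 100,
      n_null = if (full) 1000 else 400),
    `7` = function() check_dissociation(
      derive_seed(seed, 7), n_replicates = if (full) 25 else 5),
    `8` = function() check_exclusion_rules())
  names_long <- c("fpt_conservation", "oracle_equivalence",
                  "null_recovery", "parameter_recovery",
                  "model_selection_recovery", "shift_recovery",
                  "mechanism_dissociation", "exclusion_rules")
  results <- list()
  for (ch in checks) {
    t0 <- proc.time()[["elapsed"]]
    results[[names_long[ch]]] <- suppressWarnings(runners[[as.character(ch)]]())
    results[[names_long[ch]]]$elapsed_s <-
      round(proc.time()[["elapsed"]] - t0, 2)
  }
  summary <- data.frame(
    check = names(results),
    pass = vapply(results, function(r) isTRUE(r$pass), logical(1)),
    elapsed_s = vapply(results, function(r) r$elapsed_s, numeric(1)))
  rownames(summary) <- NULL
  out_list <- list(results = results, summary = summary,
                   pass = all(summary$pass), seed = seed, level = level)
  if (!is.null(out)) {
    report <- list(seed = seed, level = level, pass = out_list$pass,
                   summary = summary,
                   version = as.character(utils::packageVersion("siddm")))
    jsonlite::write_json(report, out, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  out_list
}
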