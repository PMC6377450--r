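#!/usr/bin/env Rscript
# Calibration of the generator presets (documented, seeded).
#
# Two constants feed default_profiles():
#   1. k_v  — drift gain per unit normalized disparity, tuned so accuracy
#      at the largest disparity is 95% (closed-form root find).
#   2. dv_advice (adolescent preset) — additive advice drift bias, tuned
#      so the POOLED RECOVERED psychometric shift equals 0.419 normalized
#      disparity.  The translation argument gives shift = 2*dv/k_v for
#      the true curves, but the recovered shift carries a small (~1%)
#      downward offset: advice validity is 2/3, so each advice condition
#      over-samples disparities on the advised side, and that asymmetric
#      design interacts with the probit family's mismatch to the true
#      (logistic-mixture) curve shape.  Calibrating on simulated cohorts
#      absorbs this estimator-level offset into the preset.
#
# Stage A brackets dv by bisection on simulated cohorts
# (calibrate_advice_drift); stage B refines it with one linear step
# using the exact slope d(shift)/d(dv) = 2/k_v, averaging the recovered
# shift over many replicate cohorts — bisection alone would need far
# more simulated cohorts per evaluation to reach the same precision.
#
# Usage: Rscript scripts/calibrate.R   (takes ~10 minutes)

suppressPackageStartupMessages(library(siddm))

seed <- 424242L

k_v <- calibrate_drift_gain(target_acc = 0.95)
cat(sprintf("k_v = %.4f\n", k_v))

prof <- group_profile("NT_12_14", k_v = k_v, n_participants = 26)

# Stage A: coarse bisection (bracket the root)
coarse <- calibrate_advice_drift(prof, target_shift = 0.419,
                                 seed = derive_seed(seed, 1),
                                 n_participants = 26, n_reps = 5,
                                 tol = 0.005, max_iter = 10)
cat(sprintf("stage A: dv = %.5f (achieved shift %.4f, %d iterations)\n",
            coarse$dv_advice, coarse$achieved_shift, coarse$iterations))

# Stage B: linear refinement with the exact slope 2/k_v.  The per-cohort
# shift SD is ~0.026, so hitting the target to ~0.001 (well inside the
# half-width of a 100-cohort CI) needs several hundred cohorts here.
n_reps <- 600
pr <- prof
pr$dv_advice <- coarse$dv_advice
shifts <- vapply(seq_len(n_reps), function(r) {
  coh <- simulate_cohort(list(pr), seed = derive_seed(seed, 100 + r),
                         control = ddm_control(dt = 1e-3))
  cohort_shift(apply_exclusions(coh$trials)$trials)
}, numeric(1))
m <- mean(shifts)
se <- stats::sd(shifts) / sqrt(n_reps)
dv_final <- coarse$dv_advice + (0.419 - m) * k_v / 2
cat(sprintf("stage B: mean recovered shift %.4f (se %.4f) over %d cohorts\n",
            m, se, n_reps))
cat(sprintf("dv_advice (adolescent preset) = %.5f\n", dv_final))
cat(sprintf("estimator offset absorbed: %.4f normalized disparity\n",
            2 * dv_final / k_v - 0.419))
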