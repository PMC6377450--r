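# shared fixtures for the test suite

ref_params <- function(...) {
  args <- list(v = 0.2, a = 0.11, z_rel = 0.5, ter = 0.35, eta = 0.08,
               sz = 0.02, st = 0.1, s = 0.1)
  args[names(list(...))] <- list(...)
  do.call(ddm_params, args)
}

# numeric integral of the defective density (independent check of the CDF)
density_mass <- function(params, t_lo, t_hi, boundary,
                         control = ddm_control()) {
  stats::integrate(function(t) ddm_fpt_density(t, params, boundary,
                                               control),
                   t_lo, t_hi, rel.tol = 1e-9,
                   subdivisions = 400L)$value
}

# a small deterministic synthetic participant for psychometric tests
psych_fixture <- function(mu = 0, sigma = 0.35, n_per = 60, seed = 5,
                          levels = seq(-1, 1, length.out = 7)) {
  set.seed(seed)
  disparity <- rep(levels, each = n_per)
  p <- pnorm(disparity, mean = mu, sd = sigma)
  response <- ifelse(stats::rbinom(length(p), 1, p) == 1, "left", "right")
  psych_points(disparity, response)
}
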