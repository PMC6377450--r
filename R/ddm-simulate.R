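#' Simulate diffusion-model trials
#'
#' Euler-Maruyama simulation of the full model: each trial draws its drift
#' from `Normal(v, eta)`, its starting point uniformly on
#' `z_rel * a +/- sz/2` and its non-decision time uniformly on
#' `ter +/- st/2`, then integrates the path until absorption.  The simulator
#' runs on its own seeded RNG stream, so results are byte-identical given
#' `(params, n, seed)` and independent of R's global RNG state.
#'
#' Paths that have not been absorbed by `control$t_max` seconds are returned
#' with `terminated = FALSE` and missing RT/response; they are flagged, never
#' silently dropped.
#'
#' @param params A [ddm_params()] object.
#' @param n Number of trials (>= 1).
#' @param seed Integer seed (required; no default).
#' @param control A [ddm_control()] list (`dt`, `t_max`,
#'   `boundary_correction`).
#' @return A data.frame with columns `rt` (seconds), `boundary`
#'   (`"upper"`/`"lower"`), `response` (`"left"`/`"right"`), `terminated`.
#' @export
#' @examples
#' sim <- simulate_ddm(ddm_params(v = 0.2, a = 0.1, ter = 0.3), n = 100,
#'                     seed = 1, control = ddm_control(dt = 1e-3))
#' table(sim$response)
simulate_ddm <- function(params, n, seed, control = ddm_control()) {
  stopifnot(inherits(params, "ddm_params"), n >= 1)
  if (missing(seed)) stop("an explicit 'seed' is required", call. = FALSE)
  sim_ddm_conditions(v = params$v, z_rel = params$z_rel, params = params,
                     n = as.integer(n), seed = seed, control = control)
}

# Vectorised engine: v and z_rel may be per-trial vectors (length n) while
# the remaining parameters are shared.  Used by simulate_ddm() and by the
# cohort generator, where drift and starting point vary per trial with
# disparity and advice.
sim_ddm_conditions <- function(v, z_rel, params, n, seed,
                               control = ddm_control()) {
  stopifnot(length(v) %in% c(1L, n), length(z_rel) %in% c(1L, n))
  seed <- as.numeric(seed)
  stopifnot(is.finite(seed))
  m <- cpp_sim_ddm(as.integer(n), as.numeric(v), params$a,
                   as.numeric(z_rel), params$ter, params$eta, params$sz,
                   params$st, params$s, control$dt, control$t_max, seed,
                   control$boundary_correction)
  upper <- m[, 2]
  data.frame(rt = m[, 1],
             boundary = ifelse(is.na(upper), NA_character_,
                               ifelse(upper == 1, "upper", "lower")),
             response = ifelse(is.na(upper), NA_character_,
                               ifelse(upper == 1, "left", "right")),
             terminated = !is.na(upper),
             stringsAsFactors = FALSE)
}

#' Derive a sub-stream seed from a master seed
#'
#' Deterministic integer hash used throughout the package to give every
#' sub-task (participants, bootstrap replicates, restarts) its own seed
#' from one master seed. Results always lie in `[1, 2^31 - 2]`.
#'
#' @param master Master seed.
#' @param index Sub-stream index.
#' @return An integer seed.
#' @export
#' @examples
#' derive_seed(1, 2)
derive_seed <- function(master, index) {
  stopifnot(length(master) == 1, is.finite(master))
  x <- (as.numeric(master) %% 2147483647) + 1
  for (i in seq_len(2)) {
    x <- (x * 48271 + 1 + as.numeric(index) * 16807) %% 2147483647
  }
  as.integer(x %% 2147483645 + 1)
}
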