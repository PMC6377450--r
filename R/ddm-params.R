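#' Diffusion-model parameter set
#'
#' Constructs and validates the seven-parameter decision model: drift rate,
#' boundary separation, relative starting point, non-decision time, and
#' across-trial variability in drift (Normal SD), starting point (uniform
#' range, absolute evidence units) and non-decision time (uniform range).
#' The diffusion coefficient `s` is a fixed scaling constant (0.1 by
#' convention) and is held fixed within any fit for identifiability.
#'
#' The upper boundary codes a "left" response and positive drift points
#' leftward; `z_rel = 0.5` is the unbiased midpoint.
#'
#' @param v Drift rate (evidence units per second, signed; positive = toward
#'   the "left"/upper boundary).
#' @param a Boundary separation (> 0, evidence units).
#' @param z_rel Relative starting point in (0, 1).
#' @param ter Non-decision time (seconds, >= 0).
#' @param eta Across-trial SD of drift (>= 0).
#' @param sz Across-trial range of the starting point (absolute evidence
#'   units, >= 0; support must stay strictly inside the boundaries).
#' @param st Across-trial range of non-decision time (seconds, >= 0; requires
#'   `ter - st/2 >= 0`).
#' @param s Diffusion coefficient (> 0).
#'
#' @return An object of class `ddm_params`.
#' @export
#' @examples
#' ddm_params(v = 0.25, a = 0.11, z_rel = 0.5, ter = 0.3, eta = 0.08,
#'            sz = 0.02, st = 0.1)
ddm_params <- function(v, a, z_rel = 0.5, ter = 0.3, eta = 0, sz = 0,
                       st = 0, s = 0.1) {
  p <- list(v = as.numeric(v), a = as.numeric(a), z_rel = as.numeric(z_rel),
            ter = as.numeric(ter), eta = as.numeric(eta),
            sz = as.numeric(sz), st = as.numeric(st), s = as.numeric(s))
  validate_ddm_params(p)
  structure(p, class = "ddm_params")
}

validate_ddm_params <- function(p) {
  with(p, {
    if (!all(is.finite(c(v, a, z_rel, ter, eta, sz, st, s))))
      stop("ddm_params: all parameters must be finite", call. = FALSE)
    if (a <= 0) stop("ddm_params: 'a' must be > 0", call. = FALSE)
    if (s <= 0) stop("ddm_params: 's' must be > 0", call. = FALSE)
    if (z_rel <= 0 || z_rel >= 1)
      stop("ddm_params: 'z_rel' must lie in (0, 1)", call. = FALSE)
    if (ter < 0) stop("ddm_params: 'ter' must be >= 0", call. = FALSE)
    if (eta < 0 || sz < 0 || st < 0)
      stop("ddm_params: variability parameters must be >= 0", call. = FALSE)
    if (z_rel * a - sz / 2 <= 0 || z_rel * a + sz / 2 >= a)
      stop("ddm_params: starting-point support must lie strictly inside ",
           "the boundaries (check 'sz' against 'z_rel' and 'a')",
           call. = FALSE)
    if (ter - st / 2 < 0)
      stop("ddm_params: require 'ter - st/2 >= 0'", call. = FALSE)
  })
  invisible(p)
}

#' @export
print.ddm_params <- function(x, ...) {
  cat("Diffusion model parameters (s =", format(x$s), ")\n")
  cat(sprintf("  v = %-8.4g a = %-8.4g z_rel = %-8.4g ter = %-8.4g\n",
              x$v, x$a, x$z_rel, x$ter))
  cat(sprintf("  eta = %-6.4g sz = %-7.4g st = %-7.4g\n",
              x$eta, x$sz, x$st))
  invisible(x)
}

# replace selected fields, re-validating
modify_ddm_params <- function(p, ...) {
  repl <- list(...)
  p[names(repl)] <- repl
  validate_ddm_params(p)
  structure(p, class = "ddm_params")
}
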