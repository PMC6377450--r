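#' @useDynLib siddm, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

match_boundary <- function(boundary) {
  boundary <- match.arg(boundary, c("upper", "lower"))
  boundary == "upper"
}

#' Boundary absorption probability
#'
#' Probability that the decision variable is absorbed at the given boundary
#' (upper = "left" response).  Closed form for fixed drift and starting
#' point; Normal drift and uniform starting-point variability are integrated
#' by Gaussian quadrature.
#'
#' @param params A [ddm_params()] object.
#' @param boundary `"upper"` or `"lower"`.
#' @param control A [ddm_control()] list.
#' @return A probability; `P(upper) + P(lower) = 1`.
#' @export
#' @examples
#' ddm_choice_prob(ddm_params(v = 0, a = 0.1, z_rel = 0.7, ter = 0.3))  # 0.7
ddm_choice_prob <- function(params, boundary = c("upper", "lower"),
                            control = ddm_control()) {
  stopifnot(inherits(params, "ddm_params"))
  up <- match_boundary(boundary)
  q <- quad_nodes(control)
  cpp_choice_prob(up, params$v, params$a, params$z_rel, params$eta,
                  params$sz, params$s, q$ghx, q$ghw, q$glx, q$glw)
}

#' Defective first-passage-time density
#'
#' Density (per second) of reaction times terminating at one boundary; it
#' integrates to the absorption probability of that boundary, not to 1.
#' Evaluations at `t` below the earliest possible non-decision time return
#' exactly 0.
#'
#' @param t Vector of times (seconds, including non-decision time).
#' @inheritParams ddm_choice_prob
#' @return Numeric vector of densities.
#' @export
ddm_fpt_density <- function(t, params, boundary = c("upper", "lower"),
                            control = ddm_control()) {
  stopifnot(inherits(params, "ddm_params"), all(t >= 0 | is.na(t)))
  up <- match_boundary(boundary)
  q <- quad_nodes(control)
  cpp_fpt_pdf(as.numeric(t), up, params$v, params$a, params$z_rel,
              params$ter, params$eta, params$sz, params$st, params$s,
              q$glx, q$glw, control$tol)
}

#' Defective first-passage-time CDF
#'
#' Cumulative probability of a response at the given boundary by time `t`;
#' its limit as `t` grows is [ddm_choice_prob()].
#'
#' @inheritParams ddm_fpt_density
#' @return Numeric vector of cumulative probabilities.
#' @export
ddm_fpt_cdf <- function(t, params, boundary = c("upper", "lower"),
                        control = ddm_control()) {
  stopifnot(inherits(params, "ddm_params"))
  up <- match_boundary(boundary)
  q <- quad_nodes(control)
  cpp_fpt_cdf(as.numeric(t), up, params$v, params$a, params$z_rel,
              params$ter, params$eta, params$sz, params$st, params$s,
              q$ghx, q$ghw, q$glx, q$glw, control$tol)
}

#' Conditional reaction-time quantiles
#'
#' Quantiles of the RT distribution conditional on absorption at one
#' boundary, obtained by root finding on the defective CDF.
#'
#' @param probs Strictly increasing probabilities in (0, 1).
#' @inheritParams ddm_fpt_density
#' @return Numeric vector of RTs, strictly increasing.
#' @export
ddm_fpt_quantiles <- function(params, probs = c(0.1, 0.3, 0.5, 0.7, 0.9),
                              boundary = c("upper", "lower"),
                              control = ddm_control()) {
  stopifnot(inherits(params, "ddm_params"),
            all(probs > 0 & probs < 1), !is.unsorted(probs, strictly = TRUE))
  boundary <- match.arg(boundary)
  pb <- ddm_choice_prob(params, boundary, control)
  if (pb < 1e-6)
    stop(structure(class = c("siddm_degenerate_cell", "error", "condition"),
                   list(message = paste0("degenerate cell: boundary '",
                                         boundary,
                                         "' has near-zero probability"),
                        call = sys.call(-1))))
  lo <- max(params$ter - params$st / 2, 0)
  hi <- control$t_max
  cdf <- function(t) ddm_fpt_cdf(t, params, boundary, control) / pb
  while (cdf(hi) < max(probs) && hi < 1e4) hi <- hi * 2
  vapply(probs, function(p) {
    stats::uniroot(function(t) cdf(t) - p, lower = lo, upper = hi,
                   tol = 1e-7)$root
  }, numeric(1))
}

#' Quantile-bin outcome probabilities
#'
#' Probabilities of the joint (boundary, RT-bin) outcomes used by the
#' quantile-based multinomial likelihood: interior RT edges per boundary
#' partition each boundary's probability mass into bins.
#'
#' @param edges_upper,edges_lower Strictly increasing interior RT edges for
#'   the upper ("left") and lower ("right") boundary (5 edges give the
#'   conventional 6 bins per boundary).
#' @inheritParams ddm_fpt_density
#' @return Named numeric vector, upper-boundary bins first; sums to 1.
#' @export
ddm_bin_probs <- function(params, edges_upper, edges_lower,
                          control = ddm_control()) {
  stopifnot(inherits(params, "ddm_params"))
  if (is.unsorted(edges_upper, strictly = TRUE) ||
      is.unsorted(edges_lower, strictly = TRUE))
    stop("bin edges must be strictly increasing", call. = FALSE)
  pu <- ddm_choice_prob(params, "upper", control)
  Fu <- ddm_fpt_cdf(edges_upper, params, "upper", control)
  Fl <- ddm_fpt_cdf(edges_lower, params, "lower", control)
  bu <- diff(c(0, Fu, pu))
  bl <- diff(c(0, Fl, 1 - pu))
  out <- c(bu, bl)
  out[out < 0] <- 0
  names(out) <- c(paste0("upper", seq_along(bu)),
                  paste0("lower", seq_along(bl)))
  out
}
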