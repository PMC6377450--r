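#' Numerical control settings for diffusion-model computations
#'
#' Collects the tolerances and discretisation settings shared by all
#' first-passage-time computations, the trial simulator, and the fitting
#' routines.
#'
#' @param tol Absolute truncation error per series evaluation of the
#'   first-passage-time density/CDF.
#' @param eta_nodes Number of Gauss-Hermite nodes for the Normal across-trial
#'   drift mixture (used by CDF and choice-probability evaluations; the
#'   density integrates the drift mixture in closed form).
#' @param sz_nodes,st_nodes Number of Gauss-Legendre nodes for the uniform
#'   starting-point and non-decision-time ranges.
#' @param dt Euler-Maruyama step (seconds) for the trial simulator.
#' @param t_max Hard absorption cap (seconds) for simulated paths; paths that
#'   have not been absorbed by then are flagged, never dropped.
#' @param boundary_correction Logical; move the absorbing boundaries inward by
#'   `0.5826 * s * sqrt(dt)` in the simulator to correct the discrete-time
#'   first-passage bias.
#'
#' @return A list of class `ddm_control`.
#' @export
#' @examples
#' ddm_control(dt = 1e-3)
ddm_control <- function(tol = 1e-7, eta_nodes = 10, sz_nodes = 10,
                        st_nodes = 10, dt = 1e-4, t_max = 30,
                        boundary_correction = TRUE) {
  stopifnot(tol > 0, eta_nodes >= 1, sz_nodes >= 1, st_nodes >= 1,
            dt > 0, t_max > 0)
  structure(list(tol = tol, eta_nodes = eta_nodes, sz_nodes = sz_nodes,
                 st_nodes = st_nodes, dt = dt, t_max = t_max,
                 boundary_correction = isTRUE(boundary_correction)),
            class = "ddm_control")
}

# --- Gaussian quadrature nodes (Golub-Welsch), cached per order ------------

.quad_cache <- new.env(parent = emptyenv())

# Gauss-Legendre on [-1/2, 1/2], weights summing to 1
gauss_legendre_half <- function(n) {
  key <- paste0("gl", n)
  if (!is.null(.quad_cache[[key]])) return(.quad_cache[[key]])
  if (n == 1L) {
    res <- list(x = 0, w = 1)
  } else {
    k <- seq_len(n - 1)
    b <- k / sqrt(4 * k^2 - 1)
    J <- diag(0, n)
    J[cbind(k, k + 1)] <- b
    J[cbind(k + 1, k)] <- b
    e <- eigen(J, symmetric = TRUE)
    ord <- order(e$values)
    res <- list(x = e$values[ord] / 2, w = (e$vectors[1, ord]^2))
  }
  .quad_cache[[key]] <- res
  res
}

# Gauss-Hermite rescaled so that E[g(V)] for V ~ Normal(mu, eta) is
# sum(w * g(mu + sqrt(2) * eta * x)), weights summing to 1
gauss_hermite_prob <- function(n) {
  key <- paste0("gh", n)
  if (!is.null(.quad_cache[[key]])) return(.quad_cache[[key]])
  if (n == 1L) {
    res <- list(x = 0, w = 1)
  } else {
    k <- seq_len(n - 1)
    b <- sqrt(k / 2)
    J <- diag(0, n)
    J[cbind(k, k + 1)] <- b
    J[cbind(k + 1, k)] <- b
    e <- eigen(J, symmetric = TRUE)
    ord <- order(e$values)
    res <- list(x = e$values[ord], w = e$vectors[1, ord]^2)
  }
  .quad_cache[[key]] <- res
  res
}

# assemble the node vectors a C++ call expects
quad_nodes <- function(control) {
  gh <- gauss_hermite_prob(control$eta_nodes)
  gl <- gauss_legendre_half(max(control$sz_nodes, control$st_nodes))
  list(ghx = gh$x, ghw = gh$w, glx = gl$x, glw = gl$w)
}
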