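#' Model specification: which parameters vary with advice
#'
#' Defines the parameter-tying map for the five-model comparison of how
#' advice direction may act on the decision process:
#' \describe{
#'   \item{Model 1}{no parameter varies with advice;}
#'   \item{Model 2}{only the starting point `z` varies with advice;}
#'   \item{Model 3}{only the drift rate `v` varies with advice;}
#'   \item{Model 4}{both `v` and `z` vary with advice;}
#'   \item{Model 5}{unrestricted - all seven parameters vary with advice.}
#' }
#' Drift always varies with stimulus disparity.  By default the nuisance
#' parameters (`a`, `ter`, `eta`, `sz`, `st`) are shared across disparities
#' for identifiability at ~30 trials per cell; `strict = TRUE` frees them
#' per disparity as well.
#'
#' @param model_id Integer 1-5.
#' @param disparities Sorted vector of (normalized) disparity levels.
#' @param strict Free the nuisance parameters per disparity too.
#' @return An object of class `ddm_model_spec` with the tying map and the
#'   free-parameter count `k` (13, 14, 20, 21, 26 for Models 1-5 with 7
#'   disparities under default tying).
#' @export
#' @examples
#' ddm_model_spec(4, seq(-1, 1, length.out = 7))$k  # 21
ddm_model_spec <- function(model_id, disparities, strict = FALSE) {
  if (!model_id %in% 1:5) stop("unknown model id: ", model_id,
                               call. = FALSE)
  if (length(disparities) < 1) stop("need >= 1 disparity level",
                                    call. = FALSE)
  disparities <- sort(unique(disparities))
  adv <- switch(model_id, `1` = character(0), `2` = "z", `3` = "v",
                `4` = c("v", "z"), `5` = c("v", "z", "a", "ter", "eta",
                                           "sz", "st"))
  tying <- list(v = "disparity", z = character(0), a = character(0),
                ter = character(0), eta = character(0), sz = character(0),
                st = character(0))
  if (strict) for (p in c("a", "ter", "eta", "sz", "st"))
    tying[[p]] <- "disparity"
  for (p in adv) tying[[p]] <- c(tying[[p]], "advice")
  nd <- length(disparities)
  k <- sum(vapply(tying, function(keys) {
    prod(c(1, nd)[1 + ("disparity" %in% keys)],
         c(1, 2)[1 + ("advice" %in% keys)])
  }, numeric(1)))
  structure(list(model_id = model_id, tying = tying,
                 disparities = disparities, strict = strict, k = k),
            class = "ddm_model_spec")
}

#' @export
print.ddm_model_spec <- function(x, ...) {
  lab <- c("no advice effect", "z varies with advice",
           "v varies with advice", "v and z vary with advice",
           "unrestricted")[x$model_id]
  cat(sprintf("Diffusion model %d (%s): k = %d free parameters, %d disparities%s\n",
              x$model_id, lab, x$k, length(x$disparities),
              if (x$strict) ", strict per-disparity nuisance tying" else ""))
  invisible(x)
}

# ---------------------------------------------------------------------------
# internal parameter layout.  theta is a flat bounded vector; fractional
# parameterisations keep the starting-point support inside the boundaries
# (sz) and ter - st/2 >= 0 (st) for every candidate.

PARAM_ORDER <- c("a", "ter", "eta", "sz", "st", "z", "v")

build_layout <- function(spec, min_rt) {
  cells <- expand.grid(disparity = spec$disparities,
                       advice = c("left", "right"),
                       stringsAsFactors = FALSE)
  layout <- list()
  idx <- 0L
  for (p in PARAM_ORDER) {
    keys <- spec$tying[[p]]
    g <- expand.grid(
      disparity = if ("disparity" %in% keys) spec$disparities else NA,
      advice = if ("advice" %in% keys) c("left", "right") else NA,
      stringsAsFactors = FALSE)
    g$index <- idx + seq_len(nrow(g))
    idx <- idx + nrow(g)
    layout[[p]] <- g
  }
  # per-cell index into theta for each parameter
  cell_index <- sapply(PARAM_ORDER, function(p) {
    g <- layout[[p]]
    vapply(seq_len(nrow(cells)), function(i) {
      sel <- (is.na(g$disparity) | g$disparity == cells$disparity[i]) &
        (is.na(g$advice) | g$advice == cells$advice[i])
      g$index[which(sel)[1]]
    }, numeric(1))
  })
  # ter may exceed the fastest RT when st > 0 (only ter - st/2 must stay
  # below it, which the likelihood itself enforces), so the box is loose
  bounds <- list(a = c(0.03, 0.5), ter = c(0.03, max(min(2 * min_rt, 1), 0.05)),
                 eta = c(0, 0.6), sz = c(0, 0.95), st = c(0, 0.95),
                 z = c(0.15, 0.85), v = c(-2, 2))
  lower <- upper <- numeric(idx)
  for (p in PARAM_ORDER) {
    lower[layout[[p]]$index] <- bounds[[p]][1]
    upper[layout[[p]]$index] <- bounds[[p]][2]
  }
  # which cells each theta element touches (for structured gradients)
  touches <- lapply(seq_len(idx), function(j) {
    which(apply(cell_index == j, 1, any))
  })
  list(cells = cells, layout = layout, cell_index = cell_index,
       lower = lower, upper = upper, n_par = idx, touches = touches,
       spec = spec)
}

# natural per-cell parameter sets from theta.  sz and st are fractions of
# the tightest admissible range across the cells sharing their group, so
# tied groups stay genuinely tied and always valid.
cells_params <- function(theta, lay, s) {
  ci <- lay$cell_index
  a <- theta[ci[, "a"]]; ter <- theta[ci[, "ter"]]
  eta <- theta[ci[, "eta"]]; z <- theta[ci[, "z"]]; v <- theta[ci[, "v"]]
  szf <- theta[ci[, "sz"]]; stf <- theta[ci[, "st"]]
  margin <- a * pmin(z, 1 - z)
  sz_group <- ci[, "sz"]
  min_margin <- stats::ave(margin, sz_group, FUN = min)
  sz <- szf * 2 * min_margin * 0.999
  st_group <- ci[, "st"]
  min_ter <- stats::ave(ter, st_group, FUN = min)
  st <- stf * 2 * min_ter * 0.999
  data.frame(a = a, ter = ter, eta = eta, sz = sz, st = st, z = z, v = v,
             s = s)
}

# observed quantile-bin data per cell
prep_cells <- function(trials, spec, probs) {
  tr <- trials[!trials$excluded & !is.na(trials$response) &
                 !is.na(trials$rt_s), ]
  cells <- expand.grid(disparity = spec$disparities,
                       advice = c("left", "right"),
                       stringsAsFactors = FALSE)
  collapsed <- character(0)
  dat <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    sub <- tr[tr$disparity_norm == cells$disparity[i] &
                tr$advice == cells$advice[i], ]
    one <- list()
    for (b in c("upper", "lower")) {
      rt <- sub$rt_s[sub$response == if (b == "upper") "left" else "right"]
      n <- length(rt)
      if (n >= 10) {
        edges <- unique(unname(stats::quantile(rt, probs)))
      } else if (n >= 2) {
        edges <- unique(unname(stats::quantile(rt, c(1 / 3, 2 / 3))))
        collapsed <- c(collapsed,
                       sprintf("%s/%s/%s", signif(cells$disparity[i], 3),
                               cells$advice[i], b))
      } else {
        edges <- numeric(0)
      }
      counts <- tabulate(findInterval(rt, edges) + 1L,
                         nbins = length(edges) + 1L)
      one[[b]] <- list(edges = edges, counts = counts, n = n)
    }
    dat[[i]] <- one
  }
  if (length(collapsed))
    warning("bins collapsed for small cells: ",
            paste(collapsed, collapse = ", "), call. = FALSE)
  list(cells = cells, dat = dat, n = nrow(tr),
       min_rt = min(tr$rt_s), fingerprint = fingerprint_trials(tr))
}

fingerprint_trials <- function(tr) {
  c(n = nrow(tr), rt_sum = round(sum(tr$rt_s), 6),
    left = sum(tr$response == "left"))
}

# negative log-likelihood of the cells in `which_cells` (default all)
cells_nll <- function(theta, lay, prep, q, tol, s,
                      which_cells = seq_len(nrow(lay$cells))) {
  cp <- cells_params(theta, lay, s)
  total <- 0
  for (i in which_cells) {
    d <- prep$dat[[i]]
    total <- total + cpp_cell_negloglik(
      d$upper$counts, d$lower$counts, d$upper$edges, d$lower$edges,
      cp$v[i], cp$a[i], cp$z[i], cp$ter[i], cp$eta[i], cp$sz[i], cp$st[i],
      s, q$ghx, q$ghw, q$glx, q$glw, tol)
  }
  total
}

# central-difference gradient exploiting the cell structure: a parameter
# perturbation only re-evaluates the cells it touches
cells_nll_grad <- function(theta, lay, prep, q, tol, s, free) {
  g <- numeric(lay$n_par)
  for (j in free) {
    cells_j <- lay$touches[[j]]
    h <- 1e-4 * (lay$upper[j] - lay$lower[j])
    tp <- tm <- theta
    tp[j] <- min(theta[j] + h, lay$upper[j])
    tm[j] <- max(theta[j] - h, lay$lower[j])
    if (tp[j] == tm[j]) next
    fp <- cells_nll(tp, lay, prep, q, tol, s, cells_j)
    fm <- cells_nll(tm, lay, prep, q, tol, s, cells_j)
    g[j] <- (fp - fm) / (tp[j] - tm[j])
  }
  g
}

# heuristic start values: non-decision time from the fastest responses,
# drift from choice proportions via the closed-form choice function
start_theta <- function(lay, prep, s) {
  theta <- numeric(lay$n_par)
  min_rt <- prep$min_rt
  ter0 <- min(max(0.8 * min_rt, 0.05), lay$upper[lay$layout$ter$index[1]])
  a0 <- 0.11 * (s / 0.1)
  theta[lay$layout$a$index] <- a0
  theta[lay$layout$ter$index] <- ter0
  theta[lay$layout$eta$index] <- 0.08 * (s / 0.1)
  theta[lay$layout$sz$index] <- 0.2
  theta[lay$layout$st$index] <- 0.3
  theta[lay$layout$z$index] <- 0.5
  gv <- lay$layout$v
  for (r in seq_len(nrow(gv))) {
    sel <- (is.na(gv$disparity[r]) |
              lay$cells$disparity == gv$disparity[r]) &
      (is.na(gv$advice[r]) | lay$cells$advice == gv$advice[r])
    nl <- sum(vapply(which(sel), function(i)
      prep$dat[[i]]$upper$n, numeric(1)))
    nr <- sum(vapply(which(sel), function(i)
      prep$dat[[i]]$lower$n, numeric(1)))
    p <- (nl + 0.5) / (nl + nr + 1)
    p <- min(max(p, 0.02), 0.98)
    theta[gv$index[r]] <- s^2 / a0 * stats::qlogis(p)
  }
  pmin(pmax(theta, lay$lower + 1e-6), lay$upper - 1e-6)
}

#' Fit a diffusion model to grouped trial data
#'
#' Fits one of the five advice-tying model variants to (group-level pooled)
#' trials by quantile-based multinomial maximum likelihood: per
#' disparity-by-advice cell, observed RT quantiles (default .1/.3/.5/.7/.9
#' per response boundary) define 12 outcome bins whose counts are scored
#' against the model's bin probabilities.  Cells with fewer than 10
#' responses at a boundary are collapsed to 3 bins (with a warning); fewer
#' than 2 responses contribute a single bin.  Optimisation is bounded
#' multi-start quasi-Newton with seeded restarts; the objective dispersion
#' across restarts is reported as a convergence diagnostic.
#'
#' @param trials Canonical trial table (excluded rows are ignored).
#' @param model Model id 1-5, or a [ddm_model_spec()].
#' @param probs RT quantiles defining the bin edges.
#' @param restarts Number of optimisation starts (first from the data-driven
#'   heuristic or `init`, the rest jittered).
#' @param seed Seed for restart jitter.
#' @param init Optional warm-start parameter vector (`theta` of a previous
#'   fit with a compatible layout, e.g. a simpler model in the 1-5 chain).
#' @param s Diffusion coefficient (fixed within the fit).
#' @param strict Per-disparity nuisance tying (see [ddm_model_spec()]).
#' @param control A [ddm_control()]; `fit_quad` can lower the quadrature
#'   resolution during optimisation.
#' @param fit_control Optional [ddm_control()] used inside the optimiser
#'   (defaults to a moderately coarser quadrature than `control`; final
#'   log-likelihood/BIC are always recomputed under `control`).
#' @param max_iter Iteration cap per restart.
#' @return An object of class `ddm_fit`.
#' @export
fit_ddm <- function(trials, model = 4, probs = c(0.1, 0.3, 0.5, 0.7, 0.9),
                    restarts = 5, seed = 1, init = NULL, s = 0.1,
                    strict = FALSE, control = ddm_control(),
                    fit_control = NULL, max_iter = 200) {
  spec <- if (inherits(model, "ddm_model_spec")) model else
    ddm_model_spec(model, sort(unique(
      trials$disparity_norm[!trials$excluded])), strict = strict)
  prep <- prep_cells(trials, spec, probs)
  if (any(vapply(seq_along(prep$dat), function(i)
    prep$dat[[i]]$upper$n + prep$dat[[i]]$lower$n, numeric(1)) == 0))
    stop("empty disparity-by-advice cell after exclusions", call. = FALSE)
  lay <- build_layout(spec, prep$min_rt)
  if (is.null(fit_control))
    fit_control <- ddm_control(tol = control$tol,
                               eta_nodes = min(control$eta_nodes, 6),
                               sz_nodes = min(control$sz_nodes, 4),
                               st_nodes = min(control$st_nodes, 4),
                               dt = control$dt, t_max = control$t_max)
  qfit <- quad_nodes(fit_control)
  qfin <- quad_nodes(control)
  free <- seq_len(lay$n_par)
  obj <- function(th) cells_nll(th, lay, prep, qfit, fit_control$tol, s)
  gr <- function(th) cells_nll_grad(th, lay, prep, qfit, fit_control$tol,
                                    s, free)
  th0 <- if (!is.null(init)) {
    stopifnot(length(init) == lay$n_par)
    pmin(pmax(init, lay$lower + 1e-6), lay$upper - 1e-6)
  } else start_theta(lay, prep, s)
  set.seed(seed)
  starts <- list(th0)
  if (restarts > 1) for (r in 2:restarts) {
    jit <- th0 + stats::rnorm(lay$n_par) * 0.08 * (lay$upper - lay$lower)
    starts[[r]] <- pmin(pmax(jit, lay$lower + 1e-6), lay$upper - 1e-6)
  }
  fits <- lapply(starts, function(st0) {
    tryCatch(
      stats::nlminb(st0, obj, gradient = gr, lower = lay$lower,
                    upper = lay$upper,
                    control = list(iter.max = max_iter, eval.max = 3 * max_iter,
                                   rel.tol = 1e-9)),
      error = function(e) list(objective = Inf, par = st0, convergence = 99,
                               message = conditionMessage(e)))
  })
  objs <- vapply(fits, function(f) f$objective, numeric(1))
  best <- fits[[which.min(objs)]]
  theta <- best$par
  # final objective under the full-resolution quadrature
  nll <- cells_nll(theta, lay, prep, qfin, control$tol, s)
  loglik <- -nll
  k <- spec$k
  n <- prep$n
  cp <- cells_params(theta, lay, s)
  est_cells <- cbind(lay$cells, cp[, c("v", "a", "z", "ter", "eta", "sz",
                                       "st")])
  names(est_cells)[names(est_cells) == "z"] <- "z_rel"
  fit <- structure(list(
    spec = spec, theta = theta, layout = lay, estimates = est_cells,
    loglik = loglik, bic = bic_score(loglik, k, n), k = k, n = n, s = s,
    probs = probs, prep = prep, control = control,
    fit_control = fit_control,
    converged = best$convergence %in% c(0, 1) ||
      grepl("relative convergence|X-convergence|singular convergence",
            if (is.null(best$message)) "" else best$message),
    convergence_message = if (is.null(best$message)) "" else best$message,
    restart_objectives = objs,
    restart_dispersion = diff(range(objs[is.finite(objs)])),
    seed = seed), class = "ddm_fit")
  fit$diagnostics <- predicted_vs_observed(fit)
  fit
}

# predicted bin probabilities vs observed counts per cell
predicted_vs_observed <- function(fit) {
  q <- quad_nodes(fit$control)
  lay <- fit$layout
  cp <- cells_params(fit$theta, lay, fit$s)
  out <- list()
  for (i in seq_len(nrow(lay$cells))) {
    d <- fit$prep$dat[[i]]
    p <- ddm_bin_probs(ddm_params(v = cp$v[i], a = cp$a[i],
                                  z_rel = cp$z[i], ter = cp$ter[i],
                                  eta = cp$eta[i], sz = cp$sz[i],
                                  st = cp$st[i], s = fit$s),
                       d$upper$edges, d$lower$edges, fit$control)
    nobs <- c(d$upper$counts, d$lower$counts)
    ncell <- sum(nobs)
    out[[i]] <- data.frame(
      disparity = lay$cells$disparity[i], advice = lay$cells$advice[i],
      bin = names(p), observed = nobs, expected = p * ncell)
  }
  do.call(rbind, out)
}

#' Bayesian Information Criterion score
#'
#' `k * ln(n) - 2 * loglik`; lower is better.
#'
#' @param loglik Log-likelihood.
#' @param k Number of free parameters.
#' @param n Number of observations.
#' @return The BIC score.
#' @export
#' @examples
#' bic_score(-5000, 13, 3570)  # 13 * log(3570) + 10000
bic_score <- function(loglik, k, n) {
  stopifnot(n >= 1, k >= 0)
  k * log(n) - 2 * loglik
}

#' @export
print.ddm_fit <- function(x, ...) {
  print(x$spec)
  cat(sprintf("  n = %d trials, logLik = %.2f, BIC = %.2f%s\n", x$n,
              x$loglik, x$bic,
              if (x$converged) "" else "  [optimizer NOT converged]"))
  cat(sprintf("  restart objective dispersion: %.4g (%d starts)\n",
              x$restart_dispersion, length(x$restart_objectives)))
  invisible(x)
}

#' @export
summary.ddm_fit <- function(object, ...) {
  z <- advice_split_summary(object)
  structure(list(fit = object, advice_summary = z),
            class = "summary.ddm_fit")
}

#' @export
print.summary.ddm_fit <- function(x, ...) {
  print(x$fit)
  cat("\nPer-cell estimates:\n")
  print(x$fit$estimates, digits = 4, row.names = FALSE)
  if (!is.null(x$advice_summary)) {
    cat("\nAdvice effects:\n")
    print(x$advice_summary, digits = 4, row.names = FALSE)
  }
  invisible(x)
}

# advice-direction differences implied by the fit (drift) and starting
# points per advice direction
advice_split_summary <- function(fit) {
  est <- fit$estimates
  le <- est[est$advice == "left", ]
  ri <- est[est$advice == "right", ]
  data.frame(disparity = le$disparity,
             v_left = le$v, v_right = ri$v, dv_advice = le$v - ri$v,
             z_left = le$z_rel, z_right = ri$z_rel)
}

#' @export
coef.ddm_fit <- function(object, ...) {
  lay <- object$layout
  out <- numeric(0)
  for (p in PARAM_ORDER) {
    g <- lay$layout[[p]]
    lab <- vapply(seq_len(nrow(g)), function(r) {
      paste0(p,
             if (!is.na(g$disparity[r])) paste0(".d", signif(g$disparity[r], 3)),
             if (!is.na(g$advice[r])) paste0(".", g$advice[r]))
    }, character(1))
    out <- c(out, stats::setNames(object$theta[g$index], lab))
  }
  out
}

#' @export
logLik.ddm_fit <- function(object, ...) {
  structure(object$loglik, df = object$k, nobs = object$n,
            class = "logLik")
}

#' @export
predict.ddm_fit <- function(object, type = c("choice", "quantiles"),
                            probs = c(0.1, 0.3, 0.5, 0.7, 0.9), ...) {
  type <- match.arg(type)
  lay <- object$layout
  cp <- cells_params(object$theta, lay, object$s)
  rows <- lapply(seq_len(nrow(lay$cells)), function(i) {
    p <- ddm_params(v = cp$v[i], a = cp$a[i], z_rel = cp$z[i],
                    ter = cp$ter[i], eta = cp$eta[i], sz = cp$sz[i],
                    st = cp$st[i], s = object$s)
    if (type == "choice") {
      data.frame(disparity = lay$cells$disparity[i],
                 advice = lay$cells$advice[i],
                 p_left = ddm_choice_prob(p, "upper", object$control))
    } else {
      qs <- tryCatch(ddm_fpt_quantiles(p, probs, "upper", object$control),
                     error = function(e) rep(NA_real_, length(probs)))
      data.frame(disparity = lay$cells$disparity[i],
                 advice = lay$cells$advice[i], prob = probs, rt_left = qs)
    }
  })
  do.call(rbind, rows)
}

#' @export
simulate.ddm_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (is.null(seed)) stop("simulate.ddm_fit requires a seed", call. = FALSE)
  lay <- object$layout
  cp <- cells_params(object$theta, lay, object$s)
  reps <- lapply(seq_len(nsim), function(r) {
    rows <- lapply(seq_len(nrow(lay$cells)), function(i) {
      n_i <- object$prep$dat[[i]]$upper$n + object$prep$dat[[i]]$lower$n
      if (n_i == 0) return(NULL)
      p <- ddm_params(v = cp$v[i], a = cp$a[i], z_rel = cp$z[i],
                      ter = cp$ter[i], eta = cp$eta[i], sz = cp$sz[i],
                      st = cp$st[i], s = object$s)
      sim <- simulate_ddm(p, n_i, seed = derive_seed(seed, (r - 1) * 1000 + i),
                          control = object$control)
      data.frame(sim_rep = r, disparity_norm = lay$cells$disparity[i],
                 advice = lay$cells$advice[i], response = sim$response,
                 rt_s = sim$rt, terminated = sim$terminated)
    })
    do.call(rbind, rows)
  })
  do.call(rbind, reps)
}

#' Fit the whole model chain
#'
#' Fits Models `models` in order with warm starts along the nesting chain
#' (1 -> 2, 1 -> 3, 3 -> 4 with z initialised from 2, 4 -> 5), which both
#' speeds convergence and enforces the nesting property in practice.
#'
#' @inheritParams fit_ddm
#' @param models Model ids to fit.
#' @return A named list of [fit_ddm()] results, class `ddm_fit_list`.
#' @export
fit_ddm_set <- function(trials, models = 1:5, ...) {
  args <- list(...)
  fits <- list()
  warm <- function(from, to_spec_id) {
    # map a fitted theta onto a richer model's layout
    if (is.null(from)) return(NULL)
    expand_theta(from, to_spec_id, trials, args)
  }
  for (m in sort(models)) {
    init <- NULL
    if (m == 2 && !is.null(fits[["1"]])) init <- warm(fits[["1"]], 2)
    if (m == 3 && !is.null(fits[["1"]])) init <- warm(fits[["1"]], 3)
    if (m == 4) {
      base <- if (!is.null(fits[["3"]])) fits[["3"]] else fits[["1"]]
      init <- warm(base, 4)
      if (!is.null(init) && !is.null(fits[["2"]])) {
        # seed the advice-split starting points from Model 2
        init <- seed_z_from(init, fits[["2"]], trials, args)
      }
    }
    if (m == 5) {
      base <- if (!is.null(fits[["4"]])) fits[["4"]] else NULL
      init <- warm(base, 5)
    }
    fits[[as.character(m)]] <- do.call(
      fit_ddm, c(list(trials = trials, model = m, init = init), args))
  }
  structure(fits, class = "ddm_fit_list")
}

# project a simpler fit's per-cell parameters onto a richer layout
expand_theta <- function(fit, model_id, trials, args) {
  spec_to <- ddm_model_spec(model_id, fit$spec$disparities,
                            strict = fit$spec$strict)
  lay_to <- build_layout(spec_to, fit$prep$min_rt)
  cp <- cells_params(fit$theta, fit$layout, fit$s)
  theta <- numeric(lay_to$n_par)
  for (p in PARAM_ORDER) {
    g <- lay_to$layout[[p]]
    for (r in seq_len(nrow(g))) {
      sel <- (is.na(g$disparity[r]) |
                lay_to$cells$disparity == g$disparity[r]) &
        (is.na(g$advice[r]) | lay_to$cells$advice == g$advice[r])
      i <- which(sel)[1]
      theta[g$index[r]] <- switch(p, a = cp$a[i], ter = cp$ter[i],
                                  eta = cp$eta[i], z = cp$z[i], v = cp$v[i],
                                  sz = fit$theta[fit$layout$cell_index[i, "sz"]],
                                  st = fit$theta[fit$layout$cell_index[i, "st"]])
    }
  }
  theta
}

seed_z_from <- function(theta4, fit2, trials, args) {
  spec4 <- ddm_model_spec(4, fit2$spec$disparities,
                          strict = fit2$spec$strict)
  lay4 <- build_layout(spec4, fit2$prep$min_rt)
  g <- lay4$layout$z
  cp2 <- cells_params(fit2$theta, fit2$layout, fit2$s)
  for (r in seq_len(nrow(g))) {
    i <- which(lay4$cells$advice == g$advice[r])[1]
    theta4[g$index[r]] <- cp2$z[i]
  }
  theta4
}
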