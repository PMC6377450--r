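#' Compare fitted diffusion models by BIC
#'
#' Ranks a set of fits of the same trial data by [bic_score()] and flags
#' near-ties (BIC difference below `tie_margin`, default 2, conventionally
#' "barely worth mentioning" evidence).
#'
#' @param fits A `ddm_fit_list` from [fit_ddm_set()] (or a plain list of
#'   [fit_ddm()] objects on identical data).
#' @param tie_margin BIC difference below which two models are reported as
#'   indistinguishable.
#' @return An object of class `ddm_comparison`: a table with model id, k,
#'   logLik, BIC, delta-BIC from the best, plus the winner and tie flag.
#' @export
compare_ddm <- function(fits, tie_margin = 2) {
  if (length(fits) < 2) stop("need at least two fits", call. = FALSE)
  fp <- lapply(fits, function(f) f$prep$fingerprint)
  if (!all(vapply(fp, identical, logical(1), y = fp[[1]])))
    stop("fits were not obtained on the same trial set", call. = FALSE)
  tab <- do.call(rbind, lapply(fits, function(f)
    data.frame(model = f$spec$model_id, k = f$k, n = f$n,
               loglik = f$loglik, bic = f$bic, converged = f$converged)))
  tab <- tab[order(tab$bic), ]
  tab$delta_bic <- tab$bic - tab$bic[1]
  rownames(tab) <- NULL
  structure(list(table = tab, best = tab$model[1],
                 tie = nrow(tab) > 1 && tab$delta_bic[2] < tie_margin,
                 tie_margin = tie_margin),
            class = "ddm_comparison")
}

#' @export
print.ddm_comparison <- function(x, ...) {
  cat("Model comparison (BIC, lower is better):\n")
  print(x$table, digits = 6, row.names = FALSE)
  cat(sprintf("Best: Model %d%s\n", x$best,
              if (x$tie) sprintf(" (tie: runner-up within %.3g BIC)",
                                 x$tie_margin) else ""))
  invisible(x)
}

#' Split trials by conformity and refit
#'
#' Partitions the advised trials into conformed (response matched the
#' advice direction) and non-conformed subsets and fits `model` to each.
#' Conditioning on the response makes these descriptive fits: the subsets
#' are outcome-selected, so parameter estimates are biased relative to the
#' generating process and the result carries a `caveat` field saying so.
#'
#' @inheritParams fit_ddm
#' @param min_per_cell Minimum trials required in every disparity-by-advice
#'   cell of each subset; below it the subset is skipped with a warning.
#' @param ... Passed to [fit_ddm()].
#' @return List with `conformed` and `nonconformed` fits (either may be
#'   `NULL`), subset sizes, and `caveat`.
#' @export
split_by_conformity <- function(trials, model = 4, min_per_cell = 5, ...) {
  tr <- trials[!trials$excluded, ]
  if (!all(c("conformed") %in% names(tr)))
    stop("trials must carry a 'conformed' column", call. = FALSE)
  out <- list(caveat = paste("subsets are conditioned on the observed",
                             "response; estimates are descriptive, not",
                             "generative"))
  for (lab in c("conformed", "nonconformed")) {
    sub <- tr[if (lab == "conformed") tr$conformed else !tr$conformed, ]
    tabn <- table(sub$disparity_norm, sub$advice)
    if (nrow(sub) == 0 || length(tabn) == 0 || min(tabn) < min_per_cell ||
        length(unique(sub$disparity_norm)) <
          length(unique(tr$disparity_norm))) {
      warning("conformity subset '", lab,
              "' too sparse to fit; skipped", call. = FALSE)
      out[[lab]] <- NULL
    } else {
      out[[lab]] <- fit_ddm(sub, model = model, ...)
    }
    out[[paste0("n_", lab)]] <- nrow(sub)
  }
  out
}

#' Descriptive drift rates by advice direction and conformity
#'
#' For each disparity-by-advice-by-conformity cell, re-estimates the drift
#' rate alone (all other parameters frozen at a reference fit's values) by
#' one-dimensional maximum likelihood on that cell's quantile bins, then
#' summarises by the median across disparities.  Because cells condition on
#' the observed response, these are descriptive effect summaries.
#'
#' @param trials Canonical trial table.
#' @param fit A reference [fit_ddm()] object supplying the frozen
#'   parameters.
#' @param min_n Cells with fewer trials are reported as `NA`.
#' @return List with `cells` (per-cell drift estimates) and `medians`
#'   (median drift by advice-by-conformity), plus the conditioning caveat.
#' @export
drift_by_conformity <- function(trials, fit, min_n = 5) {
  tr <- trials[!trials$excluded & !is.na(trials$rt_s), ]
  q <- quad_nodes(fit$control)
  cp <- cells_params(fit$theta, fit$layout, fit$s)
  cells <- expand.grid(disparity = fit$spec$disparities,
                       advice = c("left", "right"),
                       conformed = c(TRUE, FALSE),
                       stringsAsFactors = FALSE)
  cells$v <- NA_real_
  cells$n <- 0L
  for (i in seq_len(nrow(cells))) {
    ref <- which(fit$layout$cells$disparity == cells$disparity[i] &
                   fit$layout$cells$advice == cells$advice[i])
    sub <- tr[tr$disparity_norm == cells$disparity[i] &
                tr$advice == cells$advice[i] &
                tr$conformed == cells$conformed[i], ]
    cells$n[i] <- nrow(sub)
    if (nrow(sub) < min_n) next
    dat <- lapply(c("upper", "lower"), function(b) {
      rt <- sub$rt_s[sub$response == if (b == "upper") "left" else "right"]
      n <- length(rt)
      edges <- if (n >= 10)
        unique(unname(stats::quantile(rt, c(.1, .3, .5, .7, .9))))
      else if (n >= 2) unique(unname(stats::quantile(rt, c(1/3, 2/3))))
      else numeric(0)
      list(edges = edges,
           counts = tabulate(findInterval(rt, edges) + 1L,
                             nbins = length(edges) + 1L))
    })
    nll_v <- function(v) cpp_cell_negloglik(
      dat[[1]]$counts, dat[[2]]$counts, dat[[1]]$edges, dat[[2]]$edges,
      v, cp$a[ref], cp$z[ref], cp$ter[ref], cp$eta[ref], cp$sz[ref],
      cp$st[ref], fit$s, q$ghx, q$ghw, q$glx, q$glw, fit$control$tol)
    cells$v[i] <- stats::optimize(nll_v, c(-2, 2))$minimum
  }
  medians <- stats::aggregate(v ~ advice + conformed, data = cells,
                              FUN = stats::median, na.rm = TRUE,
                              na.action = stats::na.pass)
  list(cells = cells, medians = medians,
       caveat = paste("cells condition on the observed response;",
                      "values are descriptive summaries"))
}

#' Bootstrap confidence intervals for advice-effect parameters
#'
#' Stratified nonparametric bootstrap for the advice effects of a fitted
#' model: trials are resampled with replacement within each
#' disparity-by-advice cell, and on each replicate the drift and
#' starting-point parameters are re-estimated with the nuisance parameters
#' (`a`, `ter`, `eta`, `sz`, `st`) frozen at the point estimates and a warm
#' start at the fitted values.  Reported statistics are the per-disparity
#' advice drift difference `dv = v(left advice) - v(right advice)`, their
#' mean, and the starting points per advice direction.  Percentile
#' intervals are given at `level` and at the Bonferroni-adjusted level
#' across the family of reported tests; `flag` marks parameters whose
#' Bonferroni interval excludes the no-effect value (0 for drift
#' differences, 0.5 for starting points).
#'
#' @param fit A [fit_ddm()] object.
#' @param trials The trial table the fit used.
#' @param n_boot Number of bootstrap replicates.
#' @param seed Seed; each replicate uses a derived sub-seed.
#' @param level Base confidence level.
#' @param boot_control [ddm_control()] for the replicate refits (defaults
#'   to a coarser quadrature than the fit's, which changes the objective
#'   by far less than resampling noise).
#' @param max_iter Iteration cap per replicate refit.
#' @return An object of class `ddm_ci` with the interval table, the
#'   replicate draws, and a `widened` warning flag when any stratum had
#'   fewer than 5 trials.
#' @export
ddm_param_cis <- function(fit, trials, n_boot = 200, seed = 1,
                          level = 0.95, boot_control = NULL,
                          max_iter = 40) {
  tr <- trials[!trials$excluded & !is.na(trials$rt_s), ]
  if (is.null(boot_control))
    boot_control <- ddm_control(tol = 1e-6, eta_nodes = 5, sz_nodes = 3,
                                st_nodes = 3)
  q <- quad_nodes(boot_control)
  lay <- fit$layout
  free <- sort(c(lay$layout$v$index, lay$layout$z$index))
  strata <- split(seq_len(nrow(tr)),
                  interaction(tr$disparity_norm, tr$advice, drop = TRUE))
  widened <- any(vapply(strata, length, integer(1)) < 5)
  if (widened)
    warning("some disparity-by-advice strata have < 5 trials; ",
            "bootstrap intervals may be unstable", call. = FALSE)
  stat_of <- function(theta) {
    cp <- cells_params(theta, lay, fit$s)
    le <- lay$cells$advice == "left"
    dv <- cp$v[le] - cp$v[!le]
    zl <- cp$z[which(le)[1]]; zr <- cp$z[which(!le)[1]]
    c(stats::setNames(dv, paste0("dv.d", signif(lay$cells$disparity[le], 3))),
      dv_mean = mean(dv), z_left = zl, z_right = zr)
  }
  point <- stat_of(fit$theta)
  draws <- matrix(NA_real_, n_boot, length(point),
                  dimnames = list(NULL, names(point)))
  for (b in seq_len(n_boot)) {
    set.seed(derive_seed(seed, b))
    idx <- unlist(lapply(strata, function(ix)
      ix[sample.int(length(ix), length(ix), replace = TRUE)]),
      use.names = FALSE)
    boot_tr <- tr[idx, ]
    prep_b <- suppressWarnings(prep_cells(boot_tr, fit$spec, fit$probs))
    obj <- function(th) cells_nll(th, lay, prep_b, q, boot_control$tol,
                                  fit$s)
    gr <- function(th) cells_nll_grad(th, lay, prep_b, q,
                                      boot_control$tol, fit$s, free)
    res <- tryCatch(
      stats::nlminb(fit$theta, obj, gradient = gr, lower = lay$lower,
                    upper = lay$upper,
                    control = list(iter.max = max_iter)),
      error = function(e) NULL)
    if (!is.null(res)) {
      th <- fit$theta
      th[free] <- res$par[free]
      draws[b, ] <- stat_of(th)
    }
  }
  ok <- stats::complete.cases(draws)
  draws <- draws[ok, , drop = FALSE]
  alpha <- 1 - level
  m <- sum(grepl("^dv\\.", names(point))) + 2  # dv family + two z's
  qs <- function(x, a) unname(stats::quantile(x, c(a / 2, 1 - a / 2)))
  tab <- do.call(rbind, lapply(names(point), function(nm) {
    ci <- qs(draws[, nm], alpha)
    cib <- qs(draws[, nm], alpha / m)
    null0 <- if (grepl("^z_", nm)) 0.5 else 0
    data.frame(param = nm, estimate = unname(point[nm]),
               lower = ci[1], upper = ci[2],
               lower_bonf = cib[1], upper_bonf = cib[2],
               null_value = null0,
               flag = cib[1] > null0 || cib[2] < null0)
  }))
  rownames(tab) <- NULL
  structure(list(table = tab, draws = draws, level = level,
                 n_boot = n_boot, n_effective = nrow(draws),
                 widened = widened, seed = seed),
            class = "ddm_ci")
}

#' @export
print.ddm_ci <- function(x, ...) {
  cat(sprintf("Stratified bootstrap CIs (%d/%d replicates, level %.2f, Bonferroni-adjusted flags):\n",
              x$n_effective, x$n_boot, x$level))
  print(x$table, digits = 4, row.names = FALSE)
  if (x$widened) cat("Note: sparse strata; intervals may be unstable.\n")
  invisible(x)
}

#' Goodness-of-fit diagnostics for a fitted diffusion model
#'
#' Returns, per disparity-by-advice cell, (i) the observed versus predicted
#' probability of a leftward response, and (ii) the empirical versus
#' model-implied defective RT CDFs per response boundary on a common time
#' grid, plus summary discrepancy statistics.
#'
#' @param fit A [fit_ddm()] object.
#' @param trials The trial table the fit used.
#' @param grid_n Number of time points per cell for the CDF comparison.
#' @return An object of class `ddm_diagnostics` with elements `choice`
#'   (per-cell P(left)), `cdf` (long table), `bins` (observed vs expected
#'   bin counts from the fit), and `max_cdf_gap`.
#' @export
ddm_diagnostics <- function(fit, trials, grid_n = 50) {
  tr <- trials[!trials$excluded & !is.na(trials$rt_s), ]
  lay <- fit$layout
  cp <- cells_params(fit$theta, lay, fit$s)
  choice <- list(); cdfs <- list()
  for (i in seq_len(nrow(lay$cells))) {
    sub <- tr[tr$disparity_norm == lay$cells$disparity[i] &
                tr$advice == lay$cells$advice[i], ]
    if (nrow(sub) == 0) next
    p <- ddm_params(v = cp$v[i], a = cp$a[i], z_rel = cp$z[i],
                    ter = cp$ter[i], eta = cp$eta[i], sz = cp$sz[i],
                    st = cp$st[i], s = fit$s)
    pl_hat <- ddm_choice_prob(p, "upper", fit$control)
    choice[[i]] <- data.frame(
      disparity = lay$cells$disparity[i], advice = lay$cells$advice[i],
      n = nrow(sub), p_left_obs = mean(sub$response == "left"),
      p_left_pred = pl_hat)
    tgrid <- seq(min(sub$rt_s), max(sub$rt_s), length.out = grid_n)
    for (b in c("upper", "lower")) {
      rsp <- if (b == "upper") "left" else "right"
      emp <- vapply(tgrid, function(t0)
        mean(sub$rt_s <= t0 & sub$response == rsp), numeric(1))
      mod <- ddm_fpt_cdf(tgrid, p, boundary = b, control = fit$control)
      cdfs[[length(cdfs) + 1L]] <- data.frame(
        disparity = lay$cells$disparity[i], advice = lay$cells$advice[i],
        boundary = b, t = tgrid, empirical = emp, predicted = mod)
    }
  }
  choice <- do.call(rbind, choice)
  cdf <- do.call(rbind, cdfs)
  structure(list(choice = choice, cdf = cdf, bins = fit$diagnostics,
                 max_cdf_gap = max(abs(cdf$empirical - cdf$predicted)),
                 max_choice_gap = max(abs(choice$p_left_obs -
                                            choice$p_left_pred))),
            class = "ddm_diagnostics")
}

#' @export
print.ddm_diagnostics <- function(x, ...) {
  cat(sprintf("Diagnostics over %d cells: max |P(left) obs - pred| = %.4f, max defective-CDF gap = %.4f\n",
              nrow(x$choice), x$max_choice_gap, x$max_cdf_gap))
  invisible(x)
}
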