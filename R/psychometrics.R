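#' Normalize a disparity range to [-1, 1]
#'
#' Divides disparities by the largest absolute disparity so that each
#' participant's largest tested disparity maps to +/-1; zero maps to zero
#' and signs are preserved.  Idempotent on already-normalized sets.
#'
#' @param disparity Numeric vector of signed disparities (degrees or any
#'   common unit); at least one value must be nonzero.
#' @return Numeric vector in [-1, 1].
#' @export
#' @examples
#' normalize_disparity(c(-0.03, -0.02, -0.01, 0, 0.01, 0.02, 0.03))
normalize_disparity <- function(disparity) {
  m <- max(abs(disparity), na.rm = TRUE)
  if (!is.finite(m) || m == 0)
    stop("cannot normalize an all-zero disparity set", call. = FALSE)
  disparity / m
}

#' Aggregate trial-level responses to binomial points
#'
#' @param disparity Signed stimulus disparity per trial.
#' @param response `"left"`/`"right"` per trial.
#' @return A data.frame with columns `disparity`, `n_left`, `n_total`.
#' @export
psych_points <- function(disparity, response) {
  stopifnot(length(disparity) == length(response))
  keep <- !is.na(response) & !is.na(disparity)
  disparity <- disparity[keep]; response <- response[keep]
  lev <- sort(unique(disparity))
  n_left <- vapply(lev, function(d) sum(response[disparity == d] == "left"),
                   numeric(1))
  n_total <- vapply(lev, function(d) sum(disparity == d), numeric(1))
  data.frame(disparity = lev, n_left = n_left, n_total = n_total)
}

# adjusted R^2 of fitted vs observed proportions with p model parameters
adj_r2_points <- function(obs, fitted, p) {
  n <- length(obs)
  ss_res <- sum((obs - fitted)^2)
  ss_tot <- sum((obs - mean(obs))^2)
  r2 <- if (ss_tot <= 0) 1 else 1 - ss_res / ss_tot
  if (n - p - 1 <= 0) return(NA_real_)
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

#' Fit a cumulative-Gaussian psychometric function
#'
#' Fits `P(left | d) = Phi((d - mu) / sigma)` to binomial response counts.
#' The default is binomial maximum likelihood (probit regression), which
#' weights unequal cell counts correctly; `method = "ls"` provides an
#' unweighted least-squares fit on proportions for fidelity with
#' curve-plot-based fitting.  `sigma` is the slope parameter and doubles as
#' the disparity threshold (the SD of the fitted Gaussian).
#'
#' Degenerate data are flagged, not silently accepted: perfectly separable
#' responses pin `sigma` at its lower bound and flat (all-50 percent) data
#' pin it at its upper bound, with `converged = FALSE` in both cases.
#'
#' @param points A data.frame with columns `disparity`, `n_left`, `n_total`
#'   (see [psych_points()]); at least 3 distinct disparities.
#' @param method `"ml"` (binomial likelihood, default) or `"ls"`.
#' @return An object of class `psych_fit` with elements `mu`, `sigma`
#'   (threshold), `adj_r2`, `converged`, `points`, `fitted`.
#' @export
fit_psychometric <- function(points, method = c("ml", "ls")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(points),
            all(c("disparity", "n_left", "n_total") %in% names(points)))
  points <- points[points$n_total > 0, ]
  if (length(unique(points$disparity)) < 3)
    stop("need at least 3 distinct disparity levels", call. = FALSE)
  if (any(points$n_left < 0 | points$n_left > points$n_total))
    stop("invalid counts: need 0 <= n_left <= n_total", call. = FALSE)
  rng <- max(abs(points$disparity))
  sig_lo <- 1e-3 * rng
  sig_hi <- 1e3 * rng
  prop <- points$n_left / points$n_total

  if (method == "ml") {
    fit <- suppressWarnings(
      stats::glm(cbind(n_left, n_total - n_left) ~ disparity,
                 family = stats::binomial("probit"), data = points))
    b <- stats::coef(fit)
    slope <- b[["disparity"]]
    converged <- isTRUE(fit$converged) && is.finite(slope)
    if (!is.finite(slope) || slope <= 1 / sig_hi) {
      sigma <- sig_hi; mu <- -b[[1]] * sig_hi; converged <- FALSE
    } else {
      sigma <- 1 / slope
      mu <- -b[[1]] / slope
      if (sigma < sig_lo) { sigma <- sig_lo; converged <- FALSE }
      if (sigma > sig_hi) { sigma <- sig_hi; converged <- FALSE }
    }
    # separable data inflate coefficients without tripping glm$converged
    if (any(abs(stats::predict(fit)) > 7)) converged <- FALSE
  } else {
    sse <- function(par) {
      sum((prop - stats::pnorm((points$disparity - par[1]) /
                                 exp(par[2])))^2)
    }
    o <- stats::optim(c(0, log(rng / 2)), sse, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
    mu <- o$par[1]; sigma <- exp(o$par[2])
    converged <- o$convergence == 0 && sigma > sig_lo && sigma < sig_hi
    sigma <- min(max(sigma, sig_lo), sig_hi)
  }
  fitted <- stats::pnorm((points$disparity - mu) / sigma)
  structure(list(mu = unname(mu), sigma = unname(sigma),
                 threshold = unname(sigma),
                 adj_r2 = adj_r2_points(prop, fitted, 2),
                 converged = converged, method = method,
                 points = points, fitted = fitted),
            class = "psych_fit")
}

#' @export
print.psych_fit <- function(x, ...) {
  cat("Cumulative-Gaussian psychometric fit (", x$method, ")\n", sep = "")
  cat(sprintf("  mu = %.4g  sigma (threshold) = %.4g  adj R2 = %.3f  %s\n",
              x$mu, x$sigma, x$adj_r2,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
coef.psych_fit <- function(object, ...) {
  c(mu = object$mu, sigma = object$sigma)
}

#' @export
predict.psych_fit <- function(object, disparity = object$points$disparity,
                              ...) {
  stats::pnorm((disparity - object$mu) / object$sigma)
}

#' Paired psychometric fit by advice direction
#'
#' Fits one cumulative Gaussian per advice direction.  With
#' `shared_slope = TRUE` (the default) the two curves share a common slope
#' and the bias is the signed horizontal offset between them:
#' `shift = mu_right - mu_left`, positive when responses are displaced
#' toward the advised direction (positive disparity = leftward signal,
#' advice "left" pulls the curve toward negative disparities).
#'
#' An optional nonparametric bootstrap (resampling trials within
#' disparity-by-advice cells) gives a percentile confidence interval for the
#' shift.
#'
#' @param points_left,points_right Binomial points (see [psych_points()])
#'   under advice "left" and advice "right"; each needs >= 3 disparity
#'   levels.
#' @param shared_slope Constrain both curves to a common sigma.
#' @param n_boot Bootstrap replicates for the shift CI (0 = none).
#' @param seed Seed for the bootstrap (required if `n_boot > 0`).
#' @param level Confidence level.
#' @return An object of class `psych_pair_fit`: `mu_left`, `mu_right`,
#'   `sigma` (common, or per-curve vector), `shift`, `adj_r2`, `converged`,
#'   `ci` (or NULL).
#' @export
fit_paired_psychometric <- function(points_left, points_right,
                                    shared_slope = TRUE, n_boot = 0,
                                    seed = NULL, level = 0.95) {
  for (nm in c("left", "right")) {
    pts <- if (nm == "left") points_left else points_right
    if (!is.data.frame(pts) || nrow(pts) == 0 || all(pts$n_total == 0))
      stop("empty advice cell: advice-", nm, call. = FALSE)
    if (length(unique(pts$disparity[pts$n_total > 0])) < 3)
      stop("advice-", nm, " needs >= 3 disparity levels", call. = FALSE)
  }
  est <- paired_probit_estimate(points_left, points_right, shared_slope)
  ci <- NULL
  if (n_boot > 0) {
    if (is.null(seed)) stop("bootstrap requires a seed", call. = FALSE)
    shifts <- numeric(n_boot)
    set.seed(seed)
    for (b in seq_len(n_boot)) {
      bl <- points_left; br <- points_right
      bl$n_left <- stats::rbinom(nrow(bl), bl$n_total,
                                 ifelse(bl$n_total > 0,
                                        bl$n_left / pmax(bl$n_total, 1), 0))
      br$n_left <- stats::rbinom(nrow(br), br$n_total,
                                 ifelse(br$n_total > 0,
                                        br$n_left / pmax(br$n_total, 1), 0))
      shifts[b] <- paired_probit_estimate(bl, br, shared_slope)$shift
    }
    alpha <- (1 - level) / 2
    ci <- unname(stats::quantile(shifts, c(alpha, 1 - alpha), na.rm = TRUE))
  }
  structure(c(est, list(ci = ci, level = level, n_boot = n_boot)),
            class = "psych_pair_fit")
}

# core paired probit estimator; returns estimates without validation
paired_probit_estimate <- function(points_left, points_right,
                                   shared_slope = TRUE) {
  dat <- rbind(cbind(points_left, advice = "left"),
               cbind(points_right, advice = "right"))
  dat <- dat[dat$n_total > 0, ]
  prop <- dat$n_left / dat$n_total
  if (shared_slope) {
    fit <- suppressWarnings(
      stats::glm(cbind(n_left, n_total - n_left) ~ disparity + advice,
                 family = stats::binomial("probit"), data = dat))
    b <- stats::coef(fit)
    slope <- b[["disparity"]]
    mu_l <- -b[[1]] / slope
    mu_r <- -(b[[1]] + b[["adviceright"]]) / slope
    sigma <- 1 / slope
    converged <- isTRUE(fit$converged) && is.finite(slope) && slope > 0
    fitted <- stats::fitted(fit)
    k <- 3
  } else {
    fl <- fit_psychometric(points_left)
    fr <- fit_psychometric(points_right)
    mu_l <- fl$mu; mu_r <- fr$mu
    sigma <- c(left = fl$sigma, right = fr$sigma)
    converged <- fl$converged && fr$converged
    fitted <- c(fl$fitted, fr$fitted)[seq_len(nrow(dat))]
    fitted <- ifelse(dat$advice == "left",
                     stats::pnorm((dat$disparity - fl$mu) / fl$sigma),
                     stats::pnorm((dat$disparity - fr$mu) / fr$sigma))
    k <- 4
  }
  list(mu_left = unname(mu_l), mu_right = unname(mu_r),
       sigma = unname(sigma), shift = unname(mu_r - mu_l),
       adj_r2 = adj_r2_points(prop, fitted, k),
       converged = converged, shared_slope = shared_slope, data = dat)
}

#' @export
print.psych_pair_fit <- function(x, ...) {
  cat("Paired psychometric fit by advice direction",
      if (x$shared_slope) "(shared slope)\n" else "(free slopes)\n")
  cat(sprintf("  mu_left = %.4g  mu_right = %.4g  sigma = %s\n",
              x$mu_left, x$mu_right,
              paste(signif(x$sigma, 4), collapse = "/")))
  cat(sprintf("  shift (positive = toward advice) = %.4g   adj R2 = %.3f\n",
              x$shift, x$adj_r2))
  if (!is.null(x$ci))
    cat(sprintf("  %.0f%% bootstrap CI for shift: [%.4g, %.4g] (%d reps)\n",
                100 * x$level, x$ci[1], x$ci[2], x$n_boot))
  invisible(x)
}

#' One curve versus two advice-specific curves
#'
#' Tests whether responses are better described by two shared-slope curves
#' (one per advice direction) than by a single curve on the pooled data.
#' Reports adjusted R-squared for both models, an extra-sum-of-squares
#' F-style p-value, and (the default inferential choice) a permutation
#' p-value obtained by permuting advice labels within each disparity.
#'
#' @inheritParams fit_paired_psychometric
#' @param n_perm Number of permutations (0 skips the permutation test).
#' @param seed Seed for the permutation draw.
#' @return A list: `adj_r2_one`, `adj_r2_two`, `p_value` (permutation, or
#'   F-based when `n_perm = 0`), `p_f`, `f_stat`, `shift`.
#' @export
compare_curve_counts <- function(points_left, points_right, n_perm = 2000,
                                 seed = NULL) {
  two <- paired_probit_estimate(points_left, points_right, TRUE)
  pooled <- merge_points(points_left, points_right)
  one <- fit_psychometric(pooled)
  dat <- two$data
  prop <- dat$n_left / dat$n_total
  fit1 <- stats::pnorm((dat$disparity - one$mu) / one$sigma)
  fit2 <- stats::pnorm((dat$disparity -
                          ifelse(dat$advice == "left", two$mu_left,
                                 two$mu_right)) /
                         (if (length(two$sigma) == 1) two$sigma
                          else two$sigma[match(dat$advice,
                                               c("left", "right"))]))
  rss1 <- sum((prop - fit1)^2)
  rss2 <- sum((prop - fit2)^2)
  n <- nrow(dat)
  f_stat <- if (rss2 <= 0) Inf else ((rss1 - rss2) / 1) / (rss2 / (n - 3))
  p_f <- stats::pf(f_stat, 1, n - 3, lower.tail = FALSE)
  p_perm <- NA_real_
  if (n_perm > 0) {
    if (is.null(seed)) stop("permutation test requires a seed", call. = FALSE)
    obs <- abs(two$shift)
    set.seed(seed)
    lev <- sort(unique(c(points_left$disparity, points_right$disparity)))
    pl <- points_left[match(lev, points_left$disparity), ]
    pr <- points_right[match(lev, points_right$disparity), ]
    pl$n_left[is.na(pl$n_left)] <- 0; pl$n_total[is.na(pl$n_total)] <- 0
    pr$n_left[is.na(pr$n_left)] <- 0; pr$n_total[is.na(pr$n_total)] <- 0
    pl$disparity <- lev; pr$disparity <- lev
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      # permuting advice labels within disparity == hypergeometric
      # reallocation of left-responses between the two advice groups
      xl <- stats::rhyper(length(lev), pl$n_left + pr$n_left,
                          (pl$n_total - pl$n_left) +
                            (pr$n_total - pr$n_left), pl$n_total)
      bl <- data.frame(disparity = lev, n_left = xl, n_total = pl$n_total)
      br <- data.frame(disparity = lev,
                       n_left = pl$n_left + pr$n_left - xl,
                       n_total = pr$n_total)
      sh <- tryCatch(paired_probit_estimate(bl, br, TRUE)$shift,
                     error = function(e) NA_real_)
      if (!is.na(sh) && abs(sh) >= obs) exceed <- exceed + 1L
    }
    p_perm <- (1 + exceed) / (1 + n_perm)
  }
  list(adj_r2_one = adj_r2_points(prop, fit1, 2),
       adj_r2_two = two$adj_r2,
       p_value = if (n_perm > 0) p_perm else p_f,
       p_perm = p_perm, p_f = p_f, f_stat = f_stat, shift = two$shift)
}

merge_points <- function(a, b) {
  lev <- sort(unique(c(a$disparity, b$disparity)))
  ia <- match(lev, a$disparity); ib <- match(lev, b$disparity)
  na <- function(x) ifelse(is.na(x), 0, x)
  data.frame(disparity = lev,
             n_left = na(a$n_left[ia]) + na(b$n_left[ib]),
             n_total = na(a$n_total[ia]) + na(b$n_total[ib]))
}

#' Advice effect per disparity across participants
#'
#' At each disparity, compares participants' proportions of "left" responses
#' under left versus right advice with a two-sided Wilcoxon rank-sum test,
#' Bonferroni-corrected across disparities at family-wise 0.05.
#'
#' @param trials A canonical trial table (see [read_trials()]); excluded
#'   trials are ignored.
#' @param alpha Family-wise significance level.
#' @return A data.frame with one row per disparity: `disparity`, `n_left_adv`,
#'   `n_right_adv` (participant counts), `p`, `p_bonf`, `significant`,
#'   `direction` (`"toward"`/`"against"` advice, for significant rows).
#' @export
advice_effect_by_disparity <- function(trials, alpha = 0.05) {
  tr <- trials[!trials$excluded & !is.na(trials$response), ]
  lev <- sort(unique(tr$disparity_norm))
  res <- lapply(lev, function(d) {
    sub <- tr[tr$disparity_norm == d, ]
    pl <- tapply(sub$response == "left", sub$participant, mean)
    al <- tapply(sub$advice, sub$participant, function(a) a[1])
    # per-participant proportions within each advice direction
    agg <- stats::aggregate(I(sub$response == "left"),
                            by = list(participant = sub$participant,
                                      advice = sub$advice), FUN = mean)
    x <- agg$x[agg$advice == "left"]
    y <- agg$x[agg$advice == "right"]
    if (length(x) < 2 || length(y) < 2) {
      warning("disparity ", signif(d, 3),
              ": fewer than 2 participants per advice direction; excluded",
              call. = FALSE)
      return(data.frame(disparity = d, n_left_adv = length(x),
                        n_right_adv = length(y), p = NA_real_))
    }
    p <- if (isTRUE(all.equal(mean(x), mean(y))) &&
             stats::sd(c(x, y)) == 0) 1
         else suppressWarnings(stats::wilcox.test(x, y)$p.value)
    data.frame(disparity = d, n_left_adv = length(x),
               n_right_adv = length(y), p = p,
               dir_raw = mean(x) - mean(y))
  })
  out <- do.call(rbind, lapply(res, function(r) {
    if (!"dir_raw" %in% names(r)) r$dir_raw <- NA_real_
    r
  }))
  m <- sum(!is.na(out$p))
  out$p_bonf <- pmin(out$p * m, 1)
  out$significant <- !is.na(out$p_bonf) & out$p_bonf < alpha
  # advice-left raises P(left): effect toward advice when x > y
  out$direction <- ifelse(out$significant,
                          ifelse(out$dir_raw > 0, "toward", "against"),
                          NA_character_)
  out$dir_raw <- NULL
  rownames(out) <- NULL
  out
}

#' Per-participant psychometric fit table
#'
#' Runs the paired shared-slope fit, the one-vs-two-curve comparison, and
#' (optionally) the bootstrap shift CI for every participant in a trial
#' table, on normalized disparities.
#'
#' @inheritParams advice_effect_by_disparity
#' @param n_boot Bootstrap replicates for each shift CI (0 = skip).
#' @param n_perm Permutations for each one-vs-two comparison (0 = F-test
#'   p-value only).
#' @param seed Master seed; per-participant seeds are derived from it.
#' @return A data.frame with one row per participant: `participant`, `group`,
#'   `mu_left`, `mu_right`, `sigma`, `shift`, `adj_r2_one`, `adj_r2_two`,
#'   `p_two_vs_one`, `ci_low`, `ci_high`, `converged`.
#' @export
psychometric_summary <- function(trials, n_boot = 0, n_perm = 0, seed = 1) {
  tr <- trials[!trials$excluded & !is.na(trials$response), ]
  ids <- unique(tr$participant)
  rows <- lapply(seq_along(ids), function(i) {
    sub <- tr[tr$participant == ids[i], ]
    pl <- psych_points(sub$disparity_norm[sub$advice == "left"],
                       sub$response[sub$advice == "left"])
    pr <- psych_points(sub$disparity_norm[sub$advice == "right"],
                       sub$response[sub$advice == "right"])
    fit <- fit_paired_psychometric(pl, pr, shared_slope = TRUE,
                                   n_boot = n_boot,
                                   seed = if (n_boot > 0)
                                     derive_seed(seed, i) else NULL)
    cmp <- compare_curve_counts(pl, pr, n_perm = n_perm,
                                seed = if (n_perm > 0)
                                  derive_seed(seed, i + 10000L) else NULL)
    data.frame(participant = ids[i], group = sub$group[1],
               mu_left = fit$mu_left, mu_right = fit$mu_right,
               sigma = fit$sigma[1], shift = fit$shift,
               adj_r2_one = cmp$adj_r2_one, adj_r2_two = cmp$adj_r2_two,
               p_two_vs_one = cmp$p_value,
               ci_low = if (is.null(fit$ci)) NA_real_ else fit$ci[1],
               ci_high = if (is.null(fit$ci)) NA_real_ else fit$ci[2],
               converged = fit$converged)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
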