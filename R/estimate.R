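#' Direct (binned) modified liquid association estimate
#'
#' The robust direct estimator of modified liquid association (MLA).
#' MLA is `E[rho(Z) * Z]` — the correlation of the pair as a function of
#' the (standardized) controller, weighted by the controller value; by
#' Stein's lemma this equals the average derivative `E[rho'(Z)]` for a
#' normal controller.  The estimator discretizes the controller: samples
#' are split into `n_bins` equal-count bins on `x3`; within each bin
#' `x1` and `x2` are re-centered and re-scaled to mean 0, sd 1 (removing
#' any conditional mean/variance dependence on `x3`, the "modified"
#' adjustment), giving the within-bin correlation; the estimate is the
#' bin-size-weighted sum of (within-bin correlation) x (bin score):
#' \deqn{\widehat{MLA} = \sum_b \frac{n_b}{n}\, \hat\rho_b\, s_b,}
#' where the score `s_b = E[Z | Z in bin b]` is the expected value of a
#' standard normal within the bin's quantile range (for tertiles,
#' -1.091, 0, +1.091).  Equivalently, the overall mean of
#' `x1* . x2* . z` with `z` the discretized controller.  The theoretical
#' scores are appropriate because each gene is quantile-transformed to
#' marginal normality upstream; substituting them for the noisy
#' empirical bin means makes the estimate depend on the controller only
#' through ranks.  As the bin count grows the score magnitudes approach
#' `E|Z| = sqrt(2/pi)`, which bounds the estimate.
#'
#' Three bins is the default: with the 20-30 samples per bin typical of
#' expression studies it minimizes the mean squared error of the
#' estimate.
#'
#' @param x1,x2,x3 numeric vectors of equal length (standardized
#'   expression); samples missing in any of the three are dropped.
#' @param n_bins number of controller bins (default 3).
#' @return scalar MLA estimate.
#' @export
mla_direct <- function(x1, x2, x3, n_bins = 3L) {
  stopifnot(length(x1) == length(x2), length(x2) == length(x3))
  ok <- !(is.na(x1) | is.na(x2) | is.na(x3))
  x1 <- x1[ok]; x2 <- x2[ok]; x3 <- x3[ok]
  n <- length(x3)
  if (n < 3L * n_bins) {
    stop("need at least ", 3L * n_bins, " complete samples", call. = FALSE)
  }
  bins <- equal_count_bins(x3, n_bins)
  scores <- .bin_scores(n_bins)
  total <- 0
  for (b in seq_along(bins)) {
    idx <- bins[[b]]
    z1 <- x1[idx]; z2 <- x2[idx]
    if (max(z1) == min(z1) || max(z2) == min(z2)) {
      stop("zero within-bin variance; direct MLA estimate undefined",
           call. = FALSE)
    }
    rho_b <- stats::cor(z1, z2)
    if (!is.finite(rho_b)) {
      stop("undefined within-bin correlation; direct MLA estimate undefined",
           call. = FALSE)
    }
    total <- total + length(idx) * rho_b * scores[b]
  }
  total / n
}

# Expected value of a standard normal within each of n_bins equal-
# probability bins: s_b = n_bins * (phi(q_{b-1}) - phi(q_b)) with q the
# bin boundaries on the quantile scale.
.bin_scores <- function(n_bins) {
  q <- stats::qnorm(seq(0, 1, length.out = n_bins + 1L))
  n_bins * (stats::dnorm(q[-length(q)]) - stats::dnorm(q[-1L]))
}

# Rows of mat standardized within the sample index set to mean 0 and
# *mean-square* 1 (population sd), so tcrossprod(Z)/n_b is the within-bin
# correlation matrix.  Complete data only (the vectorized validation
# path); genes with zero within-bin variance propagate NaN.
.bin_standardize <- function(mat, idx) {
  X <- mat[, idx, drop = FALSE]
  Z <- X - rowMeans(X)
  Z / sqrt(rowSums(Z * Z) / ncol(X))
}

#' Direct MLA estimates for all pairs under one controller
#'
#' Vectorized form of [mla_direct()]: for a fixed controller, the whole
#' gene-by-gene matrix of direct MLA estimates is obtained from per-bin
#' cross-products of the bin-standardized expression submatrix weighted
#' by the normal bin scores — the same one-pass matrix algebra
#' as the `rho_diff` screen.  Requires a complete (no `NA`) matrix.
#' Each entry equals
#' `mla_direct(mat[i, ], mat[j, ], mat[controller, ], n_bins)`.
#'
#' @inheritParams rho_diff_for_controller
#' @param n_bins number of controller bins (default 3).
#' @return symmetric numeric matrix of MLA estimates (diagonal not
#'   meaningful).
#' @export
mla_direct_for_controller <- function(mat, controller, n_bins = 3L) {
  mat <- .validate_expression(mat)
  if (anyNA(mat)) stop("vectorized MLA path requires a complete matrix",
                       call. = FALSE)
  if (!controller %in% rownames(mat)) {
    stop("controller gene not in matrix: ", controller, call. = FALSE)
  }
  x3 <- mat[controller, ]
  bins <- equal_count_bins(x3, n_bins)
  scores <- .bin_scores(n_bins)
  G <- nrow(mat)
  M <- matrix(0, G, G, dimnames = dimnames(mat)[c(1L, 1L)])
  for (b in seq_along(bins)) {
    Z <- .bin_standardize(mat, bins[[b]])
    M <- M + scores[b] * tcrossprod(Z)       # n_b * rho_b * s_b
  }
  M / length(x3)
}

# Negative log-likelihood of the trivariate conditional normal model.
# theta layout (full): m10 m11 m20 m21 v10 v11 v20 v21 c0 c1
#        (simple):     m10 m20 v10 v20 c0 c1  (slopes fixed at 0)
# Given z: (x1, x2) ~ BVN(mu_i = m_i0 + m_i1 z, sigma_i^2 = exp(v_i0 +
# v_i1 z), rho = tanh(c0 + c1 z)).
.cnm_negloglik <- function(theta, x1, x2, z, full) {
  if (full) {
    m10 <- theta[1L]; m11 <- theta[2L]; m20 <- theta[3L]; m21 <- theta[4L]
    v10 <- theta[5L]; v11 <- theta[6L]; v20 <- theta[7L]; v21 <- theta[8L]
    c0 <- theta[9L]; c1 <- theta[10L]
  } else {
    m10 <- theta[1L]; m20 <- theta[2L]
    v10 <- theta[3L]; v20 <- theta[4L]
    c0 <- theta[5L]; c1 <- theta[6L]
    m11 <- m21 <- v11 <- v21 <- 0
  }
  lv1 <- v10 + v11 * z
  lv2 <- v20 + v21 * z
  if (any(abs(lv1) > 50) || any(abs(lv2) > 50)) return(1e10)
  rho <- tanh(c0 + c1 * z)
  omr2 <- pmax(1 - rho * rho, 1e-12)
  a <- (x1 - m10 - m11 * z) / exp(lv1 / 2)
  b <- (x2 - m20 - m21 * z) / exp(lv2 / 2)
  q <- (a * a - 2 * rho * a * b + b * b) / omr2
  nll <- sum(log(2 * pi) + 0.5 * (lv1 + lv2 + log(omr2)) + 0.5 * q)
  if (!is.finite(nll)) 1e10 else nll
}

# Moment-based starting values.  Per-tertile correlations (atanh) are
# regressed on the bin-mean controller value to seed (c0, c1); means and
# log-variances seed the intercepts; for the full model the mean slopes
# come from least squares on z and the log-variance slopes from the
# per-bin log variances.
.cnm_start <- function(x1, x2, z, full) {
  bins <- suppressWarnings(tertile_bins(z))
  idx <- list(bins$low_idx, bins$mid_idx, bins$high_idx)
  zbar <- vapply(idx, function(i) mean(z[i]), 0)
  rho_b <- vapply(idx, function(i) {
    r <- suppressWarnings(stats::cor(x1[i], x2[i]))
    if (!is.finite(r)) 0 else max(min(r, 0.99), -0.99)
  }, 0)
  cfit <- stats::lm.fit(cbind(1, zbar), atanh(rho_b))$coefficients
  if (anyNA(cfit)) cfit <- c(atanh(max(min(stats::cor(x1, x2), .99), -.99)), 0)
  if (!full) {
    c(mean(x1), mean(x2), log(stats::var(x1)), log(stats::var(x2)),
      cfit[1L], cfit[2L])
  } else {
    b1 <- stats::cov(x1, z) / stats::var(z)
    b2 <- stats::cov(x2, z) / stats::var(z)
    lv1 <- vapply(idx, function(i) log(max(stats::var(x1[i]), 1e-8)), 0)
    lv2 <- vapply(idx, function(i) log(max(stats::var(x2[i]), 1e-8)), 0)
    v1 <- stats::lm.fit(cbind(1, zbar), lv1)$coefficients
    v2 <- stats::lm.fit(cbind(1, zbar), lv2)$coefficients
    if (anyNA(v1)) v1 <- c(log(stats::var(x1)), 0)
    if (anyNA(v2)) v2 <- c(log(stats::var(x2)), 0)
    c(mean(x1) - b1 * mean(z), b1, mean(x2) - b2 * mean(z), b2,
      v1[1L], v1[2L], v2[1L], v2[2L], cfit[1L], cfit[2L])
  }
}

#' Fit the conditional normal model to a triplet
#'
#' Maximum-likelihood fit of the trivariate conditional normal model
#' (CNM): given the controller value `z = x3`, the pair `(x1, x2)` is
#' bivariate normal with means linear in `z`, log-variances linear in
#' `z`, and correlation `tanh(c0 + c1 * z)` (Fisher-z link).  The
#' *simple* model fixes the mean and variance slopes at zero, leaving
#' only the correlation to depend on the controller.  `c1` is the
#' liquid-association parameter: its Wald statistic `(c1 / SE)^2`
#' (observed-information standard error) tests for any controller-driven
#' change in correlation.
#'
#' Optimization is quasi-Newton (BFGS) from moment-based starting values
#' (per-tertile correlations via `atanh` seed the correlation
#' coefficients).  A failed optimization returns `converged = FALSE`
#' rather than raising.
#'
#' @param x1,x2,x3 numeric vectors without missing values among jointly
#'   observed samples; `n >= 20` recommended.
#' @param model `"full"` or `"simple"`.
#' @param max_iter,reltol optimizer budget and relative tolerance.
#' @return object of class `"cnm_fit"`: list with `model_tag`, named
#'   coefficient vector `coefs` (always length 10; structural zeros for
#'   the simple model), `loglik`, `converged`, `cov` (parameter
#'   covariance of the free parameters), `se_c1`, `wald`, `pvalue`, and
#'   `mla_estimate` (see [mla_from_cnm()]).
#' @export
fit_cnm <- function(x1, x2, x3, model = c("full", "simple"),
                    max_iter = 500L, reltol = 1e-8) {
  model <- match.arg(model)
  stopifnot(length(x1) == length(x2), length(x2) == length(x3))
  ok <- !(is.na(x1) | is.na(x2) | is.na(x3))
  x1 <- x1[ok]; x2 <- x2[ok]; z <- x3[ok]
  n <- length(z)
  if (n < 10L) stop("too few complete samples (", n, ") to fit the CNM",
                    call. = FALSE)
  if (stats::sd(x1) == 0 || stats::sd(x2) == 0 || stats::sd(z) == 0) {
    stop("degenerate input: a variable is constant", call. = FALSE)
  }
  full <- model == "full"
  start <- .cnm_start(x1, x2, z, full)
  opt <- tryCatch(
    stats::optim(start, .cnm_negloglik, x1 = x1, x2 = x2, z = z, full = full,
                 method = "BFGS", hessian = TRUE,
                 control = list(maxit = max_iter, reltol = reltol)),
    error = function(e) NULL)
  names_full <- c("m10", "m11", "m20", "m21", "v10", "v11", "v20", "v21",
                  "c0", "c1")
  names_simple <- c("m10", "m20", "v10", "v20", "c0", "c1")
  coefs <- stats::setNames(numeric(10L), names_full)
  if (is.null(opt)) {
    return(structure(list(model_tag = model, coefs = coefs, loglik = NA_real_,
                          converged = FALSE, cov = NULL, se_c1 = NA_real_,
                          wald = NA_real_, pvalue = NA_real_,
                          mla_estimate = NA_real_, n = n),
                     class = "cnm_fit"))
  }
  par_names <- if (full) names_full else names_simple
  coefs[par_names] <- opt$par
  ci <- length(opt$par)           # c1 is always the last free parameter
  covm <- tryCatch(solve(opt$hessian), error = function(e) NULL)
  se_c1 <- if (!is.null(covm) && covm[ci, ci] > 0) sqrt(covm[ci, ci]) else NA_real_
  converged <- opt$convergence == 0L && is.finite(se_c1)
  wald <- if (is.finite(se_c1)) unname((coefs["c1"] / se_c1)^2) else NA_real_
  fit <- structure(list(model_tag = model, coefs = coefs,
                        loglik = -opt$value, converged = converged,
                        cov = covm, se_c1 = se_c1, wald = unname(wald),
                        pvalue = if (is.finite(wald)) wald_pvalue(wald) else NA_real_,
                        mla_estimate = NA_real_, n = n),
                   class = "cnm_fit")
  fit$mla_estimate <- mla_from_cnm(fit, z)
  fit
}

#' @export
print.cnm_fit <- function(x, ...) {
  cat("Conditional normal model (", x$model_tag, "), n = ", x$n, "\n",
      sep = "")
  cat("  converged:", x$converged, " loglik:", format(x$loglik), "\n")
  cat("  c0 =", format(x$coefs["c0"]), " c1 =", format(x$coefs["c1"]),
      " (SE", format(x$se_c1), ")\n")
  cat("  Wald =", format(x$wald), " p =", format(x$pvalue),
      " MLA =", format(x$mla_estimate), "\n")
  invisible(x)
}

#' Two-sided p-value for a Wald statistic
#'
#' Maps a Wald statistic (a squared z-ratio, chi-square with 1 df under
#' the null) to its two-sided p-value `2 * pnorm(-sqrt(W))`.
#'
#' @param wald non-negative scalar or vector.
#' @return p-values in `(0, 1]`, strictly decreasing in `wald`.
#' @export
#' @examples
#' wald_pvalue(49.050)
wald_pvalue <- function(wald) {
  if (any(is.na(wald)) || any(wald < 0)) {
    stop("Wald statistic must be non-negative", call. = FALSE)
  }
  2 * stats::pnorm(-sqrt(wald))
}

#' Model-based MLA from a fitted CNM
#'
#' The model-based modified liquid association: the average derivative of
#' the conditional correlation `rho(z) = tanh(c0 + c1 * z)` over the
#' observed controller distribution, `mean(c1 * (1 - tanh(c0 + c1 z)^2))`.
#' Zero exactly when `c1 = 0`; approximately `c1` itself for small `c1`
#' on a standardized controller.
#'
#' @param fit a converged [fit_cnm()] result.
#' @param x3 controller values over which to average.
#' @return scalar MLA estimate.
#' @export
mla_from_cnm <- function(fit, x3) {
  stopifnot(inherits(fit, "cnm_fit"))
  z <- x3[!is.na(x3)]
  c0 <- fit$coefs["c0"]; c1 <- fit$coefs["c1"]
  unname(c1 * mean(1 - tanh(c0 + c1 * z)^2))
}

#' Lack-of-fit diagnostic for a fitted CNM
#'
#' Decides whether the conditional normal model adequately describes a
#' triplet.  The model is flagged (returns `TRUE`) when any of:
#' \enumerate{
#'   \item the optimizer did not converge;
#'   \item an empirical within-tertile correlation deviates from the
#'     model-implied `tanh(c0 + c1 * zbar_bin)` by more than `corr_tol`
#'     (catches non-linear-in-z correlation, e.g. U-shaped patterns);
#'   \item a Shapiro–Wilk test on the pooled decorrelated standardized
#'     residuals rejects normality at level `alpha` (catches non-normal
#'     pairs and outlier-driven fits).
#' }
#' Under the model the residuals `a = (x1 - mu1)/sigma1` and
#' `(b - rho a)/sqrt(1 - rho^2)` are iid standard normal, so the
#' diagnostic is calibrated: on model-generated data it fires at roughly
#' the nominal `alpha`.
#'
#' @param fit a [fit_cnm()] result.
#' @param x1,x2,x3 the triplet data the model was fitted to.
#' @param corr_tol tolerance on per-tertile correlation deviation
#'   (default 0.35).
#' @param alpha level of the residual normality test (default 0.01).
#' @return logical: `TRUE` if the model fits poorly.
#' @export
lack_of_fit <- function(fit, x1, x2, x3, corr_tol = 0.35, alpha = 0.01) {
  stopifnot(inherits(fit, "cnm_fit"))
  if (!isTRUE(fit$converged)) return(TRUE)
  ok <- !(is.na(x1) | is.na(x2) | is.na(x3))
  x1 <- x1[ok]; x2 <- x2[ok]; z <- x3[ok]
  p <- fit$coefs
  bins <- suppressWarnings(tertile_bins(z))
  for (idx in list(bins$low_idx, bins$mid_idx, bins$high_idx)) {
    if (length(idx) < 3L) next
    emp <- suppressWarnings(stats::cor(x1[idx], x2[idx]))
    mod <- tanh(p["c0"] + p["c1"] * mean(z[idx]))
    if (is.finite(emp) && abs(emp - mod) > corr_tol) return(TRUE)
  }
  mu1 <- p["m10"] + p["m11"] * z
  mu2 <- p["m20"] + p["m21"] * z
  s1 <- exp((p["v10"] + p["v11"] * z) / 2)
  s2 <- exp((p["v20"] + p["v21"] * z) / 2)
  rho <- tanh(p["c0"] + p["c1"] * z)
  a <- (x1 - mu1) / s1
  b <- (x2 - mu2) / s2
  e2 <- (b - rho * a) / sqrt(pmax(1 - rho * rho, 1e-12))
  resid <- c(a, e2)
  if (length(resid) > 5000L) {           # shapiro.test n limit; thin evenly
    resid <- resid[round(seq(1L, length(resid), length.out = 5000L))]
  }
  sw <- tryCatch(stats::shapiro.test(resid), error = function(e) NULL)
  !is.null(sw) && sw$p.value < alpha
}

#' Robust direct MLA estimate with bootstrap standard error
#'
#' Fallback estimator used when neither CNM variant fits a triplet: the
#' binned direct estimate [mla_direct()] with a standard error from
#' resampling samples with replacement.  The p-value is the two-sided
#' normal approximation `2 * pnorm(-|est| / SE)`.  Resamples whose bins
#' are degenerate (zero within-bin variance) are redrawn; the redraw
#' count is attached to the result.
#'
#' @inheritParams mla_direct
#' @param n_boot number of bootstrap replicates (>= 100; default 1000).
#' @param seed integer seed making the resampling reproducible; `NULL`
#'   uses (and advances) the current RNG state.
#' @return list of class `"robust_mla"` with `mla_estimate`, `se_boot`,
#'   `pvalue`, `n_boot`, `seed`, `n_redrawn`.
#' @export
robust_estimate <- function(x1, x2, x3, n_bins = 3L, n_boot = 1000L,
                            seed = NULL) {
  stopifnot(n_boot >= 100L)
  ok <- !(is.na(x1) | is.na(x2) | is.na(x3))
  x1 <- x1[ok]; x2 <- x2[ok]; x3 <- x3[ok]
  n <- length(x3)
  est <- mla_direct(x1, x2, x3, n_bins)
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  reps <- numeric(n_boot)
  redrawn <- 0L
  for (b in seq_len(n_boot)) {
    for (try in 1:100) {
      idx <- sample.int(n, n, replace = TRUE)
      r <- tryCatch(mla_direct(x1[idx], x2[idx], x3[idx], n_bins),
                    error = function(e) NULL)
      if (!is.null(r)) break
      redrawn <- redrawn + 1L
    }
    if (is.null(r)) stop("bootstrap resampling kept producing degenerate bins",
                         call. = FALSE)
    reps[b] <- r
  }
  se <- stats::sd(reps)
  structure(list(mla_estimate = est, se_boot = se,
                 pvalue = 2 * stats::pnorm(-abs(est) / se),
                 n_boot = n_boot, seed = seed, n_redrawn = redrawn),
            class = "robust_mla")
}

#' Estimation cascade for one screened triplet
#'
#' Stage-two decision sequence: fit the full CNM; on lack of fit, fall
#' back to the simple CNM; if that also fits poorly, use the robust
#' direct estimate with bootstrap inference.  The returned `model` code
#' records the path: `"F"` (full), `"S"` (simple), `"R"` (robust).
#'
#' @inheritParams mla_direct
#' @param n_boot bootstrap replicates for the robust fallback.
#' @param seed seed for the robust fallback's bootstrap.
#' @param lof_corr_tol,lof_alpha lack-of-fit tuning, see [lack_of_fit()].
#' @param max_iter optimizer iteration cap.
#' @return list with `mla`, `wald`, `pvalue`, `model`, and the underlying
#'   `fit` object.
#' @export
estimate_triplet <- function(x1, x2, x3, n_bins = 3L, n_boot = 1000L,
                             seed = NULL, lof_corr_tol = 0.35,
                             lof_alpha = 0.01, max_iter = 500L) {
  for (model in c("full", "simple")) {
    fit <- tryCatch(fit_cnm(x1, x2, x3, model = model, max_iter = max_iter),
                    error = function(e) NULL)
    if (!is.null(fit) &&
        !lack_of_fit(fit, x1, x2, x3, corr_tol = lof_corr_tol,
                     alpha = lof_alpha)) {
      return(list(mla = fit$mla_estimate, wald = fit$wald,
                  pvalue = fit$pvalue,
                  model = if (model == "full") "F" else "S", fit = fit))
    }
  }
  rob <- robust_estimate(x1, x2, x3, n_bins = n_bins, n_boot = n_boot,
                         seed = seed)
  list(mla = rob$mla_estimate, wald = (rob$mla_estimate / rob$se_boot)^2,
       pvalue = rob$pvalue, model = "R", fit = rob)
}
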