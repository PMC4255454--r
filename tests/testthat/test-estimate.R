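test_that("direct MLA matches an explicit per-bin oracle", {
  # fixed 12-sample toy triplet
  x1 <- c(0.5, -1.2, 0.3, 2.1, -0.7, 1.1, -0.2, 0.9, -1.5, 0.4, 0.8, -0.3)
  x2 <- c(-0.1, 0.7, 1.3, -0.9, 0.2, -1.8, 0.6, 1.0, -0.4, -1.1, 0.05, 1.6)
  x3 <- c(1.9, -0.6, 0.1, 0.8, -1.4, 0.3, -0.2, 1.1, -0.9, 0.5, -1.7, 1.2)
  expect_equal(mla_direct(x1, x2, x3), oracle_mla(x1, x2, x3))
  expect_equal(mla_direct(x1, x2, x3, n_bins = 4),
               oracle_mla(x1, x2, x3, n_bins = 4))
  # missing samples dropped jointly
  x1[3] <- NA
  expect_equal(mla_direct(x1, x2, x3),
               oracle_mla(x1[-3], x2[-3], x3[-3]))
  set.seed(51)
  for (rep in 1:5) {
    a <- rnorm(45); b <- rnorm(45); z <- rnorm(45)
    expect_equal(mla_direct(a, b, z), oracle_mla(a, b, z))
  }
})

test_that("direct MLA is near zero without liquid association", {
  set.seed(52)
  n <- 10000
  x1 <- rnorm(n)
  expect_lt(abs(mla_direct(x1, rnorm(n), rnorm(n))), 3 / sqrt(n))
  # constant coexpression (x1 == x2) carries no liquid association
  z <- rnorm(n)
  expect_lt(abs(mla_direct(x1, x1, z)), 0.02)
})

test_that("direct MLA is bounded by the binned normal moment", {
  # perfect +/- correlation pattern attains the 3-bin maximum, below
  # the analytic sqrt(2/pi) ceiling
  z <- sort(rnorm(300))
  b <- equal_count_bins(z, 3)
  x1 <- rnorm(300)
  x2 <- x1
  x2[b[[1]]] <- -x1[b[[1]]]
  x2[b[[2]]] <- rnorm(100)
  est <- mla_direct(x1, x2, z)
  expect_gt(est, 0.68)
  expect_lt(est, sqrt(2 / pi))
})

test_that("the vectorized per-controller MLA equals the scalar version", {
  m <- simulate_null(8, 45, seed = 53)
  M <- mla_direct_for_controller(m, "g0005")
  for (pair in list(c(1, 2), c(3, 7), c(4, 8))) {
    g <- rownames(m)[pair]
    expect_equal(M[g[1], g[2]],
                 mla_direct(m[g[1], ], m[g[2], ], m["g0005", ]),
                 tolerance = 1e-12)
  }
})

test_that("CNM recovers full-model parameters within 3 SE at n = 10,000", {
  truth <- c(m10 = 0, m11 = 0.2, m20 = 0, m21 = -0.2,
             v10 = 0, v11 = 0.3, v20 = 0, v21 = 0.1, c0 = 0, c1 = 0.4)
  tr <- simulate_la_triplet(10000, c0 = 0, c1 = 0.4,
                            mean_coefs = truth[c("m10", "m11", "m20", "m21")],
                            logvar_coefs = truth[c("v10", "v11", "v20", "v21")],
                            seed = 54)
  fit <- fit_cnm(tr$x1, tr$x2, tr$x3, model = "full")
  expect_true(fit$converged)
  se <- sqrt(diag(fit$cov))
  expect_true(all(abs(fit$coefs - truth) <= 3 * se))
  expect_equal(fit$wald, (fit$coefs[["c1"]] / fit$se_c1)^2)
  expect_equal(fit$pvalue, wald_pvalue(fit$wald))
})

test_that("simple model nests inside the full model", {
  tr <- simulate_la_triplet(3000, c0 = 0.3, c1 = 0.2, seed = 55)
  f_full <- fit_cnm(tr$x1, tr$x2, tr$x3, "full")
  f_simple <- fit_cnm(tr$x1, tr$x2, tr$x3, "simple")
  expect_true(f_full$converged && f_simple$converged)
  expect_gte(f_full$loglik, f_simple$loglik - 1e-6)
  # no mean/variance dependence in truth: LRT stat is ~ chi^2_4
  lrt <- 2 * (f_full$loglik - f_simple$loglik)
  expect_lt(lrt, qchisq(0.9999, df = 4))
  # structural zeros of the simple model
  expect_identical(unname(f_simple$coefs[c("m11", "m21", "v11", "v21")]),
                   rep(0, 4))
})

test_that("Wald to p-value mapping is the two-sided normal tail", {
  expect_identical(wald_pvalue(0), 1)
  expect_equal(wald_pvalue(qnorm(0.975)^2), 0.05)
  w <- c(0.5, 1, 5, 20, 45)
  expect_true(all(diff(wald_pvalue(w)) < 0))
  expect_error(wald_pvalue(-1), "non-negative")
})

test_that("model-based MLA equals the average correlation derivative", {
  tr <- simulate_la_triplet(10000, c0 = 0, c1 = 0.6, seed = 56)
  fit <- fit_cnm(tr$x1, tr$x2, tr$x3, "simple")
  expect_true(fit$converged)
  # quadrature oracle over the standard-normal controller distribution
  c0 <- fit$coefs[["c0"]]; c1 <- fit$coefs[["c1"]]
  quad <- integrate(function(z) c1 * (1 - tanh(c0 + c1 * z)^2) * dnorm(z),
                    -Inf, Inf)$value
  expect_equal(mla_from_cnm(fit, tr$x3), quad, tolerance = 0.02)
  # exact zero at c1 = 0
  fit0 <- fit
  fit0$coefs["c1"] <- 0
  expect_identical(mla_from_cnm(fit0, tr$x3), 0)
})

test_that("lack of fit is calibrated on model data and detects violations", {
  # data generated from the model: flagged rarely
  flags <- vapply(1:10, function(s) {
    tr <- simulate_la_triplet(1000, c0 = 0.2, c1 = 0.3, seed = 60 + s)
    fit <- fit_cnm(tr$x1, tr$x2, tr$x3, "full")
    lack_of_fit(fit, tr$x1, tr$x2, tr$x3)
  }, logical(1))
  expect_lte(sum(flags), 1)
  # U-shaped correlation in the controller: +0.8 in outer tertiles,
  # -0.8 in the middle -- not representable by tanh(c0 + c1 z)
  set.seed(71)
  n <- 600
  z <- rnorm(n)
  b <- suppressWarnings(tertile_bins(z))
  rho <- rep(0.8, n)
  rho[b$mid_idx] <- -0.8
  u <- rnorm(n); w <- rnorm(n)
  x1 <- u
  x2 <- rho * u + sqrt(1 - rho^2) * w
  fit <- fit_cnm(x1, x2, z, "full")
  expect_true(lack_of_fit(fit, x1, x2, z))
})

test_that("bootstrap inference is reproducible and detects planted signal", {
  tr <- simulate_la_triplet(200, c0 = 0, c1 = 0.5, seed = 81)
  r1 <- robust_estimate(tr$x1, tr$x2, tr$x3, n_boot = 200, seed = 99)
  r2 <- robust_estimate(tr$x1, tr$x2, tr$x3, n_boot = 200, seed = 99)
  expect_identical(r1$se_boot, r2$se_boot)
  expect_gt(r1$se_boot, 0)
  expect_equal(r1$mla_estimate, mla_direct(tr$x1, tr$x2, tr$x3))
  expect_equal(r1$pvalue, 2 * pnorm(-abs(r1$mla_estimate) / r1$se_boot))
  # power: rho(z) = tanh(0.5 z) at n = 300 is detected most of the time
  rej <- vapply(1:25, function(s) {
    tr <- simulate_la_triplet(300, c0 = 0, c1 = 0.5, seed = 500 + s)
    robust_estimate(tr$x1, tr$x2, tr$x3, n_boot = 200,
                    seed = s)$pvalue < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.8)
})

test_that("c1 is estimated without systematic bias across replicates", {
  for (c1 in c(0, 0.2, 0.4)) {
    est <- vapply(1:100, function(s) {
      tr <- simulate_la_triplet(1000, c0 = 0.1, c1 = c1,
                                seed = 10000 + 1000 * round(10 * c1) + s)
      f <- fit_cnm(tr$x1, tr$x2, tr$x3, "simple")
      if (f$converged) f$coefs[["c1"]] else NA_real_
    }, 0)
    est <- est[!is.na(est)]
    expect_gte(length(est), 95)
    mc_se <- sd(est) / sqrt(length(est))
    expect_lt(abs(mean(est) - c1), 2 * mc_se + 1e-3)
  }
})

test_that("the estimation cascade assigns models sensibly", {
  # clean CNM data -> full model accepted
  tr <- simulate_la_triplet(500, c0 = 0.1, c1 = 0.4,
                            mean_coefs = c(0, 0.2, 0, -0.1), seed = 91)
  est <- estimate_triplet(tr$x1, tr$x2, tr$x3, n_boot = 100, seed = 1)
  expect_identical(est$model, "F")
  expect_equal(est$pvalue, wald_pvalue(est$wald))
  # grossly non-normal pair -> pushed off the full model
  set.seed(92)
  z <- rnorm(300)
  x1 <- exp(rnorm(300))^2
  x2 <- exp(rnorm(300))^2
  est2 <- estimate_triplet(x1, x2, z, n_boot = 100, seed = 2)
  expect_true(est2$model %in% c("S", "R"))
})

test_that("direct and screen statistics agree in sign on random data", {
  m <- simulate_null(12, 73, seed = 93)
  genes <- rownames(m)
  agree <- total <- 0
  for (ctrl in genes[1:4]) {
    D <- rho_diff_for_controller(m, ctrl)
    M <- mla_direct_for_controller(m, ctrl)
    ut <- upper.tri(D)
    keep <- ut & row(D) != match(ctrl, genes) & col(D) != match(ctrl, genes)
    agree <- agree + sum(sign(D[keep]) == sign(M[keep]))
    total <- total + sum(keep)
  }
  expect_gte(agree / total, 0.97)
})
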