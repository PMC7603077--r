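test_that("wald ratio arithmetic and symmetry", {
  h <- harmonized_data("rs1", bx = 0.4, sx = 0.01, by = 0.2, sy = 0.05)
  r <- mr_wald(h)
  expect_equal(r$beta, 0.5)
  expect_equal(r$se, 0.125)
  expect_equal(r$pvalue, 2 * pnorm(-4))

  h0 <- harmonized_data("rs1", bx = 0.4, sx = 0.01, by = 0, sy = 0.05)
  expect_equal(mr_wald(h0)$beta, 0)

  hneg <- harmonized_data("rs1", bx = -0.4, sx = 0.01, by = 0.2, sy = 0.05)
  expect_equal(mr_wald(hneg)$beta, -r$beta)
  expect_equal(mr_wald(hneg)$se, r$se)

  hz <- harmonized_data("rs1", bx = 0, sx = 0.01, by = 0.2, sy = 0.05)
  expect_error(mr_wald(hz), class = "phewasmr_domain_error")
})

test_that("cochran Q: perfect fit, closed form, permutation invariance", {
  h <- toy_h(by = c(0.3, 0.2, 0.2) * 0.7)  # all ratios exactly 0.7
  q <- cochran_q(h, 0.7)
  expect_equal(q$q_stat, 0)
  expect_equal(q$q_pvalue, 1)

  # J = 2 with symmetric deviations +/- d*sy around the fit: Q = 2 d^2
  d <- 1.3
  h2 <- harmonized_data(c("a", "b"), bx = c(0.2, 0.2), sx = c(0.01, 0.01),
                        by = 0.5 * c(0.2, 0.2) + c(d * 0.04, -d * 0.05),
                        sy = c(0.04, 0.05))
  expect_equal(cochran_q(h2, 0.5)$q_stat, 2 * d^2)

  h3 <- toy_h()
  perm <- h3[c(3, 1, 2), ]
  expect_equal(cochran_q(perm, 0.1)$q_stat, cochran_q(h3, 0.1)$q_stat)
})

test_that("IVW matches the origin-constrained WLS oracle and Wald identity", {
  h <- toy_h()
  r <- mr_ivw(h)
  o <- ivw_oracle(h)
  expect_equal(r$beta, o$beta, tolerance = 1e-12)
  # RE se is the larger of the fixed-effect and lm (sigma-scaled) se
  expect_equal(r$se, max(o$se_fe, o$se_lm), tolerance = 1e-12)

  # algebraic identity: IVW = weighted mean of Wald ratios, weights (bx/sy)^2
  wr <- h$by / h$bx
  w <- (h$bx / h$sy)^2
  expect_equal(r$beta, sum(w * wr) / sum(w), tolerance = 1e-10)

  # homogeneous ratios: beta = theta0, Q = 0, RE se equals FE se
  hh <- toy_h(by = c(0.3, 0.2, 0.2) * -0.4)
  rh <- mr_ivw(hh)
  expect_equal(rh$beta, -0.4)
  expect_equal(rh$q_stat, 0)
  expect_equal(rh$se, sqrt(1 / sum(hh$bx^2 / hh$sy^2)))
})

test_that("IVW falls back to the Wald ratio for a single SNP", {
  h <- toy_h()[1, ]
  expect_message(r <- mr_ivw(h), "single SNP")
  expect_equal(r$beta, h$by / h$bx)
  expect_equal(r$note, "single-SNP fallback to wald")
})

test_that("weighted median: robustness, degeneracy and oracle agreement", {
  # equal weights, ratios (1, 2, 9): median 2, outlier ignored
  h <- harmonized_data(c("a", "b", "c"), bx = c(0.1, 0.1, 0.1), sx = 0.01,
                       by = c(0.1, 0.2, 0.9), sy = c(0.05, 0.05, 0.05))
  r <- mr_weighted_median(h, n_boot = 50, seed = 1)
  expect_equal(r$beta, 2)

  # all ratios equal: estimate equals the value, bootstrap se small
  heq <- toy_h(by = c(0.3, 0.2, 0.2) * 0.25, sy = c(1e-4, 1e-4, 1e-4))
  heq$sx <- rep(1e-5, 3)
  req <- mr_weighted_median(heq, n_boot = 100, seed = 1)
  expect_equal(req$beta, 0.25, tolerance = 1e-6)
  expect_lt(req$se, 0.01)

  expect_error(mr_weighted_median(toy_h()[1:2, ], seed = 1),
               class = "phewasmr_validation_error")
})

test_that("weighted median within range and bounded by extreme ratios", {
  withr::local_seed(42)
  for (rep in 1:50) {
    h <- random_h(sample(3:8, 1))
    est <- mr_weighted_median(h, n_boot = 2, seed = rep)$beta
    theta <- h$by / h$bx
    expect_gte(est, min(theta))
    expect_lte(est, max(theta))
  }
})

test_that("MR-Egger recovers an exact affine relation and matches lm oracle", {
  withr::local_seed(5)
  # data generated exactly as by = a0 + t0 * bx on reoriented scale
  a0 <- 0.013; t0 <- -0.4
  bx <- c(0.15, 0.25, 0.4, 0.31)
  h <- harmonized_data(paste0("rs", 1:4), bx, sx = 0.01,
                       by = a0 + t0 * bx, sy = c(0.03, 0.05, 0.04, 0.06))
  r <- mr_egger(h)
  expect_equal(r$beta, t0, tolerance = 1e-12)
  expect_equal(r$egger_intercept, a0, tolerance = 1e-12)
  expect_equal(r$q_stat, 0, tolerance = 1e-20)

  h2 <- random_h(6)
  r2 <- mr_egger(h2)
  o <- egger_oracle(h2)
  expect_equal(r2$beta, o$slope, tolerance = 1e-12)
  expect_equal(r2$egger_intercept, o$intercept, tolerance = 1e-12)
  expect_equal(r2$se, max(o$se_fe[2], o$se_lm[2]), tolerance = 1e-10)

  hz <- harmonized_data(c("a", "b", "c"), bx = c(0.2, 0.2, 0.2), sx = 0.01,
                        by = c(0.1, 0.2, 0.3), sy = 0.05)
  expect_error(mr_egger(hz), class = "phewasmr_domain_error")
  expect_error(mr_egger(toy_h()[1:2, ]), class = "phewasmr_validation_error")
})

test_that("estimators are equivariant under outcome negation and bx scaling", {
  withr::local_seed(7)
  for (rep in 1:20) {
    h <- random_h(sample(3:10, 1))
    hneg <- h; hneg$by <- -h$by
    expect_equal(mr_ivw(hneg)$beta, -mr_ivw(h)$beta, tolerance = 1e-10)
    expect_equal(mr_egger(hneg)$beta, -mr_egger(h)$beta, tolerance = 1e-10)
    expect_equal(mr_egger(hneg)$egger_intercept,
                 -mr_egger(h)$egger_intercept, tolerance = 1e-10)
    expect_equal(mr_weighted_median(hneg, n_boot = 2, seed = 1)$beta,
                 -mr_weighted_median(h, n_boot = 2, seed = 1)$beta,
                 tolerance = 1e-10)
    c_scale <- 2.5
    hs <- h; hs$bx <- h$bx * c_scale; hs$sx <- h$sx * c_scale
    expect_equal(mr_ivw(hs)$beta, mr_ivw(h)$beta / c_scale,
                 tolerance = 1e-10)
    expect_equal(mr_egger(hs)$beta, mr_egger(h)$beta / c_scale,
                 tolerance = 1e-10)
  }
})

test_that("I2GX limits and two-pass arithmetic on the iron instruments", {
  # all bx equal -> no heterogeneity attributable to measurement error
  h <- toy_h(bx = c(0.2, 0.2, 0.2))
  expect_warning(i2 <- i2_gx(h), "zero heterogeneity")
  expect_equal(i2, 0)

  # sx -> 0 at fixed spread: I2 -> 1
  h2 <- toy_h(sx = rep(1e-6, 3))
  expect_gt(i2_gx(h2), 0.999)

  # iron instruments: direct two-pass oracle on printed bx, sx
  iron <- iron_set()
  h3 <- harmonized_data(iron$snp, iron$beta, iron$se,
                        by = rep(0, 3), sy = rep(0.1, 3))
  w <- 1 / iron$se^2
  bbar <- sum(w * iron$beta) / sum(w)
  q_gx <- sum((iron$beta - bbar)^2 / iron$se^2)
  expect_equal(i2_gx(h3), (q_gx - 2) / q_gx)
  expect_gt(i2_gx(h3), 0.9)  # NOME effectively satisfied for these SNPs
})

test_that("SIMEX: no measurement error means no correction; lambda=0 is naive", {
  h <- toy_h()
  h$sx <- rep(0, 3)
  r <- mr_simex_egger(h, n_sim = 20, seed = 1)
  expect_equal(r$beta, mr_egger(h)$beta, tolerance = 1e-12)

  h2 <- random_h(5)
  naive <- mr_egger(h2)$beta
  r2 <- mr_simex_egger(h2, n_sim = 300, seed = 2)
  # extrapolation is smooth in lambda; the lambda = 0 grid point is exact
  expect_true(is.finite(r2$beta) && is.finite(r2$se))
})

test_that("SIMEX moves the Egger slope toward the truth under attenuation", {
  # strong exposure-effect measurement error attenuates naive Egger
  withr::local_seed(11)
  t0 <- 0.5
  better <- 0
  n_rep <- 100
  for (r in seq_len(n_rep)) {
    j <- 10
    bx_true <- runif(j, 0.2, 0.8)
    sx <- rep(0.15, j)
    bx_obs <- bx_true + rnorm(j, 0, sx)
    h <- harmonized_data(paste0("rs", 1:j), bx_obs, sx,
                         by = t0 * bx_true + rnorm(j, 0, 0.01),
                         sy = rep(0.01, j))
    naive <- mr_egger(h)$beta
    corr <- mr_simex_egger(h, n_sim = 100, seed = r)$beta
    if (abs(corr - t0) < abs(naive - t0)) better <- better + 1
  }
  expect_gte(better / n_rep, 0.8)
})

test_that("multivariable MR: degeneracy, orthogonality, oracle", {
  h <- toy_h()
  # K = 1 without intercept reduces to the IVW fixed-effect point estimate
  r1 <- mr_mvmr(matrix(h$bx, ncol = 1, dimnames = list(NULL, "x")),
                h$by, h$sy)
  expect_equal(r1$beta, ivw_oracle(h)$beta, tolerance = 1e-12)

  # orthogonal (weighted) columns: slopes equal univariate origin-WLS slopes
  sy <- rep(0.05, 4)
  X <- cbind(a = c(1, 1, 0, 0), b = c(0, 0, 1, 2))
  by <- c(0.2, 0.3, -0.1, -0.25)
  r <- mr_mvmr(X, by, sy)
  ua <- sum(X[, 1] * by / sy^2) / sum(X[, 1]^2 / sy^2)
  ub <- sum(X[, 2] * by / sy^2) / sum(X[, 2]^2 / sy^2)
  expect_equal(r$beta, c(ua, ub), tolerance = 1e-12)

  # generic oracle via stats::lm
  withr::local_seed(3)
  X2 <- cbind(fe = runif(8, 0.1, 0.5), cu = runif(8, 0.1, 0.5))
  by2 <- rnorm(8, 0.2 * X2[, 1] - 0.1 * X2[, 2], 0.03)
  sy2 <- runif(8, 0.02, 0.08)
  r2 <- mr_mvmr(X2, by2, sy2)
  fit <- lm(by2 ~ 0 + X2, weights = 1 / sy2^2)
  expect_equal(r2$beta, unname(coef(fit)), tolerance = 1e-10)
  # intercept mode mirrors the R-formula convention
  r3 <- mr_mvmr(X2, by2, sy2, intercept = TRUE)
  fit3 <- lm(by2 ~ X2, weights = 1 / sy2^2)
  expect_equal(r3$beta, unname(coef(fit3)[-1]), tolerance = 1e-10)

  # collinearity names the exposures
  Xc <- cbind(fe = c(0.1, 0.2, 0.3, 0.4), cu = 2 * c(0.1, 0.2, 0.3, 0.4))
  expect_error(mr_mvmr(Xc, by2[1:4], sy2[1:4]),
               class = "phewasmr_domain_error", regexp = "fe.*cu")
  expect_error(mr_mvmr(X2[1:2, ], by2[1:2], sy2[1:2]),
               class = "phewasmr_validation_error")
})

test_that("leave-one-out: count, homogeneity, and outlier localization", {
  hh <- toy_h(by = c(0.3, 0.2, 0.2) * 0.6)
  loo <- mr_leave_one_out(hh)
  expect_equal(nrow(loo), 3)
  expect_equal(loo$beta, rep(0.6, 3))
  expect_equal(loo$snp_omitted, hh$snp)

  # one outlier SNP: omitting it moves the estimate the most
  ho <- toy_h(by = c(0.3 * 0.5, 0.2 * 0.5, 0.2 * 3))
  full <- mr_ivw(ho)$beta
  loo2 <- mr_leave_one_out(ho)
  deltas <- abs(loo2$beta - full)
  expect_equal(which.max(deltas), 3L)
})

test_that("per-SD scaling transforms estimates and preserves CI order", {
  h <- toy_h()
  r <- mr_ivw(h)
  expect_equal(scale_per_sd(r, 1), r)
  r2 <- scale_per_sd(r, 2)
  expect_equal(r2$beta, 2 * r$beta)
  expect_equal(r2$or, r$or^2)
  expect_lt(r2$ci_low, r2$ci_high)
  # OR 0.9 doubled on log scale -> 0.81
  rr <- r; rr$beta <- log(0.9)
  expect_equal(scale_per_sd(rr, 2)$or, 0.81)
  expect_error(scale_per_sd(r, -1), class = "phewasmr_domain_error")
})

test_that("pleiotropy lookup flags only genome-wide-significant hits", {
  cat <- tibble::tibble(
    snp = c("rs1800562", "rs1800562", "rs855791"),
    trait = c("LDL cholesterol", "height", "hemoglobin"),
    pvalue = c(1e-30, 6e-8, 1e-10))
  hits <- pleiotropy_lookup(c("rs1800562", "rs855791"), cat)
  expect_equal(sort(hits$trait), c("LDL cholesterol", "hemoglobin"))
  # threshold is strict: p = 6e-8 is not flagged
  expect_false("height" %in% hits$trait)
  expect_equal(nrow(pleiotropy_lookup("rs1", cat[0, ])), 0)
  expect_warning(h <- pleiotropy_lookup("rs1", NULL), "skipped")
  expect_equal(nrow(h), 0)
  # the packaged synthetic catalog flags the HFE variant for LDL
  hits2 <- pleiotropy_lookup(
    iron_set()$snp, phewasmr_example("pleiotropy_catalog_synthetic.tsv"))
  expect_true("rs1800562" %in% hits2$snp)
})
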