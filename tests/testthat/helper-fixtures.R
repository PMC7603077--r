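# shared fixtures and independent oracles

iron_set <- function() {
  read_instruments(phewasmr_example("iron_benyamin.tsv"), "iron")
}

copper_set <- function() {
  read_instruments(phewasmr_example("copper_evans.tsv"), "copper")
}

# outcome-stats dialect table aligned with an instrument set
aligned_outcome <- function(set, beta, se = 0.05, eaf = NULL) {
  tibble::tibble(
    snp = set$snp,
    effect_allele = set$effect_allele,
    baseline_allele = set$baseline_allele,
    eaf = eaf %||% set$eaf,
    beta = beta,
    se = se
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

toy_h <- function(bx = c(0.3, 0.2, 0.2), sx = c(0.02, 0.02, 0.02),
                  by = c(0.03, 0.02, 0.01), sy = c(0.05, 0.04, 0.04)) {
  harmonized_data(paste0("rs", seq_along(bx)), bx, sx, by, sy)
}

# ---- independent oracles -------------------------------------------------

# origin-constrained weighted least squares via stats::lm
ivw_oracle <- function(h) {
  fit <- stats::lm(by ~ 0 + bx, data = h, weights = 1 / h$sy^2)
  s <- summary(fit)
  list(beta = unname(coef(fit)[1]),
       se_fe = unname(s$coefficients[1, 2] / s$sigma),
       se_lm = unname(s$coefficients[1, 2]))
}

# Egger oracle: reorient, then weighted lm with intercept
egger_oracle <- function(h) {
  flip <- ifelse(h$bx < 0, -1, 1)
  d <- data.frame(bx = h$bx * flip, by = h$by * flip)
  fit <- stats::lm(by ~ bx, data = d, weights = 1 / h$sy^2)
  s <- summary(fit)
  list(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]),
       se_fe = unname(s$coefficients[, 2] / s$sigma),
       se_lm = unname(s$coefficients[, 2]))
}

# weighted-median oracle: breakpoint interpolation through stats::approx
wm_oracle <- function(h) {
  theta <- h$by / h$bx
  w <- (h$bx / h$sy)^2
  w <- w / sum(w)
  o <- order(theta)
  stats::approx(cumsum(w[o]) - w[o] / 2, theta[o], xout = 0.5, rule = 2,
                ties = "ordered")$y
}

# random harmonized data for property tests
random_h <- function(j) {
  harmonized_data(
    paste0("rs", seq_len(j)),
    bx = stats::runif(j, 0.05, 0.5) * sample(c(-1, 1), j, replace = TRUE),
    sx = stats::runif(j, 0.005, 0.05),
    by = stats::rnorm(j, 0, 0.1),
    sy = stats::runif(j, 0.01, 0.1)
  )
}

# single-phenotype simulation config used by the calibration/recovery tests
one_phenotype_cfg <- function(set, phecode, prevalence, theta, n, seed,
                              name = "pheno") {
  phen <- tibble::tibble(name = name, type = "binary", phecode = phecode,
                         prevalence = prevalence, mean = NA_real_,
                         sd = NA_real_)
  eff <- if (theta != 0) {
    tibble::tibble(exposure = exposure_name(set), outcome = name,
                   effect = theta)
  } else NULL
  sim_config(set, n = n, phenotypes = phen, causal_effects = eff, seed = seed)
}

# one replicate of the two-sample pipeline for a single binary phenotype:
# simulate, scan per-SNP, return the IVW and Egger rows
simulate_and_ivw <- function(set, phecode, prevalence, theta, n, seed,
                             egger = FALSE) {
  cfg <- one_phenotype_cfg(set, phecode, prevalence, theta, n, seed)
  co <- simulate_cohort(cfg)
  h <- snp_outcome_assoc(co, set, phecode = phecode,
                         covariates = c("age", "sex"))
  out <- list(ivw = mr_ivw(h))
  if (egger) out$egger <- mr_egger(h)
  out
}
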