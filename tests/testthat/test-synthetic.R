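test_that("fixed seed gives identical cohorts; config is validated", {
  iron <- iron_set()
  cfg <- sim_config(iron, n = 1500, seed = 11)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$dosages, b$dosages)
  expect_identical(a$participants, b$participants)
  expect_identical(a$diagnoses, b$diagnoses)
  expect_identical(a$biomarkers, b$biomarkers)

  # infeasible variance configurations are rejected
  bad <- iron_set(); bad$r2 <- c(0.5, 0.4, 0.2)
  expect_error(sim_config(instrument_set(bad, "iron"), n = 100),
               class = "phewasmr_validation_error", regexp = "r2")
  heavy <- iron_set(); heavy$beta <- c(3, 3, 3)
  expect_error(sim_config(instrument_set(heavy, "iron"), n = 100),
               class = "phewasmr_validation_error")
  phen <- default_phenotypes(); phen$prevalence[1] <- 1.5
  expect_error(sim_config(iron, n = 100, phenotypes = phen),
               class = "phewasmr_validation_error")
})

test_that("genotypes respect the configured allele frequencies", {
  iron <- iron_set()
  cfg <- sim_config(iron, n = 100000, seed = 12,
                    phenotypes = default_phenotypes()[1, ])
  co <- simulate_cohort(cfg)
  # binomial sampling bound (6 sigma) at n = 100k
  for (j in seq_len(nrow(iron))) {
    eaf_hat <- mean(co$dosages[, iron$snp[j]]) / 2
    expect_lt(abs(eaf_hat - iron$eaf[j]), 0.01)
  }
  # dosages satisfy HWE by construction
  hwe <- hwe_test(co$dosages)
  expect_true(all(hwe$pvalue > 1e-4))
})

test_that("exposure variance decomposes into configured per-SNP r2", {
  iron <- iron_set()
  cfg <- sim_config(iron, n = 200000, seed = 13,
                    phenotypes = default_phenotypes()[1, ])
  co <- simulate_cohort(cfg)
  x <- co$true_exposures$iron
  expect_equal(var(x), 1, tolerance = 0.02)
  for (j in seq_len(nrow(iron))) {
    g <- co$dosages[, iron$snp[j]]
    r2_hat <- cor(x, g)^2
    expect_lt(abs(r2_hat - iron$r2[j]) / iron$r2[j], 0.15)
  }
})

test_that("binary prevalences hit their targets and emit mapped ICD codes", {
  iron <- iron_set()
  cfg <- sim_config(iron, n = 50000, seed = 14)
  co <- simulate_cohort(cfg)
  phen <- cfg$phenotypes[cfg$phenotypes$type == "binary", ]
  # each phenotype's own emission rate (direct diagnoses, before parent
  # propagation), within its eligible-sex denominator
  lookup <- phewasmr:::map_icd_lookup(co$map)
  dx <- tibble::tibble(
    participant_id = co$diagnoses$participant_id,
    icd = phewasmr:::normalize_icd(co$diagnoses$icd10))
  for (i in seq_len(nrow(phen))) {
    codes <- lookup$icd[lookup$phecode == phen$phecode[i]]
    n_case <- length(unique(dx$participant_id[dx$icd %in% codes]))
    sex_req <- co$map$sex[co$map$phecode == phen$phecode[i]]
    denom <- if (sex_req == "both") nrow(co$participants) else
      sum(co$participants$sex == sex_req)
    p_hat <- n_case / denom
    expect_lt(abs(p_hat - phen$prevalence[i]),
              6 * sqrt(phen$prevalence[i] / denom) + 0.002)
  }
  # every emitted ICD code is present in the map
  lookup <- phewasmr:::map_icd_lookup(co$map)
  expect_true(all(phewasmr:::normalize_icd(co$diagnoses$icd10) %in%
                    lookup$icd))
})

test_that("null configuration produces null per-SNP associations", {
  iron <- iron_set()
  cfg <- one_phenotype_cfg(iron, "280", 0.05, theta = 0, n = 20000,
                           seed = 15)
  co <- simulate_cohort(cfg)
  h <- snp_outcome_assoc(co, iron, phecode = "280",
                         covariates = c("age", "sex"))
  expect_true(all(abs(h$by / h$sy) < 4))
})

test_that("a configured causal effect propagates to the IVW estimate", {
  iron <- iron_set()
  theta <- log(0.75)
  r <- simulate_and_ivw(iron, "280", 0.05, theta, n = 60000, seed = 16)$ivw
  expect_lt(abs(r$beta - theta), 3 * r$se)
})

test_that("sex effect modifiers separate the strata", {
  copper <- copper_set()
  phen <- tibble::tibble(name = "t2d", type = "binary", phecode = "250.2",
                         prevalence = 0.10, mean = NA_real_, sd = NA_real_)
  cfg <- sim_config(
    copper, n = 40000, phenotypes = phen,
    causal_effects = tibble::tibble(exposure = "copper", outcome = "t2d",
                                    effect = log(1.6)),
    sex_modifiers = tibble::tibble(exposure = "copper", outcome = "t2d",
                                   female = 1, male = 0),
    seed = 17)
  co <- simulate_cohort(cfg)
  hf <- snp_outcome_assoc(co, copper, phecode = "250.2",
                          covariates = c("age"), stratum = "female")
  hm <- snp_outcome_assoc(co, copper, phecode = "250.2",
                          covariates = c("age"), stratum = "male")
  rf <- suppressMessages(mr_ivw(hf))
  rm_ <- suppressMessages(mr_ivw(hm))
  # female stratum carries the effect, male stratum is null
  expect_lt(abs(rf$beta - log(1.6)), 3 * rf$se)
  expect_lt(abs(rm_$beta), 3 * rm_$se)
  expect_gt(rf$beta, rm_$beta)
})

test_that("simulated summary stats are deterministic and recover the truth", {
  iron <- iron_set()
  phen <- tibble::tibble(name = "LDL", type = "continuous",
                         phecode = NA_character_, prevalence = NA_real_,
                         mean = 3.56, sd = 0.87)
  cfg <- sim_config(
    iron, n = 100000, phenotypes = phen,
    causal_effects = tibble::tibble(exposure = "iron", outcome = "LDL",
                                    effect = -0.089),
    seed = 18)
  s1 <- simulate_summary_stats(cfg, "LDL")
  s2 <- simulate_summary_stats(cfg, "LDL")
  expect_identical(s1, s2)
  expect_named(s1, c("snp", "effect_allele", "baseline_allele", "eaf",
                     "beta", "se", "pvalue", "n"))
  h <- harmonize(iron, s1)
  r <- mr_ivw(h)
  expect_lt(abs(r$beta - (-0.089)), 2 * r$se)
  expect_error(simulate_summary_stats(cfg, "nope"),
               class = "phewasmr_config_error")
})
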