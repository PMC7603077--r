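#' Miniature synthetic phecode map
#'
#' A small (~19 phecode) map in the phewascatalog CSV dialect, covering the
#' lipid-metabolism hierarchy (272 > 272.1 hyperlipidemia > 272.11
#' hypercholesterolemia), the anemia range, varicose veins, diabetes,
#' osteoarthrosis, and one sex-specific phenotype, with exclusion ranges
#' wide enough to exercise control-exclusion logic. Every ICD-10 code maps
#' to exactly one phecode; parent phecodes are reached by propagation.
#'
#' @return A `phecode_map` tibble.
#' @export
synthetic_phecode_map <- function() {
  x <- tibble::tribble(
    ~phecode, ~description, ~icd10_codes, ~exclude_range_lo, ~exclude_range_hi, ~parent_phecode, ~sex,
    "200",    "Myeloproliferative disease",          "D47.1",       200, 208, NA,      "both",
    "218",    "Uterine leiomyoma",                   "D25",         218, 219, NA,      "female",
    "244",    "Hypothyroidism",                      "E03",         240, 246, NA,      "both",
    "250",    "Diabetes mellitus",                   "E14",         249, 251, NA,      "both",
    "250.2",  "Type 2 diabetes",                     "E11",         249, 251, "250",   "both",
    "272",    "Disorders of lipid metabolism",       "E78.9",       270, 279, NA,      "both",
    "272.1",  "Hyperlipidemia",                      "E78.5",       270, 279, "272",   "both",
    "272.11", "Hypercholesterolemia",                "E78.0",       270, 279, "272.1", "both",
    "272.3",  "Hyperglyceridemia",                   "E78.1",       270, 279, "272",   "both",
    "280",    "Iron deficiency anemia",              "D50",         280, 285, NA,      "both",
    "285",    "Other anemia",                        "D64",         280, 285, NA,      "both",
    "296",    "Mood disorders",                      "F32;F33",     295, 302, NA,      "both",
    "401",    "Hypertension",                        "I10",         401, 405, NA,      "both",
    "454",    "Varicose veins",                      "I83.9",       454, 459, NA,      "both",
    "454.1",  "Varicose veins of lower extremity",   "I83.0",       454, 459, "454",   "both",
    "530",    "Diseases of esophagus",               "K21",         530, 539, NA,      "both",
    "571",    "Chronic liver disease and cirrhosis", "K74",         571, 573, NA,      "both",
    "735",    "Acquired foot deformities",           "M20",         735, 736, NA,      "both",
    "740",    "Osteoarthrosis",                      "M15;M19",     740, 741, NA,      "both"
  )
  as_phecode_map(x)
}

#' Write the synthetic phecode map to a CSV fixture
#'
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
make_phecode_fixture <- function(path = tempfile(fileext = ".csv")) {
  readr::write_csv(synthetic_phecode_map(), path)
  invisible(path)
}

#' Default synthetic phenotype panel
#'
#' Binary phenotypes tied to leaf phecodes of [synthetic_phecode_map()] with
#' prevalences typical of a middle-aged European-ancestry biobank, plus the
#' four lipid biomarkers (mmol/L) with population means and residual SDs.
#'
#' @return Tibble `name`, `type`, `phecode`, `prevalence`, `mean`, `sd`.
#' @export
default_phenotypes <- function() {
  tibble::tribble(
    ~name,                    ~type,        ~phecode, ~prevalence, ~mean, ~sd,
    "iron_deficiency_anemia", "binary",     "280",    0.02,        NA,    NA,
    "other_anemia",           "binary",     "285",    0.03,        NA,    NA,
    "hyperlipidemia",         "binary",     "272.1",  0.10,        NA,    NA,
    "hypercholesterolemia",   "binary",     "272.11", 0.12,        NA,    NA,
    "varicose_veins",         "binary",     "454.1",  0.025,       NA,    NA,
    "type_2_diabetes",        "binary",     "250.2",  0.05,        NA,    NA,
    "osteoarthrosis",         "binary",     "740",    0.08,        NA,    NA,
    "uterine_leiomyoma",      "binary",     "218",    0.04,        NA,    NA,
    "TC",                     "continuous", NA,       NA,          5.69,  1.14,
    "LDL",                    "continuous", NA,       NA,          3.56,  0.87,
    "HDL",                    "continuous", NA,       NA,          1.45,  0.38,
    "TG",                     "continuous", NA,       NA,          1.75,  1.00
  )
}

#' Configure a synthetic cohort simulation
#'
#' Defines the generative world for [simulate_cohort()]: instrument SNPs in
#' Hardy-Weinberg equilibrium, exposures built from the instruments plus
#' Gaussian noise so each SNP explains its configured variance fraction,
#' logistic binary phenotypes and Gaussian biomarkers with configurable
#' causal effects per SD of exposure, optional per-SNP direct (pleiotropic)
#' effects, optional sex-specific effect multipliers, and age/sex covariate
#' effects. Demographics mirror a middle-aged biobank: age ~ Normal(56.86,
#' 8) truncated to 40-69, 53.5% female.
#'
#' @param instruments An [instrument_set()] or list of them (one per
#'   exposure).
#' @param n Number of individuals.
#' @param phenotypes As [default_phenotypes()].
#' @param causal_effects Tibble `exposure`, `outcome`, `effect`: log-odds
#'   (binary) or slope in outcome units (continuous) per SD of the exposure.
#'   Unlisted pairs have effect 0.
#' @param pleiotropy Tibble `snp`, `outcome`, `effect`: direct per-allele
#'   effects bypassing the exposure (horizontal pleiotropy). Default none.
#' @param sex_modifiers Tibble `exposure`, `outcome`, `female`, `male`:
#'   multipliers on the causal effect per sex. Default 1/1.
#' @param covariate_effects Tibble `outcome`, `age`, `sex`: log-odds (or
#'   units) per year of age (centred) and for female sex. Default none.
#' @param map Phecode map used to emit one ICD code per binary case.
#' @param statin_prevalence Probability of the statin-use flag.
#' @param seed Integer RNG seed; fixed seed gives bit-reproducible cohorts
#'   (Mersenne-Twister / inversion / rejection sampling, version-pinned via
#'   [set.seed()] defaults of R >= 3.6).
#' @return A `sim_config` list.
#' @export
sim_config <- function(instruments, n = 10000,
                       phenotypes = default_phenotypes(),
                       causal_effects = NULL,
                       pleiotropy = NULL,
                       sex_modifiers = NULL,
                       covariate_effects = NULL,
                       map = synthetic_phecode_map(),
                       statin_prevalence = 0.17,
                       seed = 1) {
  if (inherits(instruments, "instrument_set")) instruments <- list(instruments)
  stopifnot(length(instruments) >= 1,
            all(vapply(instruments, inherits, logical(1), "instrument_set")))
  names(instruments) <- vapply(instruments, exposure_name, character(1))
  if (n < 1) abort("n must be >= 1", class = "phewasmr_validation_error")
  prev <- phenotypes$prevalence[phenotypes$type == "binary"]
  if (any(!is.finite(prev)) || any(prev <= 0) || any(prev >= 1)) {
    abort("binary phenotype prevalences must lie in (0, 1)",
          class = "phewasmr_validation_error")
  }
  for (set in instruments) {
    if (sum(set$r2) >= 1) {
      abort(sprintf("infeasible r2 configuration for %s: sum(r2) >= 1",
                    exposure_name(set)),
            class = "phewasmr_validation_error")
    }
    gvar <- sum(set$beta^2 * 2 * set$eaf * (1 - set$eaf))
    if (gvar >= exposure_sd(set)^2) {
      abort(sprintf(
        "infeasible configuration for %s: genetic variance %.3f >= exposure_sd^2",
        exposure_name(set), gvar),
        class = "phewasmr_validation_error")
    }
  }
  structure(list(
    instruments = instruments, n = as.integer(n), phenotypes = phenotypes,
    causal_effects = causal_effects %||%
      tibble(exposure = character(), outcome = character(),
             effect = numeric()),
    pleiotropy = pleiotropy %||%
      tibble(snp = character(), outcome = character(), effect = numeric()),
    sex_modifiers = sex_modifiers %||%
      tibble(exposure = character(), outcome = character(),
             female = numeric(), male = numeric()),
    covariate_effects = covariate_effects %||%
      tibble(outcome = character(), age = numeric(), sex = numeric()),
    map = as_phecode_map(map),
    statin_prevalence = statin_prevalence,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# intercept for a logistic phenotype hitting the target mean over eta,
# solved by bisection (uniroot) on the sample-average probability
solve_logistic_intercept <- function(eta, prevalence, tol = 1e-6) {
  f <- function(c) mean(plogis(c + eta)) - prevalence
  uniroot(f, interval = c(-40, 40), tol = tol)$root
}

causal_effect_of <- function(cfg, exposure, outcome) {
  hit <- cfg$causal_effects[cfg$causal_effects$exposure == exposure &
                              cfg$causal_effects$outcome == outcome, ]
  if (nrow(hit) == 0) 0 else hit$effect[1]
}

sex_multiplier <- function(cfg, exposure, outcome, female01) {
  hit <- cfg$sex_modifiers[cfg$sex_modifiers$exposure == exposure &
                             cfg$sex_modifiers$outcome == outcome, ]
  if (nrow(hit) == 0) return(rep(1, length(female01)))
  ifelse(female01 == 1, hit$female[1], hit$male[1])
}

#' Simulate an individual-level cohort
#'
#' Draws genotypes per SNP as Binomial(2, EAF) (Hardy-Weinberg, no LD),
#' builds each exposure as the dosage-weighted sum of its instrument betas
#' plus Gaussian noise scaled so the total exposure variance equals
#' `exposure_sd^2`, then generates phenotypes: binary outcomes from a
#' logistic model whose intercept is solved numerically to hit the target
#' prevalence, continuous biomarkers from a Gaussian model. Each binary case
#' is emitted as one ICD-10 diagnosis sampled uniformly from the phecode's
#' mapped codes.
#'
#' @param cfg A [sim_config()].
#' @return A `cohort` object: list with `participants` (covariates),
#'   `dosages` (individuals x SNPs effect-allele count matrix), `diagnoses`
#'   (long `participant_id`, `icd10`), `biomarkers` (with `statin` flag),
#'   `true_exposures` (hidden truth, for testing), `map`, and `config`.
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n
  ids <- sprintf("id%07d", seq_len(n))
  female <- rbinom(n, 1, 0.535)
  # truncated normal age via inverse-CDF so a fixed seed is reproducible
  plo <- pnorm(40, 56.86, 8); phi <- pnorm(69, 56.86, 8)
  age <- qnorm(runif(n, plo, phi), 56.86, 8)
  pcs <- matrix(rnorm(n * 10), n, 10,
                dimnames = list(NULL, paste0("PC", 1:10)))
  participants <- dplyr::bind_cols(
    tibble(participant_id = ids, age = age,
           sex = ifelse(female == 1, "female", "male"),
           array = "axiom", centre = "centre_1"),
    as_tibble(pcs)
  )

  all_snps <- dplyr::bind_rows(lapply(cfg$instruments, as_tibble))
  dosages <- vapply(seq_len(nrow(all_snps)),
                    function(j) rbinom(n, 2, all_snps$eaf[j]),
                    numeric(n))
  colnames(dosages) <- all_snps$snp

  exposures <- lapply(cfg$instruments, function(set) {
    g <- dosages[, set$snp, drop = FALSE]
    genetic <- drop(g %*% set$beta)
    gvar <- sum(set$beta^2 * 2 * set$eaf * (1 - set$eaf))
    noise_sd <- sqrt(exposure_sd(set)^2 - gvar)
    x <- genetic + rnorm(n, 0, noise_sd)
    x / exposure_sd(set)  # per-SD units for the structural models
  })

  diagnoses <- list()
  biomarkers <- tibble(participant_id = ids,
                       statin = rbinom(n, 1, cfg$statin_prevalence))
  for (i in seq_len(nrow(cfg$phenotypes))) {
    ph <- cfg$phenotypes[i, ]
    eta <- rep(0, n)
    for (ex in names(cfg$instruments)) {
      theta <- causal_effect_of(cfg, ex, ph$name)
      if (theta != 0) {
        eta <- eta + theta * sex_multiplier(cfg, ex, ph$name, female) *
          exposures[[ex]]
      }
    }
    plei <- cfg$pleiotropy[cfg$pleiotropy$outcome == ph$name, ]
    for (k in seq_len(nrow(plei))) {
      eta <- eta + plei$effect[k] * dosages[, plei$snp[k]]
    }
    cov_eff <- cfg$covariate_effects[cfg$covariate_effects$outcome == ph$name, ]
    if (nrow(cov_eff) > 0) {
      eta <- eta + cov_eff$age[1] * (age - 56.86) + cov_eff$sex[1] * female
    }
    if (ph$type == "binary") {
      map_row <- cfg$map[cfg$map$phecode == ph$phecode, ]
      if (nrow(map_row) == 0) {
        abort(sprintf("phenotype %s references phecode %s absent from map",
                      ph$name, ph$phecode),
              class = "phewasmr_config_error")
      }
      eligible <- if (map_row$sex[1] %in% c("male", "female")) {
        female == (map_row$sex[1] == "female")
      } else rep(TRUE, n)
      intercept <- solve_logistic_intercept(eta[eligible], ph$prevalence)
      y <- integer(n)
      y[eligible] <- rbinom(sum(eligible), 1,
                            plogis(intercept + eta[eligible]))
      codes <- strsplit(map_row$icd10_codes[1], ";")[[1]]
      case_idx <- which(y == 1)
      if (length(case_idx) > 0) {
        diagnoses[[ph$name]] <- tibble(
          participant_id = ids[case_idx],
          icd10 = sample(codes, length(case_idx), replace = TRUE))
      }
    } else {
      biomarkers[[ph$name]] <- ph$mean + eta + rnorm(n, 0, ph$sd)
    }
  }

  true_exposures <- dplyr::bind_cols(
    tibble(participant_id = ids),
    as_tibble(setNames(exposures, names(cfg$instruments))))

  structure(list(
    participants = participants,
    dosages = dosages,
    diagnoses = if (length(diagnoses) > 0) dplyr::bind_rows(diagnoses) else
      tibble(participant_id = character(), icd10 = character()),
    biomarkers = biomarkers,
    true_exposures = true_exposures,
    map = cfg$map,
    config = cfg
  ), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d participants, %d SNPs, %d diagnosis records\n",
              nrow(x$participants), ncol(x$dosages), nrow(x$diagnoses)))
  invisible(x)
}

#' Numeric covariate matrix for association scans
#'
#' @param cohort A `cohort`.
#' @param include Covariates to include: any of `"age"`, `"sex"`, `"pc"`.
#' @return Numeric matrix (sex coded female = 1).
#' @export
cohort_covariates <- function(cohort, include = c("age", "sex", "pc")) {
  p <- cohort$participants
  out <- list()
  if ("age" %in% include) out$age <- p$age
  if ("sex" %in% include) out$sex <- as.numeric(p$sex == "female")
  if ("pc" %in% include) {
    for (k in 1:10) out[[paste0("PC", k)]] <- p[[paste0("PC", k)]]
  }
  do.call(cbind, out)
}

#' Case status of a phenotype in a simulated or mapped cohort
#'
#' @param cohort A `cohort`.
#' @param phecode Phecode id.
#' @return A [build_case_control()] partition using the cohort's map.
#' @export
cohort_case_control <- function(cohort, phecode) {
  sets <- map_to_phecodes(cohort$diagnoses, cohort$map)
  build_case_control(phecode, sets, cohort$map, cohort$participants)
}

#' Simulate external outcome summary statistics
#'
#' Simulates an independent cohort from the same generative configuration
#' (with a seed deterministically offset from `cfg$seed`) and fits per-SNP
#' age/sex-adjusted regressions for one outcome, returning the table in the
#' outcome summary-statistics dialect used by [harmonize()] — a stand-in for
#' consortium replication data.
#'
#' @param cfg A [sim_config()].
#' @param outcome Phenotype name from `cfg$phenotypes`.
#' @param n Cohort size (default `cfg$n`).
#' @return Tibble `snp`, `effect_allele`, `baseline_allele`, `eaf`, `beta`,
#'   `se`, `pvalue`, `n`.
#' @export
simulate_summary_stats <- function(cfg, outcome, n = cfg$n) {
  stopifnot(inherits(cfg, "sim_config"))
  ph <- cfg$phenotypes[cfg$phenotypes$name == outcome, ]
  if (nrow(ph) == 0) {
    abort(sprintf("outcome %s not configured", outcome),
          class = "phewasmr_config_error")
  }
  cfg2 <- cfg
  cfg2$n <- as.integer(n)
  cfg2$seed <- (cfg$seed + 1000003L) %% .Machine$integer.max
  cohort <- simulate_cohort(cfg2)
  covs <- cohort_covariates(cohort, include = c("age", "sex"))
  all_snps <- dplyr::bind_rows(lapply(cfg$instruments, as_tibble))
  if (ph$type == "binary") {
    cc <- cohort_case_control(cohort, ph$phecode)
    idx <- cohort$participants$participant_id %in%
      c(cc$case_ids, cc$control_ids)
    status <- cohort$participants$participant_id %in% cc$case_ids
    status <- as.integer(status[idx])
  }
  rows <- purrr::map(seq_len(nrow(all_snps)), function(j) {
    snp <- all_snps$snp[j]
    g <- cohort$dosages[, snp]
    res <- if (ph$type == "binary") {
      logistic_assoc(status, g[idx], covs[idx, , drop = FALSE],
                     outcome = outcome, predictor_name = snp)
    } else {
      linear_assoc(cohort$biomarkers[[outcome]], g, covs,
                   outcome = outcome, predictor_name = snp)
    }
    tibble(snp = snp,
           effect_allele = all_snps$effect_allele[j],
           baseline_allele = all_snps$baseline_allele[j],
           eaf = mean(g) / 2,
           beta = res$beta, se = res$se, pvalue = res$pvalue,
           n = res$n)
  })
  dplyr::bind_rows(rows)
}
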