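#' Phenome-wide association screen for one exposure
#'
#' Scans every phecode in the map: builds the case/control/excluded partition,
#' optionally drops phenotypes with insufficient MR power, and fits
#' covariate-adjusted logistic regressions of case status on the weighted
#' genetic risk score (the screening statistic) and, optionally, on each
#' instrument SNP (feeding the downstream MR). GRS p-values are
#' Benjamini-Hochberg adjusted across phecodes.
#'
#' @param cohort A `cohort` object (or any list with `participants`,
#'   `dosages`, `diagnoses`, `map` of the same shape).
#' @param set An [instrument_set()].
#' @param map Phecode map (defaults to the cohort's).
#' @param predictors `"grs"`, `"per_snp"`, or both.
#' @param covariates Covariate blocks for [cohort_covariates()].
#' @param or_detect,power_alpha,power_threshold Power-filter settings
#'   ([mr_power()]); `apply_power_filter = FALSE` disables the filter.
#' @param stratum `"all"`, `"male"` or `"female"`; stratified scans restrict
#'   the cohort to one sex and drop the sex covariate.
#' @return Tibble of class `phewas_screen`: `phecode`, `description`,
#'   `n_case`, `n_control`, `predictor`, `beta`, `se`, `pvalue`, `q` (GRS
#'   rows only), `power`, `stratum`, `converged`.
#' @export
phewas_screen <- function(cohort, set, map = cohort$map,
                          predictors = c("grs", "per_snp"),
                          covariates = c("age", "sex", "pc"),
                          or_detect = 1.2, power_alpha = 0.05,
                          power_threshold = 0.8,
                          apply_power_filter = TRUE,
                          stratum = "all") {
  map <- as_phecode_map(map)
  predictors <- match.arg(predictors, several.ok = TRUE)
  participants <- cohort$participants
  keep <- rep(TRUE, nrow(participants))
  if (stratum %in% c("male", "female")) {
    keep <- participants$sex == stratum
    covariates <- setdiff(covariates, "sex")
  }
  participants <- participants[keep, ]
  dosages <- cohort$dosages[keep, , drop = FALSE]
  covs <- cohort_covariates(list(participants = participants), covariates)
  grs <- compute_grs(dosages, set)
  phe_sets <- map_to_phecodes(cohort$diagnoses, map)
  r2_total <- total_variance_explained(set)

  rows <- purrr::map(map$phecode, function(ph) {
    cc <- build_case_control(ph, phe_sets, map, participants)
    # sex-specific phecodes restrict to one sex: the sex covariate is
    # structurally constant there and silently omitted
    cv_all <- covs
    if (map$sex[map$phecode == ph] %in% c("male", "female") &&
        "sex" %in% colnames(cv_all)) {
      cv_all <- cv_all[, colnames(cv_all) != "sex", drop = FALSE]
    }
    base <- tibble(phecode = ph, description = cc$description,
                   n_case = cc$n_case, n_control = cc$n_control)
    if (cc$n_case < 1 || cc$n_control < 1) {
      return(dplyr::mutate(base, predictor = NA_character_,
                           beta = NA_real_, se = NA_real_,
                           pvalue = NA_real_, power = NA_real_,
                           stratum = stratum, converged = FALSE))
    }
    pw <- mr_power(cc$n_case, cc$n_control, r2_total,
                   or_detect = or_detect, alpha = power_alpha)
    if (apply_power_filter && pw <= power_threshold) {
      return(NULL)  # filtered out before testing
    }
    idx <- participants$participant_id %in% c(cc$case_ids, cc$control_ids)
    status <- as.integer(
      participants$participant_id[idx] %in% cc$case_ids)
    cv <- cv_all[idx, , drop = FALSE]
    fits <- list()
    if ("grs" %in% predictors) {
      fits$grs <- logistic_assoc(status, grs[idx], cv, outcome = ph,
                                 predictor_name = "GRS", stratum = stratum)
    }
    if ("per_snp" %in% predictors) {
      for (snp in set$snp) {
        fits[[snp]] <- logistic_assoc(status, dosages[idx, snp], cv,
                                      outcome = ph, predictor_name = snp,
                                      stratum = stratum)
      }
    }
    fits <- dplyr::bind_rows(fits)
    dplyr::bind_cols(
      base[rep(1, nrow(fits)), ],
      dplyr::select(fits, "predictor", "beta", "se", "pvalue", "stratum",
                    "converged"),
      tibble(power = pw)
    )
  })
  out <- dplyr::bind_rows(rows)
  out$q <- NA_real_
  grs_ok <- !is.na(out$predictor) & out$predictor == "GRS" & out$converged
  if (any(grs_ok)) {
    out$q[grs_ok] <- bh_fdr(pmax(out$pvalue[grs_ok], .Machine$double.xmin))
  }
  out <- dplyr::relocate(out, "q", .after = "pvalue")
  class(out) <- c("phewas_screen", class(out))
  attr(out, "exposure_name") <- exposure_name(set)
  out
}

#' Per-SNP instrument-outcome associations for one outcome
#'
#' Fits one covariate-adjusted regression per instrument SNP against a
#' phecode case/control partition (logistic) or a biomarker (linear), and
#' assembles the result with the instrument-exposure effects into an
#' `mr_harmonized` table ready for the MR estimators. Dosages are counts of
#' the instrument's effect allele, so no allele flipping is involved.
#'
#' @param cohort A `cohort`.
#' @param set An [instrument_set()].
#' @param phecode Phecode id for a binary outcome, or `NULL`.
#' @param biomarker Biomarker column name for a continuous outcome, or
#'   `NULL`. Exactly one of `phecode`/`biomarker` must be given.
#' @param covariates Covariate blocks for [cohort_covariates()].
#' @param stratum `"all"`, `"male"` or `"female"`.
#' @param exclude_statin Drop statin users (lipid biomarkers).
#' @param exclude_snps SNP ids to drop (instrument-exclusion reruns).
#' @return `mr_harmonized` tibble with per-SNP `n_case`/`n_control` (or `n`)
#'   attached, plus attribute `assoc` holding the raw regression rows.
#' @export
snp_outcome_assoc <- function(cohort, set, phecode = NULL, biomarker = NULL,
                              covariates = c("age", "sex", "pc"),
                              stratum = "all", exclude_statin = FALSE,
                              exclude_snps = NULL) {
  stopifnot(xor(is.null(phecode), is.null(biomarker)))
  participants <- cohort$participants
  keep <- rep(TRUE, nrow(participants))
  if (stratum %in% c("male", "female")) {
    keep <- participants$sex == stratum
    covariates <- setdiff(covariates, "sex")
  }
  snps <- setdiff(set$snp, exclude_snps)
  if (length(snps) == 0) {
    abort("all instrument SNPs excluded", class = "phewasmr_validation_error")
  }
  participants <- participants[keep, ]
  dosages <- cohort$dosages[keep, , drop = FALSE]
  covs <- cohort_covariates(list(participants = participants), covariates)
  if (!is.null(phecode)) {
    phe_sets <- map_to_phecodes(cohort$diagnoses, cohort$map)
    cc <- build_case_control(phecode, phe_sets, cohort$map, participants)
    sex_req <- cohort$map$sex[cohort$map$phecode == phecode]
    if (length(sex_req) == 1 && sex_req %in% c("male", "female") &&
        "sex" %in% colnames(covs)) {
      covs <- covs[, colnames(covs) != "sex", drop = FALSE]
    }
    if (cc$n_case < 1 || cc$n_control < 1) {
      abort(sprintf("phecode %s has no cases or no controls in stratum %s",
                    phecode, stratum),
            class = "phewasmr_validation_error")
    }
    idx <- participants$participant_id %in% c(cc$case_ids, cc$control_ids)
    y <- as.integer(participants$participant_id[idx] %in% cc$case_ids)
    fit_one <- function(snp) {
      logistic_assoc(y, dosages[idx, snp], covs[idx, , drop = FALSE],
                     outcome = phecode, predictor_name = snp,
                     stratum = stratum)
    }
  } else {
    bio <- cohort$biomarkers[keep, ]
    idx <- rep(TRUE, nrow(participants))
    if (exclude_statin) idx <- bio$statin == 0
    y <- bio[[biomarker]][idx]
    fit_one <- function(snp) {
      linear_assoc(y, dosages[idx, snp], covs[idx, , drop = FALSE],
                   outcome = biomarker, predictor_name = snp,
                   stratum = stratum)
    }
  }
  assoc <- dplyr::bind_rows(purrr::map(snps, fit_one))
  ok <- assoc$converged
  if (any(!ok)) {
    warn(paste0("excluding non-converged SNP association(s): ",
                paste(assoc$predictor[!ok], collapse = ", ")))
  }
  assoc <- assoc[ok, ]
  sub <- set[match(assoc$predictor, set$snp), ]
  h <- harmonized_data(assoc$predictor, sub$beta, sub$se,
                       assoc$beta, assoc$se,
                       exposure_name = exposure_name(set),
                       exposure_sd = exposure_sd(set))
  attr(h, "assoc") <- assoc
  h
}
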