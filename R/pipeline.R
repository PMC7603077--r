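#' Configure a PheWAS-MR study
#'
#' Collects the tunable thresholds of the full pipeline. Defaults follow
#' common two-sample-MR practice: 5% FDR for the screen, the 80% power
#' filter at a detectable OR of 1.2 per SD, and reporting gates requiring no
#' evidence of heterogeneity (Cochran Q p >= 0.05) or directional pleiotropy
#' (Egger intercept p >= 0.05).
#'
#' @param fdr_cutoff FDR threshold for the GRS screen.
#' @param or_detect,power_alpha,power_threshold,apply_power_filter Power
#'   filter, see [mr_power()].
#' @param q_gate,intercept_gate Minimum Cochran-Q and Egger-intercept
#'   p-values for a pair to be reported as causal.
#' @param sig_level Two-sided p-value threshold used when labeling
#'   sex-specific effects.
#' @param n_boot Weighted-median bootstrap replicates.
#' @param simex `"auto"` runs SIMEX only when `i2_gx < simex_i2_threshold`;
#'   `"always"`/`"never"` override.
#' @param simex_i2_threshold NOME threshold below which SIMEX is applied.
#' @param simex_n_sim,simex_lambdas SIMEX settings ([mr_simex_egger()]).
#' @param covariates Covariate blocks for the association scans.
#' @param sex_stratified Run the per-sex analysis of gated pairs.
#' @param statin_exclusion Exclude statin users from lipid-biomarker scans.
#' @param seed Seed for the stochastic methods (bootstrap, SIMEX).
#' @return A `study_config` list.
#' @export
study_config <- function(fdr_cutoff = 0.05, or_detect = 1.2,
                         power_alpha = 0.05, power_threshold = 0.8,
                         apply_power_filter = TRUE,
                         q_gate = 0.05, intercept_gate = 0.05,
                         sig_level = 0.05,
                         n_boot = 1000,
                         simex = c("auto", "always", "never"),
                         simex_i2_threshold = 0.9,
                         simex_n_sim = 500,
                         simex_lambdas = c(0, 0.5, 1, 1.5, 2),
                         covariates = c("age", "sex", "pc"),
                         sex_stratified = TRUE,
                         statin_exclusion = TRUE,
                         seed = 1) {
  for (thr in c(fdr_cutoff, q_gate, intercept_gate, sig_level)) {
    if (!is.finite(thr) || thr <= 0 || thr >= 1) {
      abort("thresholds must lie in (0, 1)", class = "phewasmr_config_error")
    }
  }
  structure(list(
    fdr_cutoff = fdr_cutoff, or_detect = or_detect,
    power_alpha = power_alpha, power_threshold = power_threshold,
    apply_power_filter = apply_power_filter,
    q_gate = q_gate, intercept_gate = intercept_gate,
    sig_level = sig_level, n_boot = n_boot,
    simex = match.arg(simex),
    simex_i2_threshold = simex_i2_threshold,
    simex_n_sim = simex_n_sim, simex_lambdas = simex_lambdas,
    covariates = covariates,
    sex_stratified = sex_stratified,
    statin_exclusion = statin_exclusion,
    seed = as.integer(seed)
  ), class = "study_config")
}

lipid_biomarkers <- c("TC", "LDL", "HDL", "TG")

mr_with_sensitivity <- function(h, config, outcome, stratum = "all") {
  sd <- attr(h, "exposure_sd") %||% 1
  res <- mr_estimate(h, n_boot = config$n_boot, seed = config$seed)
  i2 <- if (nrow(h) >= 2) i2_gx(h) else NA_real_
  run_simex <- nrow(h) >= 3 && (config$simex == "always" ||
    (config$simex == "auto" && is.finite(i2) &&
       i2 < config$simex_i2_threshold))
  if (run_simex) {
    res <- dplyr::bind_rows(
      res, mr_simex_egger(h, lambdas = config$simex_lambdas,
                          n_sim = config$simex_n_sim, seed = config$seed))
  }
  res$outcome <- outcome
  res$stratum <- stratum
  res$i2_gx <- i2
  res <- scale_per_sd(res, sd)
  loo <- if (nrow(h) >= 3) {
    l <- scale_per_sd(mr_leave_one_out(h), sd)
    l$outcome <- outcome; l$stratum <- stratum
    l
  } else NULL
  list(mr = res, loo = loo)
}

#' Run the full PheWAS-MR study
#'
#' End-to-end orchestration for one or more exposures against a cohort:
#' Hardy-Weinberg checks on the instrument SNPs, the GRS-based PheWAS screen
#' with power filter and FDR control, per-candidate two-sample MR (exposure
#' effects from the instrument tables, outcome effects from per-SNP scans in
#' the cohort) with the full sensitivity suite, heterogeneity/pleiotropy
#' reporting gates, sex-stratified estimates for the gated pairs, and
#' lipid-biomarker MR with statin exclusion. Deterministic given
#' `config$seed`.
#'
#' @param cohort A `cohort` object.
#' @param instruments An [instrument_set()] or list of them.
#' @param config A [study_config()].
#' @param pleiotropy_catalog Optional local secondary-phenotype catalog for
#'   [pleiotropy_lookup()]; flagged SNPs trigger instrument-exclusion reruns
#'   for biomarker outcomes.
#' @return A `study_report` list: `screen`, `mr`, `causal` (gated pairs),
#'   `sex_stratified`, `biomarker_mr`, `sensitivity` (leave-one-out, HWE,
#'   instrument-exclusion reruns, flagged SNPs), `counts`, and a `manifest`
#'   (config hash, seed, versions) sufficient to re-run bit-identically.
#' @export
run_phewas_mr <- function(cohort, instruments, config = study_config(),
                          pleiotropy_catalog = NULL) {
  if (inherits(instruments, "instrument_set")) instruments <- list(instruments)
  names(instruments) <- vapply(instruments, exposure_name, character(1))
  inform(sprintf("[stage:init] %d participants, %d exposure(s)",
                 nrow(cohort$participants), length(instruments)))

  hwe <- hwe_test(cohort$dosages)

  flagged <- if (!is.null(pleiotropy_catalog)) {
    pleiotropy_lookup(colnames(cohort$dosages), pleiotropy_catalog)
  } else tibble(snp = character(), trait = character(), pvalue = numeric())

  screens <- list(); mr_rows <- list(); loo_rows <- list()
  for (ex in names(instruments)) {
    set <- instruments[[ex]]
    screen <- phewas_screen(
      cohort, set,
      covariates = config$covariates,
      or_detect = config$or_detect, power_alpha = config$power_alpha,
      power_threshold = config$power_threshold,
      apply_power_filter = config$apply_power_filter)
    screen$exposure <- ex
    screens[[ex]] <- screen
    sig <- screen$phecode[!is.na(screen$q) & screen$q <= config$fdr_cutoff]
    inform(sprintf(
      "[stage:screen] %s: %d phecode(s) tested, %d FDR-significant",
      ex, sum(screen$predictor == "GRS", na.rm = TRUE), length(sig)))
    for (ph in sig) {
      h <- snp_outcome_assoc(cohort, set, phecode = ph,
                             covariates = config$covariates)
      out <- mr_with_sensitivity(h, config, outcome = ph)
      mr_rows[[paste(ex, ph)]] <- out$mr
      loo_rows[[paste(ex, ph)]] <- out$loo
    }
  }
  screen_tbl <- dplyr::bind_rows(screens)
  # typed empty template so downstream selections work with zero candidates
  empty_mr <- mr_result_row("ivw", NA_real_, 1, 0L)[0, ]
  mr_tbl <- dplyr::bind_rows(c(list(empty_mr), mr_rows))
  loo_tbl <- dplyr::bind_rows(loo_rows)

  causal <- if (nrow(mr_tbl) > 0) {
    ivw <- mr_tbl[mr_tbl$method == "ivw", ]
    gate <- dplyr::group_by(mr_tbl, .data$exposure, .data$outcome) |>
      dplyr::summarise(
        q_ok = all(.data$q_pvalue >= config$q_gate, na.rm = TRUE),
        intercept_ok = all(.data$egger_intercept_p >= config$intercept_gate,
                           na.rm = TRUE),
        .groups = "drop")
    dplyr::inner_join(ivw, gate[gate$q_ok & gate$intercept_ok,
                                c("exposure", "outcome")],
                      by = c("exposure", "outcome"))
  } else mr_tbl
  inform(sprintf("[stage:gates] %d candidate pair(s), %d pass the gates",
                 nrow(mr_tbl[mr_tbl$method == "ivw", ]), nrow(causal)))

  sex_tbl <- NULL
  if (config$sex_stratified && nrow(causal) > 0) {
    sex_tbl <- run_sex_stratified(cohort, instruments, causal, config)
  }

  bio_names <- intersect(lipid_biomarkers, names(cohort$biomarkers))
  bio_rows <- list(); rerun_rows <- list()
  for (ex in names(instruments)) {
    set <- instruments[[ex]]
    excl <- intersect(flagged$snp, set$snp)
    for (bm in bio_names) {
      h <- snp_outcome_assoc(cohort, set, biomarker = bm,
                             covariates = config$covariates,
                             exclude_statin = config$statin_exclusion)
      out <- mr_with_sensitivity(h, config, outcome = bm)
      res <- out$mr
      # report WM as headline when IVW heterogeneity is significant
      ivw_qp <- res$q_pvalue[res$method == "ivw"]
      res$headline <- res$method ==
        if (length(ivw_qp) == 1 && is.finite(ivw_qp) &&
            ivw_qp < 0.05 && "wm" %in% res$method) "wm" else "ivw"
      bio_rows[[paste(ex, bm)]] <- res
      loo_rows[[paste(ex, bm, "bio")]] <- out$loo
      if (length(excl) > 0 && nrow(set) - length(excl) >= 1) {
        h2 <- snp_outcome_assoc(cohort, set, biomarker = bm,
                                covariates = config$covariates,
                                exclude_statin = config$statin_exclusion,
                                exclude_snps = excl)
        r2 <- suppressMessages(mr_ivw(h2))
        r2 <- scale_per_sd(r2, exposure_sd(set))
        r2$outcome <- bm
        r2$excluded_snps <- paste(excl, collapse = ";")
        full_beta <- res$beta[res$method == "ivw"]
        r2$delta_beta <- r2$beta - full_beta
        rerun_rows[[paste(ex, bm)]] <- r2
      }
    }
  }
  bio_tbl <- dplyr::bind_rows(bio_rows)
  loo_tbl <- dplyr::bind_rows(loo_tbl, dplyr::bind_rows(
    loo_rows[grepl(" bio$", names(loo_rows))]))

  manifest <- list(
    config_hash = rlang::hash(config),
    sim_seed = cohort$config$seed %||% NA_integer_,
    analysis_seed = config$seed,
    package_version = as.character(packageVersion("phewasmr")),
    r_version = paste(R.version$major, R.version$minor, sep = "."))

  structure(list(
    screen = screen_tbl,
    mr = mr_tbl,
    causal = causal,
    sex_stratified = sex_tbl,
    biomarker_mr = bio_tbl,
    sensitivity = list(
      leave_one_out = loo_tbl,
      hwe = hwe,
      flagged_snps = flagged,
      instrument_exclusion = dplyr::bind_rows(rerun_rows)),
    counts = list(
      n_participants = nrow(cohort$participants),
      n_phecodes_tested = sum(screen_tbl$predictor == "GRS", na.rm = TRUE),
      n_candidates = length(unique(paste(mr_tbl$exposure, mr_tbl$outcome))),
      n_causal = nrow(causal)),
    manifest = manifest
  ), class = "study_report")
}

#' Sex-stratified IVW MR for candidate pairs
#'
#' Refits the instrument-outcome associations within each sex (dropping the
#' sex covariate), runs IVW per stratum, and labels a pair sex-specific when
#' its estimate is significant in exactly one stratum and not in the
#' combined sample. Pairs whose candidates table shows pleiotropy evidence
#' should be excluded by the caller (the pipeline passes only gated pairs).
#' Single-sex phecodes are skipped in the other stratum with a note.
#'
#' @param cohort A `cohort`.
#' @param instruments Named list of [instrument_set()]s.
#' @param candidates `mr_result` rows (IVW, combined) with `exposure` and
#'   `outcome` (phecode) columns.
#' @param config A [study_config()].
#' @return Tibble of per-stratum IVW rows (including the combined rows) with
#'   logical `significant` and, per pair, `sex_specific`
#'   (`"female"`/`"male"`/`NA`).
#' @export
run_sex_stratified <- function(cohort, instruments, candidates,
                               config = study_config()) {
  if (inherits(instruments, "instrument_set")) instruments <- list(instruments)
  names(instruments) <- vapply(instruments, exposure_name, character(1))
  rows <- list()
  for (i in seq_len(nrow(candidates))) {
    ex <- candidates$exposure[i]; ph <- candidates$outcome[i]
    set <- instruments[[ex]]
    map_row <- cohort$map[cohort$map$phecode == ph, ]
    combined <- candidates[i, ]
    combined$stratum <- "all"
    per <- list(combined)
    for (sx in c("female", "male")) {
      if (nrow(map_row) == 1 && map_row$sex[1] %in% c("male", "female") &&
          map_row$sex[1] != sx) {
        inform(sprintf("[stage:sex] phecode %s is %s-only; skipping %s",
                       ph, map_row$sex[1], sx))
        next
      }
      h <- tryCatch(
        snp_outcome_assoc(cohort, set, phecode = ph,
                          covariates = config$covariates, stratum = sx),
        error = function(e) NULL)
      if (is.null(h)) next
      r <- suppressMessages(mr_ivw(h))
      r <- scale_per_sd(r, exposure_sd(set))
      r$outcome <- ph; r$stratum <- sx
      per[[sx]] <- r
    }
    per <- dplyr::bind_rows(per)
    per$significant <- per$pvalue < config$sig_level
    sig_strata <- per$stratum[per$significant & per$stratum != "all"]
    combined_sig <- any(per$significant[per$stratum == "all"])
    per$sex_specific <- if (length(sig_strata) == 1 && !combined_sig) {
      sig_strata
    } else NA_character_
    rows[[i]] <- per
  }
  dplyr::bind_rows(rows)
}

#' Replication MR against external summary statistics
#'
#' Harmonizes the instruments against an external outcome summary-statistics
#' table (consortium-style) and runs IVW, weighted-median and MR-Egger,
#' formatting the result in the forest-table layout used for lipid
#' replication: one row per method with effect and pleiotropy p-values.
#'
#' @param set An [instrument_set()].
#' @param external_stats Data frame in the outcome summary-statistics dialect
#'   (`snp`, `effect_allele`, `baseline_allele`, `eaf`, `beta`, `se`,
#'   `pvalue`, `n`).
#' @param outcome,data_label Labels for the output.
#' @param config A [study_config()] (bootstrap and seed settings).
#' @return Tibble with columns `exposure`, `outcome`, `method`, `n_snps`,
#'   `beta`, `se`, `ci_low`, `ci_high`, `p_effect`, `p_pleiotropy`,
#'   `n_total`, `data`. The pleiotropy p is Cochran's Q for IVW and the
#'   intercept test for MR-Egger.
#' @export
run_replication <- function(set, external_stats, outcome = "outcome",
                            data_label = "external",
                            config = study_config()) {
  h <- harmonize(set, external_stats)
  res <- mr_estimate(h, n_boot = config$n_boot, seed = config$seed)
  res <- scale_per_sd(res, exposure_sd(set))
  n_total <- if ("n" %in% names(external_stats)) {
    max(external_stats$n, na.rm = TRUE)
  } else NA_real_
  tibble(
    exposure = exposure_name(set),
    outcome = outcome,
    method = res$method,
    n_snps = res$n_snps,
    beta = res$beta,
    se = res$se,
    ci_low = res$ci_low,
    ci_high = res$ci_high,
    p_effect = res$pvalue,
    p_pleiotropy = dplyr::case_when(
      res$method == "ivw" ~ res$q_pvalue,
      res$method == "egger" ~ res$egger_intercept_p,
      TRUE ~ NA_real_),
    n_total = n_total,
    data = data_label)
}

#' Hardy-Weinberg equilibrium test
#'
#' One-degree-of-freedom chi-square test comparing observed genotype counts
#' to the p^2 / 2pq / q^2 expectation at the sample allele frequency.
#' Accepts a dosage matrix (hard calls by rounding) or a 3-column matrix of
#' (n_AA, n_Aa, n_aa) counts per SNP.
#'
#' @param x Dosage matrix (individuals x SNPs) or counts matrix (SNPs x 3).
#' @return Tibble `snp`, `chisq`, `pvalue` (monomorphic SNPs get p = 1 with
#'   a warning).
#' @export
hwe_test <- function(x) {
  x <- as.matrix(x)
  counts <- if (ncol(x) == 3 && !is.null(colnames(x)) &&
                all(colnames(x) %in% c("n_AA", "n_Aa", "n_aa"))) {
    x
  } else {
    hard <- round(x)
    t(apply(hard, 2, function(g) {
      c(n_AA = sum(g == 2), n_Aa = sum(g == 1), n_aa = sum(g == 0))
    }))
  }
  snps <- rownames(counts) %||% as.character(seq_len(nrow(counts)))
  res <- purrr::map(seq_len(nrow(counts)), function(i) {
    n2 <- counts[i, "n_AA"]; n1 <- counts[i, "n_Aa"]; n0 <- counts[i, "n_aa"]
    n <- n2 + n1 + n0
    p <- (2 * n2 + n1) / (2 * n)
    if (p == 0 || p == 1) {
      warn(sprintf("SNP %s is monomorphic; HWE p set to 1", snps[i]))
      return(tibble(snp = snps[i], chisq = 0, pvalue = 1))
    }
    expected <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
    chisq <- sum((c(n2, n1, n0) - expected)^2 / expected)
    tibble(snp = snps[i], chisq = chisq,
           pvalue = pchisq(chisq, 1, lower.tail = FALSE))
  })
  dplyr::bind_rows(res)
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  cat(sprintf("  participants: %d\n", x$counts$n_participants))
  cat(sprintf("  phecodes tested (GRS rows): %d\n",
              x$counts$n_phecodes_tested))
  cat(sprintf("  candidate pairs: %d; gated causal pairs: %d\n",
              x$counts$n_candidates, x$counts$n_causal))
  cat(sprintf("  manifest: config %s, seed %d\n",
              substr(x$manifest$config_hash, 1, 8), x$manifest$analysis_seed))
  invisible(x)
}

#' Tidy a study report
#'
#' `tidy()` returns the full MR table; `glance()` one row of study-level
#' counts and the manifest hash.
#'
#' @param x A `study_report`.
#' @param ... Unused.
#' @method tidy study_report
#' @export
tidy.study_report <- function(x, ...) x$mr

#' @rdname tidy.study_report
#' @method glance study_report
#' @export
glance.study_report <- function(x, ...) {
  tibble(n_participants = x$counts$n_participants,
         n_phecodes_tested = x$counts$n_phecodes_tested,
         n_candidates = x$counts$n_candidates,
         n_causal = x$counts$n_causal,
         config_hash = x$manifest$config_hash)
}
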