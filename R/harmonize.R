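#' Harmonize instrument and outcome summary statistics
#'
#' Aligns per-SNP outcome associations to the instrument's effect allele so
#' the two-sample MR estimators see effects expressed per copy of the same
#' allele. For each instrument SNP found in the outcome table:
#'
#' * identical allele pair: kept as is;
#' * swapped alleles: outcome beta negated, outcome EAF replaced by `1 - eaf`;
#' * complementary-strand pair: treated as the same orientation (beta kept);
#' * complementary and swapped: beta negated, EAF flipped.
#'
#' Strand-ambiguous (palindromic A/T or G/C) SNPs cannot be aligned from
#' alleles alone; they are resolved by comparing allele frequencies: the
#' orientation whose outcome EAF is closer to the instrument EAF is chosen,
#' and SNPs whose frequencies are too close to 0.5 to discriminate (within
#' `eaf_tolerance`) are dropped as unresolvable.
#'
#' @param set An [instrument_set()].
#' @param outcome_stats Data frame keyed by `snp` with columns
#'   `effect_allele`, `baseline_allele`, `eaf`, `beta`, `se` (the outcome
#'   summary-statistics dialect; `pvalue` and `n` are carried through when
#'   present).
#' @param eaf_tolerance Palindromic SNPs with instrument or outcome EAF within
#'   this distance of 0.5 are dropped (default 0.08).
#' @return A tibble of class `mr_harmonized`, in instrument order, with
#'   columns `snp`, `effect_allele`, `baseline_allele`, `eaf`, `bx`, `sx`
#'   (instrument effect and SE), `by`, `sy` (aligned outcome effect and SE),
#'   and `action` (one of `keep`, `swap`, `strand_flip`, `strand_swap`,
#'   `palindromic_keep`, `palindromic_flip`). Dropped SNPs are reported via
#'   warnings and omitted. The result can itself be passed as `outcome_stats`
#'   (harmonization is idempotent). Attributes `exposure_name`/`exposure_sd`
#'   are carried from `set`.
#' @examples
#' iron <- read_instruments(phewasmr_example("iron_benyamin.tsv"), "iron")
#' out <- tibble::tibble(snp = iron$snp, effect_allele = iron$baseline_allele,
#'   baseline_allele = iron$effect_allele, eaf = 1 - iron$eaf,
#'   beta = c(0.1, 0.2, 0.3), se = 0.05)
#' harmonize(iron, out)  # betas come back negated
#' @export
harmonize <- function(set, outcome_stats, eaf_tolerance = 0.08) {
  stopifnot(inherits(set, "instrument_set"))
  outcome_stats <- as_tibble(outcome_stats)
  # accept an already-harmonized table (columns by/sy) as outcome stats
  if (all(c("by", "sy") %in% names(outcome_stats)) &&
      !all(c("beta", "se") %in% names(outcome_stats))) {
    outcome_stats <- dplyr::rename(outcome_stats, beta = "by", se = "sy")
  }
  need <- c("snp", "effect_allele", "baseline_allele", "eaf", "beta", "se")
  miss <- setdiff(need, names(outcome_stats))
  if (length(miss) > 0) {
    abort(paste0("outcome table is missing column(s): ",
                 paste(miss, collapse = ", ")),
          class = "phewasmr_config_error")
  }

  rows <- purrr::map(seq_len(nrow(set)), function(i) {
    ins <- set[i, ]
    out <- outcome_stats[outcome_stats$snp == ins$snp, ]
    if (nrow(out) == 0) {
      warn(sprintf("SNP %s absent from outcome table; dropped", ins$snp))
      return(NULL)
    }
    out <- out[1, ]
    ea_i <- ins$effect_allele; ba_i <- ins$baseline_allele
    ea_o <- out$effect_allele; ba_o <- out$baseline_allele
    flip <- NA  # TRUE -> outcome effect refers to the baseline allele
    action <- NA_character_
    if (is_palindromic(ea_i, ba_i)) {
      # A/T or G/C: allele labels cannot distinguish keep vs strand+swap
      if (!setequal(c(ea_o, ba_o), c(ea_i, ba_i)) &&
          !setequal(c(ea_o, ba_o), dna_complement[c(ea_i, ba_i)])) {
        warn(sprintf("SNP %s: outcome alleles %s/%s incompatible; dropped",
                     ins$snp, ea_o, ba_o))
        return(NULL)
      }
      if (abs(ins$eaf - 0.5) < eaf_tolerance ||
          abs(out$eaf - 0.5) < eaf_tolerance) {
        warn(sprintf(
          "SNP %s: palindromic with allele frequency near 0.5; dropped",
          ins$snp))
        return(NULL)
      }
      same <- abs(ins$eaf - out$eaf) <= abs(ins$eaf - (1 - out$eaf))
      flip <- !same
      action <- if (same) "palindromic_keep" else "palindromic_flip"
    } else if (ea_o == ea_i && ba_o == ba_i) {
      flip <- FALSE; action <- "keep"
    } else if (ea_o == ba_i && ba_o == ea_i) {
      flip <- TRUE; action <- "swap"
    } else if (identical(unname(dna_complement[ea_o]), ea_i) &&
               identical(unname(dna_complement[ba_o]), ba_i)) {
      flip <- FALSE; action <- "strand_flip"
    } else if (identical(unname(dna_complement[ea_o]), ba_i) &&
               identical(unname(dna_complement[ba_o]), ea_i)) {
      flip <- TRUE; action <- "strand_swap"
    } else {
      warn(sprintf("SNP %s: outcome alleles %s/%s incompatible; dropped",
                   ins$snp, ea_o, ba_o))
      return(NULL)
    }
    tibble(
      snp = ins$snp,
      effect_allele = ea_i,
      baseline_allele = ba_i,
      eaf = if (flip) 1 - out$eaf else out$eaf,
      bx = ins$beta,
      sx = ins$se,
      by = if (flip) -out$beta else out$beta,
      sy = out$se,
      action = action
    )
  })
  h <- dplyr::bind_rows(rows)
  if (nrow(h) == 0) {
    abort("no instrument SNPs could be harmonized against the outcome table",
          class = "phewasmr_validation_error")
  }
  new_harmonized(h, exposure_name = exposure_name(set),
                 exposure_sd = exposure_sd(set))
}

new_harmonized <- function(h, exposure_name = NULL, exposure_sd = 1) {
  structure(as_tibble(h),
            class = c("mr_harmonized", class(as_tibble(h))),
            exposure_name = exposure_name,
            exposure_sd = exposure_sd)
}

#' Assemble harmonized data from aligned effect vectors
#'
#' Convenience constructor for already-aligned two-sample data (e.g. when the
#' outcome associations were estimated on effect-allele dosages from the same
#' instrument table, so no allele flipping can be needed).
#'
#' @param snp SNP identifiers.
#' @param bx,sx Instrument-exposure effects and standard errors.
#' @param by,sy Instrument-outcome effects and standard errors.
#' @param exposure_name,exposure_sd Exposure metadata (see [instrument_set()]).
#' @return A tibble of class `mr_harmonized`.
#' @export
harmonized_data <- function(snp, bx, sx, by, sy,
                            exposure_name = NULL, exposure_sd = 1) {
  n <- length(snp)
  recycle <- function(x) {
    if (length(x) == 1) rep(x, n)
    else if (length(x) == n) x
    else abort("effect vectors must have length 1 or length(snp)",
               class = "phewasmr_validation_error")
  }
  bx <- recycle(bx); sx <- recycle(sx)
  by <- recycle(by); sy <- recycle(sy)
  if (any(!is.finite(sx)) || any(sx < 0) || any(!is.finite(sy)) ||
      any(sy <= 0)) {
    abort("standard errors must be finite and positive (sx may be zero)",
          class = "phewasmr_validation_error")
  }
  new_harmonized(
    tibble(snp = snp, bx = bx, sx = sx, by = by, sy = sy),
    exposure_name = exposure_name, exposure_sd = exposure_sd
  )
}
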