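#' Construct a validated instrument set
#'
#' An instrument set is a tibble of genetic variants used as instrumental
#' variables for one exposure (e.g. serum iron), with one row per SNP and the
#' summary statistics reported by the discovery GWAS: effect and baseline
#' alleles, effect-allele frequency, per-allele effect on the exposure with
#' its standard error and p-value, the fraction of exposure variance the SNP
#' explains, and the GWAS sample size.
#'
#' @param x Data frame with columns `snp`, `effect_allele`, `baseline_allele`,
#'   `chrom`, `eaf`, `beta`, `se`, `pvalue`, `r2`, `n`.
#' @param exposure_name Label for the exposure (e.g. `"iron"`).
#' @param exposure_sd Standard deviation of the exposure, in the units of
#'   `beta`, used by [scale_per_sd()] to express causal estimates per SD
#'   increment. Default 1 treats the instrument betas as already SD-scaled.
#' @return A tibble of class `instrument_set` with attributes `exposure_name`
#'   and `exposure_sd`. Row order is preserved.
#' @examples
#' iron <- read_instruments(phewasmr_example("iron_benyamin.tsv"), "iron")
#' total_variance_explained(iron)
#' @export
instrument_set <- function(x, exposure_name, exposure_sd = 1) {
  required <- c("snp", "effect_allele", "baseline_allele", "chrom",
                "eaf", "beta", "se", "pvalue", "r2", "n")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(
      paste0("instrument table is missing column(s): ",
             paste(missing_cols, collapse = ", ")),
      class = "phewasmr_config_error"
    )
  }
  x <- as_tibble(x)[required]
  if (nrow(x) == 0) {
    abort("instrument table has no rows", class = "phewasmr_validation_error")
  }
  check_row <- function(i) {
    row <- x[i, ]
    fail <- function(field, why) {
      abort(sprintf("instrument row %d (%s): invalid %s (%s)",
                    i, row$snp %||% "?", field, why),
            class = "phewasmr_validation_error")
    }
    if (!row$effect_allele %in% c("A", "C", "G", "T"))
      fail("effect_allele", "must be one of A/C/G/T")
    if (!row$baseline_allele %in% c("A", "C", "G", "T"))
      fail("baseline_allele", "must be one of A/C/G/T")
    if (row$effect_allele == row$baseline_allele)
      fail("baseline_allele", "equals effect_allele")
    if (!is.finite(row$se) || row$se <= 0) fail("se", "must be > 0")
    if (!is.finite(row$eaf) || row$eaf <= 0 || row$eaf >= 1)
      fail("eaf", "must lie strictly in (0, 1)")
    if (!is.finite(row$r2) || row$r2 < 0 || row$r2 >= 1)
      fail("r2", "must lie in [0, 1)")
    if (!is.finite(row$n) || row$n < 3) fail("n", "must be >= 3")
    invisible(NULL)
  }
  for (i in seq_len(nrow(x))) check_row(i)
  if (anyDuplicated(x$snp)) {
    abort("duplicate snp ids in instrument table",
          class = "phewasmr_validation_error")
  }
  if (!is.numeric(exposure_sd) || exposure_sd <= 0) {
    abort("exposure_sd must be a positive number",
          class = "phewasmr_validation_error")
  }
  structure(x,
            class = c("instrument_set", class(x)),
            exposure_name = exposure_name,
            exposure_sd = exposure_sd)
}

#' Read genetic instruments from a delimited file
#'
#' Reads a tab- or comma-delimited summary-statistics table (header
#' `snp,effect_allele,baseline_allele,chrom,eaf,beta,se,pvalue,r2,n`) and
#' validates it into an [instrument_set()]. The delimiter is auto-detected
#' from the header line.
#'
#' @inheritParams instrument_set
#' @param path Path to the file.
#' @export
read_instruments <- function(path, exposure_name, exposure_sd = 1) {
  header <- readLines(path, n = 1)
  if (length(header) == 0) {
    abort("instrument file is empty", class = "phewasmr_validation_error")
  }
  delim <- if (grepl(",", header, fixed = TRUE)) "," else "\t"
  x <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                         progress = FALSE)
  instrument_set(x, exposure_name = exposure_name, exposure_sd = exposure_sd)
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("<instrument_set> exposure: %s (SD = %g), %d SNP(s)\n",
              exposure_name(x), exposure_sd(x), nrow(x)))
  NextMethod()
}

#' @rdname instrument_set
#' @export
exposure_name <- function(x) attr(x, "exposure_name")

#' @rdname instrument_set
#' @export
exposure_sd <- function(x) attr(x, "exposure_sd") %||% 1

#' Path to a packaged example data file
#'
#' @param file File name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @export
phewasmr_example <- function(file = NULL) {
  if (is.null(file)) {
    dir(system.file("extdata", package = "phewasmr"))
  } else {
    system.file("extdata", file, package = "phewasmr", mustWork = TRUE)
  }
}

#' Instrument-strength F-statistic
#'
#' Strength of a genetic instrument from its explained variance fraction
#' \eqn{R^2} and discovery sample size \eqn{N}:
#' \deqn{F = (N - 2) \frac{R^2}{1 - R^2}.}
#' Values above 10 are conventionally taken to rule out weak-instrument bias.
#'
#' @param r2 Fraction of exposure variance explained, in `[0, 1)`. May also be
#'   an [instrument_set()], in which case `n` is ignored and a vector of
#'   per-SNP F-statistics is returned.
#' @param n Discovery GWAS sample size (>= 3).
#' @return Nonnegative numeric vector.
#' @examples
#' f_statistic(0.013, 48972)  # ~645
#' @export
f_statistic <- function(r2, n = NULL) {
  if (inherits(r2, "instrument_set")) {
    set <- r2
    return(setNames(f_statistic(set$r2, set$n), set$snp))
  }
  if (any(r2 >= 1)) {
    abort("r2 must be < 1", class = "phewasmr_domain_error")
  }
  if (any(r2 < 0) || any(n < 3)) {
    abort("require 0 <= r2 < 1 and n >= 3", class = "phewasmr_domain_error")
  }
  (n - 2) * r2 / (1 - r2)
}

#' Total exposure variance explained by an instrument set
#'
#' @param set An [instrument_set()].
#' @return Sum of per-SNP `r2` (a fraction).
#' @export
total_variance_explained <- function(set) {
  stopifnot(inherits(set, "instrument_set"))
  sum(set$r2)
}

#' Genetic-risk-score weights
#'
#' Per-SNP weights for a dosage-weighted genetic risk score: the instrument
#' betas, aligned to effect-allele dosage coding (0..2 copies of the effect
#' allele).
#'
#' @param set An [instrument_set()].
#' @return Named numeric vector of per-SNP weights.
#' @export
grs_weights <- function(set) {
  stopifnot(inherits(set, "instrument_set"))
  setNames(set$beta, set$snp)
}

#' Compute a weighted genetic risk score
#'
#' @param dosages Numeric matrix (individuals x SNPs) of effect-allele
#'   dosages, with column names matching the instrument SNP ids.
#' @param set An [instrument_set()].
#' @return Numeric vector, one score per individual.
#' @export
compute_grs <- function(dosages, set) {
  w <- grs_weights(set)
  missing_snps <- setdiff(names(w), colnames(dosages))
  if (length(missing_snps) > 0) {
    abort(paste0("dosage matrix lacks instrument SNP(s): ",
                 paste(missing_snps, collapse = ", ")),
          class = "phewasmr_config_error")
  }
  drop(dosages[, names(w), drop = FALSE] %*% w)
}
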