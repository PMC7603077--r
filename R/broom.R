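#' Tidy MR results
#'
#' Broom-style accessors: `tidy()` returns one row per estimate with
#' `estimate`/`std.error`/`conf.low`/`conf.high`/`p.value` naming, `glance()`
#' the heterogeneity and pleiotropy diagnostics.
#'
#' @param x An `mr_result` tibble.
#' @param exponentiate Report odds ratios instead of log-odds.
#' @param ... Unused.
#' @method tidy mr_result
#' @export
tidy.mr_result <- function(x, exponentiate = FALSE, ...) {
  out <- tibble(
    exposure = x$exposure, outcome = x$outcome, stratum = x$stratum,
    method = x$method, n_snps = x$n_snps,
    estimate = if (exponentiate) x$or else x$beta,
    std.error = x$se,
    conf.low = if (exponentiate) x$or_ci_low else x$ci_low,
    conf.high = if (exponentiate) x$or_ci_high else x$ci_high,
    p.value = x$pvalue)
  if ("snp_omitted" %in% names(x)) out$snp_omitted <- x$snp_omitted
  out
}

#' @rdname tidy.mr_result
#' @method glance mr_result
#' @export
glance.mr_result <- function(x, ...) {
  tibble(method = x$method, n_snps = x$n_snps,
         q_stat = x$q_stat, q_df = x$q_df, q_pvalue = x$q_pvalue,
         egger_intercept = x$egger_intercept,
         egger_intercept_p = x$egger_intercept_p)
}

#' Tidy a PheWAS screen
#'
#' @param x A `phewas_screen` tibble.
#' @param ... Unused.
#' @method tidy phewas_screen
#' @export
tidy.phewas_screen <- function(x, ...) {
  as_tibble(x)
}

#' @rdname tidy.phewas_screen
#' @method glance phewas_screen
#' @export
glance.phewas_screen <- function(x, ...) {
  grs <- x[!is.na(x$predictor) & x$predictor == "GRS", ]
  tibble(n_phecodes_tested = nrow(grs),
         n_significant = sum(grs$q <= 0.05, na.rm = TRUE),
         min_q = suppressWarnings(min(grs$q, na.rm = TRUE)))
}
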