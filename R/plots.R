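#' Forest plot of MR estimates
#'
#' @param object An `mr_result` tibble (any number of rows).
#' @param exponentiate Plot odds ratios on a log axis (default TRUE).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mr_result
#' @export
autoplot.mr_result <- function(object, exponentiate = TRUE, ...) {
  d <- tidy.mr_result(object, exponentiate = exponentiate)
  d$label <- paste(ifelse(is.na(d$outcome), "", d$outcome), d$method,
                   ifelse(d$stratum == "all", "", d$stratum))
  null_x <- if (exponentiate) 1 else 0
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$label)) +
    ggplot2::geom_vline(xintercept = null_x, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$conf.low, xmax = .data$conf.high),
      height = 0.2) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = if (exponentiate) "OR per SD of exposure (95% CI)"
                  else "log-odds per SD of exposure (95% CI)",
                  y = NULL) +
    ggplot2::theme_minimal()
  if (exponentiate) p <- p + ggplot2::scale_x_log10()
  p
}

#' PheWAS screen plot
#'
#' -log10 GRS p-values by phecode with the FDR-significant phenotypes
#' highlighted.
#'
#' @param object A `phewas_screen` tibble.
#' @param fdr_cutoff Highlight threshold on q.
#' @param ... Unused.
#' @method autoplot phewas_screen
#' @export
autoplot.phewas_screen <- function(object, fdr_cutoff = 0.05, ...) {
  d <- object[!is.na(object$predictor) & object$predictor == "GRS", ]
  d$significant <- !is.na(d$q) & d$q <= fdr_cutoff
  ggplot2::ggplot(d, ggplot2::aes(x = .data$phecode,
                                  y = -log10(.data$pvalue),
                                  colour = .data$significant)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "phecode", y = expression(-log[10](p)),
                  colour = "FDR significant") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Forest plot of a study report's gated causal pairs
#'
#' @param object A `study_report`.
#' @param ... Passed to [autoplot.mr_result()].
#' @method autoplot study_report
#' @export
autoplot.study_report <- function(object, ...) {
  if (nrow(object$causal) == 0) {
    abort("no gated causal pairs to plot", class = "phewasmr_validation_error")
  }
  autoplot.mr_result(object$causal, ...) +
    ggplot2::labs(title = "Gated causal mineral-outcome pairs (IVW)")
}
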