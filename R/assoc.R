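#' @noRd
# Drop constant and linearly dependent covariate columns, with warnings.
prep_design <- function(predictor, covariates, n) {
  X <- cbind(`(Intercept)` = rep(1, n), predictor = predictor)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (is.null(colnames(covariates))) {
      colnames(covariates) <- paste0("cov", seq_len(ncol(covariates)))
    }
    keep <- apply(covariates, 2, function(col) stats::var(col) > 0)
    if (any(!keep)) {
      warn(paste0("dropping constant covariate(s): ",
                  paste(colnames(covariates)[!keep], collapse = ", ")))
      covariates <- covariates[, keep, drop = FALSE]
    }
    if (ncol(covariates) > 0) X <- cbind(X, covariates)
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    drop_idx <- qx$pivot[(qx$rank + 1):ncol(X)]
    if (any(drop_idx <= 2)) {
      abort("predictor is collinear with the covariates",
            class = "phewasmr_domain_error")
    }
    warn(paste0("dropping linearly dependent covariate(s): ",
                paste(colnames(X)[drop_idx], collapse = ", ")))
    X <- X[, -drop_idx, drop = FALSE]
  }
  X
}

#' Covariate-adjusted logistic association
#'
#' Maximum-likelihood logistic regression of case status on a predictor (a
#' SNP dosage or a genetic risk score) plus covariates, returning the
#' predictor's log-odds coefficient with its Wald standard error and p-value.
#' Constant covariates (e.g. a genotyping-array label that never varies) and
#' linearly dependent columns are dropped with a warning. Non-convergence or
#' separation is flagged (`converged = FALSE`) rather than raised, so callers
#' can exclude the result downstream.
#'
#' @param status 0/1 (or logical) case indicator.
#' @param predictor Numeric vector, same length.
#' @param covariates Optional numeric matrix / data frame of covariates.
#' @param outcome,predictor_name,stratum Labels carried into the result.
#' @return One-row tibble: `outcome`, `predictor`, `beta`, `se`, `pvalue`,
#'   `n_case`, `n_control`, `n`, `stratum`, `converged`.
#' @export
logistic_assoc <- function(status, predictor, covariates = NULL,
                           outcome = NA_character_,
                           predictor_name = "predictor", stratum = "all") {
  status <- as.integer(status)
  n <- length(status)
  stopifnot(length(predictor) == n)
  if (sum(status) < 1 || sum(1 - status) < 1) {
    abort("need at least one case and one control",
          class = "phewasmr_validation_error")
  }
  X <- prep_design(predictor, covariates, n)
  fit <- suppressWarnings(
    glm.fit(X, status, family = binomial())
  )
  beta <- fit$coefficients["predictor"]
  # Wald SE from the unscaled covariance of the IRLS fit
  cov_un <- chol2inv(qr.R(fit$qr))
  se <- sqrt(diag(cov_un))[which(colnames(X) == "predictor")]
  converged <- isTRUE(fit$converged) && is.finite(beta) && is.finite(se) &&
    abs(beta) < 15 && se < 100
  tibble(outcome = outcome, predictor = predictor_name,
         beta = unname(beta), se = unname(se),
         pvalue = 2 * pnorm(-abs(beta / se)),
         n_case = sum(status), n_control = sum(1 - status), n = n,
         stratum = stratum, converged = converged)
}

#' Covariate-adjusted linear association
#'
#' Ordinary least squares of a continuous outcome (e.g. a lipid biomarker)
#' on a predictor plus covariates. For lipid outcomes the caller is expected
#' to have removed statin users beforehand.
#'
#' @inheritParams logistic_assoc
#' @param y Numeric outcome vector.
#' @return One-row tibble: `outcome`, `predictor`, `beta`, `se`, `pvalue`,
#'   `n`, `stratum`, `converged`.
#' @export
linear_assoc <- function(y, predictor, covariates = NULL,
                         outcome = NA_character_,
                         predictor_name = "predictor", stratum = "all") {
  n <- length(y)
  stopifnot(length(predictor) == n)
  if (any(!is.finite(y))) {
    abort("outcome contains non-finite values",
          class = "phewasmr_validation_error")
  }
  if (stats::var(y) == 0) {
    abort("outcome has zero variance", class = "phewasmr_validation_error")
  }
  X <- prep_design(predictor, covariates, n)
  fit <- lm.fit(X, y)
  p <- ncol(X)
  sigma2 <- sum(fit$residuals^2) / (n - p)
  cov_un <- chol2inv(qr.R(fit$qr)) * sigma2
  j <- which(colnames(X) == "predictor")
  beta <- fit$coefficients["predictor"]
  se <- sqrt(diag(cov_un))[j]
  tibble(outcome = outcome, predictor = predictor_name,
         beta = unname(beta), se = unname(se),
         pvalue = 2 * pnorm(-abs(beta / se)),
         n = n, stratum = stratum,
         converged = is.finite(beta) && is.finite(se))
}

#' Approximate power of a two-sample MR analysis for a binary outcome
#'
#' Two-sided z-test power approximation for detecting an odds ratio
#' `or_detect` per SD of exposure, given the case/control split and the
#' variance fraction the instruments explain. With \eqn{N} total samples,
#' case fraction \eqn{K}, and instrument strength \eqn{R^2}, the standard
#' error of the causal log-odds is approximated by
#' \eqn{1/\sqrt{N R^2 K (1-K)}}, giving two-sided power
#' \eqn{\Phi(|\log OR|/SE - z_{1-\alpha/2}) + \Phi(-|\log OR|/SE -
#' z_{1-\alpha/2})} (the second tail vanishes for any usefully powered
#' design and makes the null-effect limit equal \eqn{\alpha}). Phenotypes
#' with power below 0.8 are conventionally dropped from the PheWAS.
#'
#' @param n_case,n_control Case and control counts.
#' @param r2 Total variance explained by the instruments, in (0, 1).
#' @param or_detect Odds ratio to detect (not 1).
#' @param alpha Test level (default 0.05).
#' @return Power in `[0, 1]` (vectorized over counts).
#' @export
mr_power <- function(n_case, n_control, r2, or_detect = 1.2, alpha = 0.05) {
  stopifnot(r2 > 0, r2 < 1, or_detect != 1)
  n <- n_case + n_control
  k <- n_case / n
  se <- 1 / sqrt(n * r2 * k * (1 - k))
  z <- qnorm(1 - alpha / 2)
  d <- abs(log(or_detect)) / se
  pw <- pnorm(d - z) + pnorm(-d - z)
  pw[k <= 0 | k >= 1 | !is.finite(se)] <- 0
  pw
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment:
#' \eqn{q_{(i)} = \min_{j \ge i} p_{(j)} m / j}, ties handled stably, and the
#' result returned in the original input order.
#'
#' @param pvalues Numeric vector of p-values in (0, 1].
#' @return q-value vector, same length and order.
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  stopifnot(all(pvalues > 0), all(pvalues <= 1))
  bh_step_up(pvalues)
}
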