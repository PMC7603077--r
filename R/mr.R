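#' @noRd
mr_result_row <- function(method, beta, se, n_snps,
                          q_stat = NA_real_, q_df = NA_real_,
                          q_pvalue = NA_real_,
                          egger_intercept = NA_real_,
                          egger_intercept_se = NA_real_,
                          egger_intercept_p = NA_real_,
                          exposure = NULL, outcome = NA_character_,
                          stratum = "all", note = NA_character_) {
  beta <- unname(beta); se <- unname(se)
  z <- qnorm(0.975)
  ci_low <- beta - z * se
  ci_high <- beta + z * se
  res <- tibble(
    exposure = exposure %||% NA_character_,
    outcome = outcome,
    stratum = stratum,
    method = method,
    n_snps = as.integer(n_snps),
    beta = beta,
    se = se,
    ci_low = ci_low,
    ci_high = ci_high,
    pvalue = 2 * pnorm(-abs(beta / se)),
    or = exp(beta),
    or_ci_low = exp(ci_low),
    or_ci_high = exp(ci_high),
    q_stat = q_stat,
    q_df = q_df,
    q_pvalue = q_pvalue,
    egger_intercept = egger_intercept,
    egger_intercept_se = egger_intercept_se,
    egger_intercept_p = egger_intercept_p,
    note = note
  )
  class(res) <- c("mr_result", class(res))
  res
}

h_meta <- function(h) {
  list(exposure = attr(h, "exposure_name"),
       sd = attr(h, "exposure_sd") %||% 1)
}

check_h <- function(h, min_snps, method) {
  stopifnot(is.data.frame(h), all(c("bx", "sx", "by", "sy") %in% names(h)))
  if (nrow(h) < min_snps) {
    abort(sprintf("%s requires at least %d SNPs (got %d)",
                  method, min_snps, nrow(h)),
          class = "phewasmr_validation_error")
  }
  invisible(h)
}

#' Wald ratio causal estimate for a single instrument
#'
#' The per-SNP causal estimate `by / bx` with the first-order delta-method
#' standard error `sy / |bx|`. A second-order correction
#' (adding `by^2 sx^2 / bx^4`) is available behind `second_order`.
#'
#' @param h An `mr_harmonized` tibble with exactly one row, or a one-row data
#'   frame with columns `bx`, `sx`, `by`, `sy`.
#' @param second_order Use the second-order delta variance (default FALSE).
#' @return One-row `mr_result` tibble.
#' @export
mr_wald <- function(h, second_order = FALSE) {
  check_h(h, 1, "wald_ratio")
  h <- h[1, ]
  if (h$bx == 0) {
    abort("wald ratio undefined for bx = 0", class = "phewasmr_domain_error")
  }
  beta <- h$by / h$bx
  v <- h$sy^2 / h$bx^2
  if (second_order) v <- v + h$by^2 * h$sx^2 / h$bx^4
  m <- h_meta(h)
  mr_result_row("wald", beta, sqrt(v), 1L, exposure = m$exposure)
}

#' Cochran's Q heterogeneity statistic
#'
#' \eqn{Q = \sum_j (by_j - \beta\, bx_j)^2 / sy_j^2} with \eqn{J - 1} degrees
#' of freedom and an upper-tail chi-square p-value. Large Q signals
#' heterogeneity across instruments, a symptom of horizontal pleiotropy.
#'
#' @param h Harmonized data (>= 2 SNPs).
#' @param beta Causal estimate the residuals are measured around (typically
#'   the IVW estimate).
#' @return A list with `q_stat`, `q_df`, `q_pvalue`.
#' @export
cochran_q <- function(h, beta) {
  check_h(h, 2, "cochran_q")
  q <- sum((h$by - beta * h$bx)^2 / h$sy^2)
  df <- nrow(h) - 1L
  list(q_stat = q, q_df = df, q_pvalue = pchisq(q, df, lower.tail = FALSE))
}

#' Inverse-variance-weighted MR estimate
#'
#' Weighted regression of outcome effects on exposure effects through the
#' origin with weights \eqn{1/sy^2}:
#' \deqn{\hat\theta = \frac{\sum bx_j by_j / sy_j^2}{\sum bx_j^2 / sy_j^2},}
#' equivalently the inverse-variance-weighted average of per-SNP Wald ratios.
#' The reported standard error follows the multiplicative random-effects
#' model: the fixed-effect SE is inflated by
#' \eqn{\max(1, \sqrt{Q/(J-1)})}, so heterogeneity widens, and never narrows,
#' the interval. With a single SNP the function falls back to [mr_wald()]
#' with a note.
#'
#' @param h Harmonized data.
#' @return One-row `mr_result` tibble with heterogeneity diagnostics.
#' @export
mr_ivw <- function(h) {
  check_h(h, 1, "ivw")
  if (nrow(h) < 2) {
    inform("ivw: single SNP; falling back to the Wald ratio")
    res <- mr_wald(h)
    res$note <- "single-SNP fallback to wald"
    return(res)
  }
  w <- 1 / h$sy^2
  sxx <- sum(w * h$bx^2)
  beta <- sum(w * h$bx * h$by) / sxx
  se_fe <- sqrt(1 / sxx)
  qq <- cochran_q(h, beta)
  se <- se_fe * max(1, sqrt(qq$q_stat / qq$q_df))
  m <- h_meta(h)
  mr_result_row("ivw", beta, se, nrow(h),
                q_stat = qq$q_stat, q_df = qq$q_df, q_pvalue = qq$q_pvalue,
                exposure = m$exposure)
}

#' Weighted-median MR estimate
#'
#' The median of the precision-weighted empirical distribution of per-SNP
#' Wald ratios; consistent when instruments carrying more than half of the
#' weight are valid. Weights are the first-order inverse variances of the
#' ratio estimates, \eqn{w_j \propto (bx_j / sy_j)^2}, normalized to sum 1.
#' With ratios sorted ascending and cumulative midpoints
#' \eqn{s_j = \sum_{k \le j} w_k - w_j / 2}, the estimate interpolates the
#' sorted ratios linearly in \eqn{s} at 0.5. The standard error comes from a
#' parametric bootstrap that redraws `bx` and `by` from their sampling
#' distributions.
#'
#' @param h Harmonized data (>= 3 SNPs).
#' @param n_boot Bootstrap replicates for the SE (default 1000).
#' @param seed Optional integer seed for the bootstrap; with `NULL` the
#'   current RNG state is used.
#' @return One-row `mr_result` tibble.
#' @export
mr_weighted_median <- function(h, n_boot = 1000, seed = NULL) {
  check_h(h, 3, "weighted_median")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  est <- weighted_median_point(h$bx, h$by, h$sy)
  J <- nrow(h)
  boots <- vapply(seq_len(n_boot), function(b) {
    bx_b <- rnorm(J, h$bx, h$sx)
    by_b <- rnorm(J, h$by, h$sy)
    weighted_median_point(bx_b, by_b, h$sy)
  }, numeric(1))
  m <- h_meta(h)
  mr_result_row("wm", est, stats::sd(boots), J, exposure = m$exposure)
}

# point estimate: interpolated weighted median of ratio estimates
weighted_median_point <- function(bx, by, sy) {
  theta <- by / bx
  w <- (bx / sy)^2
  w <- w / sum(w)
  o <- order(theta)
  theta <- theta[o]; w <- w[o]
  s <- cumsum(w) - w / 2
  if (s[1] >= 0.5) return(theta[1])
  if (s[length(s)] <= 0.5) return(theta[length(theta)])
  k <- max(which(s < 0.5))
  theta[k] + (theta[k + 1] - theta[k]) * (0.5 - s[k]) / (s[k + 1] - s[k])
}

#' MR-Egger regression
#'
#' Weighted regression of outcome effects on exposure effects with a free
#' intercept, after reorienting SNPs so all exposure effects are
#' nonnegative. The slope is a pleiotropy-robust causal estimate; a nonzero
#' intercept indicates unbalanced horizontal pleiotropy (the intercept test).
#' Both standard errors carry the multiplicative random-effects inflation
#' \eqn{\max(1, \sqrt{Q_E/(J-2)})}, where \eqn{Q_E} is the weighted residual
#' sum of squares.
#'
#' @param h Harmonized data (>= 3 SNPs).
#' @return One-row `mr_result` tibble with `egger_intercept` fields.
#' @export
mr_egger <- function(h) {
  check_h(h, 3, "mr_egger")
  flip <- sign(h$bx)
  flip[flip == 0] <- 1
  bx <- h$bx * flip
  by <- h$by * flip
  w <- 1 / h$sy^2
  fit <- wls_fit(cbind(intercept = 1, bx = bx), by, w)
  if (is.na(fit$beta[2])) {
    abort("mr_egger: exposure effects have no spread (collinear)",
          class = "phewasmr_domain_error")
  }
  J <- nrow(h)
  q_e <- fit$rss
  scale <- max(1, sqrt(q_e / (J - 2)))
  se <- fit$se * scale
  m <- h_meta(h)
  mr_result_row("egger", fit$beta[2], se[2], J,
                q_stat = q_e, q_df = J - 2L,
                q_pvalue = pchisq(q_e, J - 2, lower.tail = FALSE),
                egger_intercept = unname(fit$beta[1]),
                egger_intercept_se = unname(se[1]),
                egger_intercept_p = unname(2 * pnorm(-abs(fit$beta[1] / se[1]))),
                exposure = m$exposure)
}

# weighted least squares via the normal equations; se from (X'WX)^{-1}
wls_fit <- function(X, y, w) {
  sw <- sqrt(w)
  qr_fit <- lm.fit(X * sw, y * sw)
  if (qr_fit$rank < ncol(X)) {
    return(list(beta = rep(NA_real_, ncol(X)), se = rep(NA_real_, ncol(X)),
                rss = NA_real_, rank = qr_fit$rank))
  }
  XtWX_inv <- chol2inv(qr.R(qr_fit$qr))
  resid <- y - drop(X %*% qr_fit$coefficients)
  list(beta = qr_fit$coefficients,
       se = sqrt(diag(XtWX_inv)),
       rss = sum(w * resid^2),
       rank = qr_fit$rank)
}

#' I-squared statistic for the NO-Measurement-Error assumption
#'
#' Quantifies how much measurement error in the SNP-exposure effects would
#' attenuate MR-Egger: \eqn{I^2_{GX} = \max(0, (Q_{GX} - (J-1))/Q_{GX})} with
#' \eqn{Q_{GX}} the 1/\eqn{sx^2}-weighted heterogeneity of the (reoriented)
#' exposure effects around their weighted mean. Values above 0.9 are taken to
#' mean attenuation is negligible; lower values call for SIMEX correction.
#'
#' @param h Harmonized data (>= 2 SNPs).
#' @param weights `"exposure_se"` (default) weights by `1/sx^2`;
#'   `"outcome_se"` uses the alternative `bx/sy`-based effective weights.
#' @return A fraction in `[0, 1]`.
#' @export
i2_gx <- function(h, weights = c("exposure_se", "outcome_se")) {
  check_h(h, 2, "i2_gx")
  weights <- match.arg(weights)
  bx <- abs(h$bx)
  # weighted mean of the reoriented exposure effects; the alternative variant
  # centres on the Egger-regression (outcome-SE) weighted mean instead
  wm <- if (weights == "exposure_se") 1 / h$sx^2 else 1 / h$sy^2
  bbar <- sum(wm * bx) / sum(wm)
  q_gx <- sum((bx - bbar)^2 / h$sx^2)
  if (q_gx == 0) {
    warn("i2_gx: zero heterogeneity in exposure effects; returning 0")
    return(0)
  }
  max(0, (q_gx - (nrow(h) - 1)) / q_gx)
}

#' SIMEX-corrected MR-Egger slope
#'
#' Simulation-extrapolation correction for the attenuation of the MR-Egger
#' slope under exposure-effect measurement error. For each multiplier
#' \eqn{\lambda} in `lambdas`, `n_sim` perturbed data sets are created by
#' adding `Normal(0, lambda * sx^2)` noise to the exposure effects; the mean
#' Egger slope per \eqn{\lambda} is fitted with a quadratic in \eqn{\lambda}
#' and extrapolated to \eqn{\lambda = -1} (the no-measurement-error limit).
#' The standard error is a jackknife over simulation replicates.
#'
#' @param h Harmonized data (>= 3 SNPs).
#' @param lambdas Noise-multiplier grid (default `c(0, 0.5, 1, 1.5, 2)`).
#' @param n_sim Simulation replicates per lambda (default 1000).
#' @param seed Optional integer seed.
#' @return One-row `mr_result` tibble (`method = "egger_simex"`).
#' @export
mr_simex_egger <- function(h, lambdas = c(0, 0.5, 1, 1.5, 2),
                           n_sim = 1000, seed = NULL) {
  check_h(h, 3, "simex_egger")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  J <- nrow(h)
  # orientation is fixed once from the observed exposure effects; perturbed
  # replicates are not re-oriented (re-flipping would bend the lambda profile)
  flip <- sign(h$bx); flip[flip == 0] <- 1
  bx0 <- h$bx * flip; by0 <- h$by * flip
  w <- 1 / h$sy^2
  wls_slope <- function(bxp) {
    mx <- sum(w * bxp) / sum(w); my <- sum(w * by0) / sum(w)
    sum(w * (bxp - mx) * (by0 - my)) / sum(w * (bxp - mx)^2)
  }
  naive <- wls_slope(bx0)
  slopes <- matrix(NA_real_, nrow = n_sim, ncol = length(lambdas))
  for (l in seq_along(lambdas)) {
    lam <- lambdas[l]
    if (lam == 0 || all(h$sx == 0)) {
      slopes[, l] <- naive
      next
    }
    noise_sd <- sqrt(lam) * h$sx
    for (b in seq_len(n_sim)) {
      slopes[b, l] <- wls_slope(bx0 + rnorm(J, 0, noise_sd))
    }
  }
  # quadratic extrapolation is linear in the per-lambda means:
  # est = a' m, with a from the polynomial design
  X <- cbind(1, lambdas, lambdas^2)
  a <- drop(c(1, -1, 1) %*% solve(crossprod(X), t(X)))
  means <- colMeans(slopes, na.rm = TRUE)
  est <- drop(a %*% means)
  # jackknife over replicates
  B <- n_sim
  loo <- vapply(seq_len(B), function(b) {
    m_b <- (B * means - slopes[b, ]) / (B - 1)
    drop(a %*% m_b)
  }, numeric(1))
  se <- sqrt((B - 1) / B * sum((loo - mean(loo))^2))
  if (all(h$sx == 0)) se <- mr_egger(h)$se
  m <- h_meta(h)
  mr_result_row("egger_simex", est, se, J, exposure = m$exposure)
}

#' Multivariable MR by weighted regression
#'
#' Estimates the direct causal effect of each of K exposures on a shared
#' outcome from the pooled instruments of all exposures: weighted least
#' squares of the per-SNP outcome effects on the K columns of per-SNP
#' exposure effects, without an intercept, weighted by the inverse variance
#' of the outcome effects. Each slope is the effect of its exposure
#' conditioning on the others.
#'
#' @param bx_matrix Numeric matrix (SNPs x exposures) of exposure effects,
#'   with exposure names as column names.
#' @param by,sy Per-SNP effects on the shared outcome and their SEs.
#' @param intercept Include an intercept (default FALSE, the standard
#'   multivariable-MR convention; TRUE mirrors an R formula with intercept).
#' @param weights `"inverse_variance"` (default, `1/sy^2`) or `"inverse_se"`
#'   (a literal `1/sy`, provided for sensitivity analysis).
#' @return `mr_result` tibble with one row per exposure (`method = "mvmr"`),
#'   the exposure name in `exposure`.
#' @export
mr_mvmr <- function(bx_matrix, by, sy, intercept = FALSE,
                    weights = c("inverse_variance", "inverse_se")) {
  weights <- match.arg(weights)
  bx_matrix <- as.matrix(bx_matrix)
  K <- ncol(bx_matrix)
  J <- nrow(bx_matrix)
  if (is.null(colnames(bx_matrix))) {
    colnames(bx_matrix) <- paste0("exposure", seq_len(K))
  }
  stopifnot(length(by) == J, length(sy) == J)
  if (any(sy <= 0)) {
    abort("sy must be positive", class = "phewasmr_validation_error")
  }
  if (J < K + 1) {
    abort(sprintf("multivariable MR needs at least K+1 = %d SNPs (got %d)",
                  K + 1, J),
          class = "phewasmr_validation_error")
  }
  X <- if (intercept) cbind(`(Intercept)` = 1, bx_matrix) else bx_matrix
  if (qr(X)$rank < ncol(X)) {
    abort(paste0("collinear exposure effects among: ",
                 paste(colnames(bx_matrix), collapse = ", ")),
          class = "phewasmr_domain_error")
  }
  w <- if (weights == "inverse_variance") 1 / sy^2 else 1 / sy
  fit <- wls_fit(X, by, w)
  keep <- if (intercept) -1 else seq_len(ncol(X))
  betas <- fit$beta[keep]
  ses <- fit$se[keep]
  res <- purrr::map2(seq_along(betas), colnames(bx_matrix), function(k, nm) {
    mr_result_row("mvmr", betas[k], ses[k], J, exposure = nm)
  })
  dplyr::bind_rows(res)
}

#' Leave-one-out sensitivity analysis
#'
#' Refits the IVW estimate omitting one SNP at a time (falling back to the
#' Wald ratio when a single SNP remains), to check that no single instrument
#' drives the result.
#'
#' @param h Harmonized data (>= 3 SNPs recommended; >= 2 accepted).
#' @return `mr_result` tibble with one row per omitted SNP and a
#'   `snp_omitted` column.
#' @export
mr_leave_one_out <- function(h) {
  check_h(h, 2, "leave_one_out")
  res <- purrr::map(seq_len(nrow(h)), function(j) {
    r <- suppressMessages(mr_ivw(h[-j, , drop = FALSE]))
    r$snp_omitted <- if ("snp" %in% names(h)) h$snp[j] else as.character(j)
    r
  })
  dplyr::bind_rows(res)
}

#' Rescale a causal estimate to one SD of the exposure
#'
#' Multiplies the causal log-odds (or slope), its SE and CI bounds by
#' `exposure_sd`, re-exponentiating the odds-ratio fields, so estimates are
#' expressed per SD increment of the exposure.
#'
#' @param result An `mr_result` tibble.
#' @param exposure_sd Positive scalar SD of the exposure.
#' @return The rescaled `mr_result`.
#' @export
scale_per_sd <- function(result, exposure_sd) {
  if (!is.numeric(exposure_sd) || length(exposure_sd) != 1 ||
      !is.finite(exposure_sd) || exposure_sd <= 0) {
    abort("exposure_sd must be a positive scalar",
          class = "phewasmr_domain_error")
  }
  for (col in c("beta", "se", "ci_low", "ci_high",
                "egger_intercept", "egger_intercept_se")) {
    if (col %in% names(result)) result[[col]] <- result[[col]] * exposure_sd
  }
  result$or <- exp(result$beta)
  result$or_ci_low <- exp(result$ci_low)
  result$or_ci_high <- exp(result$ci_high)
  result
}

#' Flag instruments with known secondary-phenotype associations
#'
#' Local stand-in for a GWAS-catalog / PhenoScanner lookup: scans a
#' user-supplied association catalog for genome-wide-significant secondary
#' traits of the instrument SNPs, which are then candidates for
#' exclusion-sensitivity reruns.
#'
#' @param snp_ids Character vector of SNP ids.
#' @param catalog Data frame (or path to a delimited file) with columns
#'   `snp`, `trait`, `pvalue`. `NULL` skips the lookup with a warning.
#' @param p_threshold Significance threshold (default `5e-8`).
#' @return Tibble of flagged `snp`, `trait`, `pvalue` rows (zero rows if none).
#' @export
pleiotropy_lookup <- function(snp_ids, catalog, p_threshold = 5e-8) {
  if (is.null(catalog)) {
    warn("no pleiotropy catalog supplied; lookup skipped")
    return(tibble(snp = character(), trait = character(),
                  pvalue = numeric()))
  }
  if (is.character(catalog) && length(catalog) == 1) {
    catalog <- readr::read_tsv(catalog, show_col_types = FALSE,
                               progress = FALSE)
  }
  catalog <- as_tibble(catalog)
  stopifnot(all(c("snp", "trait", "pvalue") %in% names(catalog)))
  dplyr::filter(catalog, .data$snp %in% snp_ids,
                .data$pvalue < p_threshold)
}

#' Run a set of MR estimators on harmonized data
#'
#' @param h Harmonized data.
#' @param methods Subset of `c("ivw", "wm", "egger")`.
#' @param n_boot,seed Passed to [mr_weighted_median()].
#' @return `mr_result` tibble, one row per method that is defined for the
#'   number of SNPs available.
#' @export
mr_estimate <- function(h, methods = c("ivw", "wm", "egger"),
                        n_boot = 1000, seed = NULL) {
  methods <- match.arg(methods, several.ok = TRUE)
  out <- list()
  if ("ivw" %in% methods) out$ivw <- mr_ivw(h)
  if ("wm" %in% methods && nrow(h) >= 3) {
    out$wm <- mr_weighted_median(h, n_boot = n_boot, seed = seed)
  }
  if ("egger" %in% methods && nrow(h) >= 3) out$egger <- mr_egger(h)
  dplyr::bind_rows(out)
}
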