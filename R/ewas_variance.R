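#' Per-dataset variance EWAS (Breusch-Pagan heteroscedasticity test)
#'
#' For every CpG: (1) fit the same first-stage OLS of M-values on age and
#' covariates as the mean EWAS and extract residuals; (2) screen the
#' residuals with a Shapiro-Wilk normality test — CpGs whose residuals
#' strongly deviate from normality (typically uncorrected SNP-driven
#' multimodality) are flagged and excluded from testing; (3) regress the
#' squared residuals on age (the auxiliary regression); (4) the Lagrange
#' multiplier statistic is \code{n * R^2} of the auxiliary regression,
#' referred to the upper tail of a chi-square with 1 degree of freedom. The
#' sign of the auxiliary slope gives the direction of the variance change,
#' which the sample-size-weighted meta-analysis uses. The \code{n * R^2}
#' (studentized) form is robust to non-normal residual kurtosis, which
#' matters for bounded methylation data.
#'
#' An auxiliary regression of squared beta-scale residuals on age is fitted
#' in parallel to express the variance slope in methylation-fraction-squared
#' units per year, the scale on which variance changes are reported.
#'
#' @param ds A gated, filtered [methyl_dataset()].
#' @param covariates Character vector of covariate columns (as in
#'   [fit_mean_ewas()]).
#' @param shapiro_p Shapiro-Wilk p-value below which a CpG is flagged as
#'   non-normal and not tested (default 1e-5).
#' @return data.frame with one row per CpG: \code{cpg}, \code{bp_stat},
#'   \code{var_slope} (M-scale auxiliary slope), \code{var_slope_beta}
#'   (fraction^2 per year), \code{direction} (-1/0/+1), \code{p},
#'   \code{log_p} (natural log, carried so extreme significance does not
#'   underflow), \code{shapiro_p}, \code{n}, \code{filtered}. Flagged CpGs
#'   carry NA statistics.
#' @export
fit_variance_ewas <- function(ds, covariates = character(),
                              shapiro_p = 1e-5) {
  stopifnot(inherits(ds, "methyl_dataset"))
  n <- ncol(ds$beta)
  if (n < 10) stop("need at least 10 samples for the variance EWAS")
  X <- .build_design(ds, covariates)
  M <- beta_to_m(clip_beta(ds$beta))
  fm <- .rowwise_ols(X, M, "age")
  fb <- .rowwise_ols(X, ds$beta, "age")
  res <- fm$residuals            # samples x CpGs
  age <- ds$sample_meta$age

  # Shapiro-Wilk screen (stats::shapiro.test caps at 5000 observations;
  # larger cohorts are screened on their first 5000 samples)
  idx <- if (n > 5000) seq_len(5000) else seq_len(n)
  sw <- apply(res[idx, , drop = FALSE], 2, function(r) {
    if (stats::sd(r) == 0) return(0)  # degenerate: flag
    stats::shapiro.test(r)$p.value
  })
  filtered <- sw < shapiro_p

  Z <- cbind(`(Intercept)` = 1, age = age)
  qrZ <- qr(Z)
  e2 <- res^2
  aux_coef <- qr.coef(qrZ, e2)["age", ]
  rss <- colSums(qr.resid(qrZ, e2)^2)
  tss <- colSums(scale(e2, scale = FALSE)^2)
  r2 <- ifelse(tss > 0, 1 - rss / tss, 0)
  bp <- n * r2
  log_p <- stats::pchisq(bp, df = 1, lower.tail = FALSE, log.p = TRUE)
  aux_beta <- qr.coef(qrZ, fb$residuals^2)["age", ]

  zero_var <- fm$sigma2 < 1e-20 | tss <= 0
  filtered <- filtered | zero_var
  out <- data.frame(cpg = rownames(ds$beta),
                    bp_stat = bp, var_slope = aux_coef,
                    var_slope_beta = aux_beta,
                    direction = sign(aux_coef),
                    p = exp(log_p), log_p = log_p,
                    shapiro_p = sw, n = n, filtered = filtered,
                    row.names = NULL, stringsAsFactors = FALSE)
  out$filter_reason <- ifelse(zero_var, "zero residual variance",
                              ifelse(filtered, "non-normal residuals", ""))
  for (col in c("bp_stat", "var_slope", "var_slope_beta", "direction",
                "p", "log_p"))
    out[[col]][filtered] <- NA
  out
}
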