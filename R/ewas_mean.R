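# shared design-matrix builder for the per-dataset regressions
.build_design <- function(ds, covariates, require_age = TRUE) {
  sm <- ds$sample_meta
  miss <- setdiff(covariates, names(sm))
  if (length(miss))
    stop("covariates absent from sample metadata: ",
         paste(miss, collapse = ", "))
  terms <- c(if (require_age) "age", covariates)
  fml <- stats::reformulate(if (length(terms)) terms else "1")
  X <- stats::model.matrix(fml, data = sm)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  if (nrow(X) <= ncol(X) + 2)
    stop("too few samples (n = ", nrow(X), ") for ", ncol(X), " coefficients")
  X
}

# OLS of every CpG (rows of y_mat) on X; returns per-CpG coefficient of
# `term`, its unit (sigma = 1) standard error, residual variances and the
# residual matrix
.rowwise_ols <- function(X, y_mat, term) {
  qrX <- qr(X)
  Y <- t(y_mat)
  coefs <- qr.coef(qrX, Y)
  res <- qr.resid(qrX, Y)
  df <- nrow(X) - ncol(X)
  sigma2 <- colSums(res^2) / df
  v_unit <- chol2inv(qr.R(qrX))[match(term, colnames(X)),
                                match(term, colnames(X))]
  list(coef = coefs[term, ], sigma2 = sigma2, se_unit = sqrt(v_unit),
       residuals = res, df = df)
}

#' Per-dataset mean-methylation EWAS
#'
#' Fits, CpG by CpG, an ordinary least-squares model of the M-value on age
#' and the requested covariates; inference uses empirical-Bayes moderated
#' t-statistics (residual variances shrunk toward a common prior estimated by
#' the method of moments, as in limma). A parallel OLS on the beta values
#' with the same design provides the effect size in methylation-fraction
#' units per year of age, which is how effects are conventionally reported;
#' the M-value fit drives inference.
#'
#' @param ds A gated, filtered [methyl_dataset()].
#' @param covariates Character vector of sample-metadata columns to adjust
#'   for (e.g. \code{c("sex", "batch", "bmi")}).
#' @param moderate Apply empirical-Bayes variance moderation (default TRUE).
#' @return data.frame with one row per CpG: \code{cpg}, \code{effect_m}
#'   (M-units per year), \code{se_m}, \code{t} (moderated when enabled),
#'   \code{p}, \code{effect_beta} (fraction per year), \code{se_beta},
#'   \code{effect_beta_pct_per_year}, \code{n}, \code{df_residual}.
#' @export
fit_mean_ewas <- function(ds, covariates = character(), moderate = TRUE) {
  stopifnot(inherits(ds, "methyl_dataset"))
  X <- .build_design(ds, covariates)
  M <- beta_to_m(clip_beta(ds$beta))
  fm <- .rowwise_ols(X, M, "age")
  fb <- .rowwise_ols(X, ds$beta, "age")
  if (moderate) {
    sq <- limma::squeezeVar(fm$sigma2, fm$df)
    se <- fm$se_unit * sqrt(sq$var.post)
    df_t <- fm$df + sq$df.prior
  } else {
    se <- fm$se_unit * sqrt(fm$sigma2)
    df_t <- fm$df
  }
  tt <- fm$coef / se
  p <- 2 * stats::pt(abs(tt), df = df_t, lower.tail = FALSE)
  data.frame(cpg = rownames(ds$beta),
             effect_m = fm$coef, se_m = se, t = tt, p = p,
             effect_beta = fb$coef,
             se_beta = fb$se_unit * sqrt(fb$sigma2),
             effect_beta_pct_per_year = 100 * fb$coef,
             n = nrow(X), df_residual = fm$df,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Estimate an empirical null from a vector of z-scores
#'
#' Under sparse signal, the central mass of the z-score distribution reflects
#' the null: its location estimates systematic bias, its robust scale
#' (median absolute deviation, normal-consistent) estimates inflation from
#' unmodelled confounding or correlation.
#'
#' @param z Numeric vector of z-scores.
#' @return Named numeric vector \code{c(bias, inflation)}.
#' @export
estimate_empirical_null <- function(z) {
  bias <- stats::median(z)
  inflation <- stats::mad(z)  # 1.4826 * median |z - median(z)|
  if (!is.finite(inflation) || inflation <= 0)
    stop("estimated inflation is not positive; degenerate z-scores")
  c(bias = bias, inflation = inflation)
}

#' Bias/inflation correction of EWAS summary statistics
#'
#' Re-centers and re-scales per-CpG association statistics by the empirical
#' null: \code{z' = (z - bias)/inflation}, with the standard error inflated
#' (\code{se' = se * inflation}) and the effect re-centered
#' (\code{effect' = effect - bias * se}) so that \code{effect'/se' = z'}.
#' P-values are recomputed from the adjusted z-scores. Adjusted statistics
#' are invariant to a constant shift of all input z-scores.
#'
#' @param records An EWAS result data.frame (see [fit_mean_ewas()]).
#' @param effect_col,se_col Names of the effect and standard-error columns to
#'   adjust (defaults \code{"effect_m"}, \code{"se_m"}).
#' @return \code{records} with the effect/se columns adjusted, \code{t} and
#'   \code{p} replaced by the adjusted z and its two-sided normal p-value,
#'   and attributes \code{bias} and \code{inflation}.
#' @export
empirical_null_adjust <- function(records, effect_col = "effect_m",
                                  se_col = "se_m") {
  if (nrow(records) < 100)
    stop("need at least 100 records to estimate the empirical null")
  z <- records[[effect_col]] / records[[se_col]]
  null <- estimate_empirical_null(z)
  z_adj <- (z - null["bias"]) / null["inflation"]
  records[[effect_col]] <- records[[effect_col]] - null["bias"] * records[[se_col]]
  records[[se_col]] <- records[[se_col]] * null["inflation"]
  records$t <- z_adj
  records$p <- 2 * stats::pnorm(abs(z_adj), lower.tail = FALSE)
  attr(records, "bias") <- unname(null["bias"])
  attr(records, "inflation") <- unname(null["inflation"])
  records
}
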