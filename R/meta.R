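#' Inverse-variance fixed-effects meta-analysis
#'
#' Pools per-dataset effect estimates with weights \code{w_i = 1/se_i^2}:
#' pooled effect \code{sum(w e)/sum(w)}, pooled SE \code{1/sqrt(sum(w))},
#' z = pooled/SE, two-sided p. Heterogeneity is summarized by Cochran's
#' \code{Q = sum(w (e - pooled)^2)} and \code{I2 = max(0, (Q-(k-1))/Q)*100}.
#' With a single study the pooled result is that study and I2 is reported as
#' 0 with \code{k1 = TRUE}.
#'
#' @param effect Numeric vector of per-dataset effects.
#' @param se Matching positive standard errors.
#' @return One-row data.frame: \code{pooled_effect}, \code{pooled_se},
#'   \code{z}, \code{p}, \code{log_p} (natural log), \code{k}, \code{Q},
#'   \code{I2}, \code{k1}.
#' @export
meta_inverse_variance <- function(effect, se) {
  if (length(effect) != length(se) || length(effect) < 1)
    stop("effect and se must be non-empty vectors of equal length")
  if (any(se <= 0)) stop("all standard errors must be positive")
  w <- 1 / se^2
  pooled <- sum(w * effect) / sum(w)
  pooled_se <- 1 / sqrt(sum(w))
  z <- pooled / pooled_se
  log_p <- stats::pnorm(abs(z), lower.tail = FALSE, log.p = TRUE) + log(2)
  k <- length(effect)
  Q <- sum(w * (effect - pooled)^2)
  I2 <- if (k > 1 && Q > 0) max(0, (Q - (k - 1)) / Q) * 100 else 0
  data.frame(pooled_effect = pooled, pooled_se = pooled_se, z = z,
             p = exp(log_p), log_p = log_p, k = k, Q = Q, I2 = I2,
             k1 = k == 1)
}

#' Sample-size-weighted (Stouffer) fixed-effects meta-analysis
#'
#' Converts each dataset's two-sided p-value into a signed z-score,
#' \code{z_i = sign_i * qnorm(1 - p_i/2)}, and combines them weighted by the
#' square root of the sample size:
#' \code{Z = sum(sqrt(n_i) z_i) / sqrt(sum(n_i))}. This is the pooling used
#' for test statistics (such as the Breusch-Pagan LM statistic) that have no
#' effect/SE decomposition. Log p-values are carried throughout, so extreme
#' significance does not truncate at the double-precision floor.
#'
#' @param p Per-dataset two-sided p-values, or NA where \code{log_p} is given.
#' @param direction Per-dataset direction of effect (-1 or +1; 0 excluded
#'   upstream).
#' @param n Per-dataset sample sizes.
#' @param log_p Optional natural-log p-values used in preference to \code{p}.
#' @return One-row data.frame: \code{z}, \code{p}, \code{log_p}, \code{k},
#'   \code{n_total}.
#' @export
meta_sample_size <- function(p, direction, n, log_p = NULL) {
  k <- length(direction)
  if (k < 1) stop("need at least one study")
  if (is.null(log_p)) {
    if (any(p == 0)) {
      warning("p = 0 clamped to the smallest representable positive value")
      p <- pmax(p, .Machine$double.xmin)
    }
    log_p <- log(p)
  }
  if (any(direction == 0))
    stop("directions must be nonzero for signed pooling")
  z_i <- sign(direction) * stats::qnorm(log_p - log(2), lower.tail = FALSE,
                                        log.p = TRUE)
  z <- sum(sqrt(n) * z_i) / sqrt(sum(n))
  lp <- stats::pnorm(abs(z), lower.tail = FALSE, log.p = TRUE) + log(2)
  data.frame(z = z, p = exp(lp), log_p = lp, k = k, n_total = sum(n))
}

#' Minimum-presence rules for meta-analyzed CpGs
#'
#' A CpG enters the mean-methylation meta-analysis only if it is present in
#' at least \code{min_datasets} datasets; it enters the variance
#' meta-analysis only if its contributing datasets together cover at least
#' \code{min_sample_frac} of all pooled samples.
#'
#' @param k Number of datasets the CpG is present in.
#' @param n_contrib Total samples in those datasets.
#' @param n_total Total samples across all datasets.
#' @param mode \code{"mean"} or \code{"variance"}.
#' @param min_datasets Dataset-count rule for the mean mode (default 3).
#' @param min_sample_frac Sample-coverage rule for the variance mode
#'   (default 0.15).
#' @return Logical.
#' @export
presence_filter <- function(k, n_contrib, n_total,
                            mode = c("mean", "variance"),
                            min_datasets = 3, min_sample_frac = 0.15) {
  mode <- match.arg(mode)
  if (mode == "mean") k >= min_datasets
  else n_contrib >= min_sample_frac * n_total
}

#' Benjamini-Hochberg q-values and significance calls
#'
#' @param p P-values in (0, 1].
#' @param q Q-values.
#' @param threshold FDR threshold (default 0.005).
#' @return \code{bh_fdr}: step-up q-values; \code{call_significant}: logical.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  stats::p.adjust(p, method = "BH")
}

#' @rdname bh_fdr
#' @export
call_significant <- function(q, threshold = 0.005) {
  !is.na(q) & q < threshold
}

# stack per-dataset EWAS tables into one long frame keyed by cpg
.stack_records <- function(records_list, cols) {
  do.call(rbind, lapply(seq_along(records_list), function(i) {
    r <- records_list[[i]][, c("cpg", cols)]
    r$dataset <- names(records_list)[i] %||% as.character(i)
    r
  }))
}

#' Meta-analyze per-dataset mean EWAS results across cohorts
#'
#' Runs the inverse-variance pooling per CpG, separately on the M-scale
#' summaries (which drive z, p and FDR) and on the beta-scale summaries
#' (which give the reported effect in fraction-per-year units). CpGs present
#' in fewer than \code{min_datasets} cohorts are dropped.
#'
#' @param records_list Named list of [fit_mean_ewas()] data.frames (possibly
#'   bias/inflation-adjusted with [empirical_null_adjust()]).
#' @param min_datasets Presence rule (default 3; use 1 to keep everything).
#' @return data.frame keyed by \code{cpg}: \code{k}, pooled M-scale effect,
#'   SE, \code{z}, \code{p}, \code{q}, \code{Q}, \code{I2}, and pooled
#'   beta-scale \code{pooled_effect_beta}, \code{pooled_se_beta},
#'   \code{pooled_effect_beta_pct} (percent methylation per year).
#' @export
meta_ewas_mean <- function(records_list, min_datasets = 3) {
  long <- .stack_records(records_list,
                         c("effect_m", "se_m", "effect_beta", "se_beta"))
  f <- factor(long$cpg)
  k <- as.vector(table(f))
  w <- 1 / long$se_m^2
  sw <- as.vector(rowsum(w, f))
  swe <- as.vector(rowsum(w * long$effect_m, f))
  pooled <- swe / sw
  pooled_se <- 1 / sqrt(sw)
  Q <- as.vector(rowsum(w * long$effect_m^2, f)) - swe^2 / sw
  I2 <- ifelse(k > 1 & Q > 0, pmax(0, (Q - (k - 1)) / Q) * 100, 0)
  wb <- 1 / long$se_beta^2
  swb <- as.vector(rowsum(wb, f))
  pooled_b <- as.vector(rowsum(wb * long$effect_beta, f)) / swb
  z <- pooled / pooled_se
  log_p <- stats::pnorm(abs(z), lower.tail = FALSE, log.p = TRUE) + log(2)
  out <- data.frame(cpg = levels(f), k = k,
                    pooled_effect = pooled, pooled_se = pooled_se,
                    z = z, p = exp(log_p), log_p = log_p,
                    Q = Q, I2 = I2,
                    pooled_effect_beta = pooled_b,
                    pooled_se_beta = 1 / sqrt(swb),
                    pooled_effect_beta_pct = 100 * pooled_b,
                    stringsAsFactors = FALSE)
  out <- out[out$k >= min_datasets, , drop = FALSE]
  out$q <- bh_fdr(out$p)
  rownames(out) <- NULL
  out
}

#' Meta-analyze per-dataset variance EWAS results across cohorts
#'
#' Pools the signed Breusch-Pagan evidence per CpG with the
#' sample-size-weighted z method. Shapiro-flagged records and zero-direction
#' records are excluded before pooling; CpGs whose contributing datasets
#' cover less than \code{min_sample_frac} of all pooled samples are dropped.
#' A sample-size-weighted mean of the beta-scale variance slopes is reported
#' as the descriptive effect size.
#'
#' @param records_list Named list of [fit_variance_ewas()] data.frames.
#' @param min_sample_frac Coverage rule (default 0.15).
#' @return data.frame keyed by \code{cpg}: \code{k}, \code{n_contrib},
#'   \code{z}, \code{p}, \code{q}, \code{var_slope_beta} (weighted mean,
#'   fraction^2 per year).
#' @export
meta_ewas_variance <- function(records_list, min_sample_frac = 0.15) {
  n_total <- sum(vapply(records_list, function(r) r$n[1], numeric(1)))
  long <- .stack_records(records_list,
                         c("log_p", "direction", "n", "var_slope_beta",
                           "filtered"))
  long <- long[!long$filtered & long$direction != 0, , drop = FALSE]
  if (!nrow(long)) stop("no testable records after filtering")
  f <- factor(long$cpg)
  k <- as.vector(table(f))
  n_contrib <- as.vector(rowsum(long$n, f))
  z_i <- sign(long$direction) *
    stats::qnorm(long$log_p - log(2), lower.tail = FALSE, log.p = TRUE)
  z <- as.vector(rowsum(sqrt(long$n) * z_i, f)) / sqrt(n_contrib)
  log_p <- stats::pnorm(abs(z), lower.tail = FALSE, log.p = TRUE) + log(2)
  vsb <- as.vector(rowsum(long$n * long$var_slope_beta, f)) / n_contrib
  out <- data.frame(cpg = levels(f), k = k, n_contrib = n_contrib,
                    z = z, p = exp(log_p), log_p = log_p,
                    var_slope_beta = vsb, stringsAsFactors = FALSE)
  keep <- presence_filter(out$k, out$n_contrib, n_total, mode = "variance",
                          min_sample_frac = min_sample_frac)
  out <- out[keep, , drop = FALSE]
  out$q <- bh_fdr(out$p)
  rownames(out) <- NULL
  out
}
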