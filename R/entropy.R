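#' Covariate-adjusted beta values
#'
#' Removes technical and biological covariate effects from a methylation
#' matrix while deliberately preserving the effect of age: for each CpG an
#' OLS model of the M-value on the covariates (never age) is fitted, the
#' CpG's mean M-value is added back to the residuals, and the result is
#' transformed back to the beta scale and clipped into the open unit
#' interval. With no covariates this reconstructs the input exactly.
#'
#' @param ds A [methyl_dataset()].
#' @param covariates Covariate columns to remove; must not contain
#'   \code{"age"}.
#' @return Adjusted beta matrix, CpGs x samples, values in
#'   \code{[1e-6, 1-1e-6]}.
#' @export
adjusted_betas <- function(ds, covariates = character()) {
  stopifnot(inherits(ds, "methyl_dataset"))
  if ("age" %in% covariates)
    stop("age must not be adjusted out before the entropy analysis")
  M <- beta_to_m(clip_beta(ds$beta))
  if (length(covariates) == 0)
    return(clip_beta(ds$beta))
  X <- .build_design(ds, covariates, require_age = FALSE)
  res <- qr.resid(qr(X), t(M))           # samples x CpGs
  adj_m <- t(res) + rowMeans(M)
  clip_beta(m_to_beta(adj_m))
}

#' Normalized Shannon entropy of a methylation profile
#'
#' The mean binary entropy of the per-CpG methylation fractions of one
#' sample:
#' \deqn{H = \frac{1}{N \log_2 \tfrac12}\sum_i
#'   \left[ MF_i \log_2 MF_i + (1 - MF_i)\log_2(1 - MF_i) \right]}
#' where the normalizing constant \eqn{N \log_2 \tfrac12 = -N} maps the sum
#' into \code{[0, 1]}. An entropy of 0 means every CpG is methylated at
#' exactly 0% or 100% (a fully predictable methylome); an entropy of 1 means
#' every CpG is methylated at exactly 50%. Terms at exactly 0 or 1 use the
#' \code{0 * log2(0) = 0} limit convention.
#'
#' @param mf Numeric vector of methylation fractions in \code{[0, 1]}.
#' @return Entropy value in \code{[0, 1]}.
#' @examples
#' shannon_entropy(rep(0.5, 100))   # 1
#' shannon_entropy(c(0, 1, 0, 1))   # 0
#' @export
shannon_entropy <- function(mf) {
  if (length(mf) < 1) stop("need at least one CpG")
  if (any(!is.finite(mf)) || any(mf < 0 | mf > 1))
    stop("methylation fractions must lie in [0, 1]")
  xlx <- function(x) ifelse(x > 0, x * log2(x), 0)
  h <- sum(xlx(mf) + xlx(1 - mf)) / (length(mf) * log2(0.5))
  h + 0  # normalize IEEE negative zero from the sign flip
}

# column-wise entropy of a beta matrix (one value per sample)
.entropy_per_sample <- function(beta) {
  xlx <- function(x) ifelse(x > 0, x * log2(x), 0)
  colSums(xlx(beta) + xlx(1 - beta)) / (nrow(beta) * log2(0.5))
}

#' Regression of per-sample entropy on age
#'
#' Fits \code{entropy ~ age} (plus optional additional covariates such as
#' cell-type fractions) by OLS and reports the slope per decade of age
#' (per-year coefficient times 10), its standard error and p-value. Constant
#' entropy yields a degenerate record (slope 0, se 0, flagged).
#'
#' @param entropy Per-sample entropy values.
#' @param age Matching ages in years.
#' @param covariates Optional data.frame of additional regressors (e.g.
#'   estimated cell fractions).
#' @return One-row data.frame: \code{slope_per_decade}, \code{se}, \code{p},
#'   \code{n}, \code{degenerate}.
#' @export
entropy_vs_age <- function(entropy, age, covariates = NULL) {
  n <- length(entropy)
  if (n < 10) stop("need at least 10 samples")
  if (stats::sd(entropy) == 0)
    return(data.frame(slope_per_decade = 0, se = 0, p = NA_real_, n = n,
                      degenerate = TRUE))
  df <- data.frame(entropy = entropy, age = age)
  if (!is.null(covariates)) df <- cbind(df, covariates)
  fit <- stats::lm(entropy ~ ., data = df)
  sm <- summary(fit)$coefficients
  data.frame(slope_per_decade = 10 * sm["age", "Estimate"],
             se = 10 * sm["age", "Std. Error"],
             p = sm["age", "Pr(>|t|)"], n = n, degenerate = FALSE)
}

#' Per-sample entropy over CpG subsets
#'
#' Computes, on covariate-adjusted betas, one entropy value per sample for
#' each named CpG subset (e.g. genome-wide, age-related, non-age-related,
#' homoscedastic DMPs, DMPs-VMPs, constant VMPs, entropic and anti-entropic
#' DMPs). Because the statistic is a mean over CpGs, the entropy of a union
#' of disjoint subsets is the size-weighted mean of their entropies.
#'
#' @param ds A [methyl_dataset()].
#' @param subsets Named list of CpG-id character vectors; each must be a
#'   non-empty subset of the dataset's CpGs.
#' @param covariates Covariates removed before computing entropy (never age).
#' @return data.frame: \code{sample_id}, \code{subset}, \code{n_cpgs},
#'   \code{entropy}.
#' @export
entropy_by_subset <- function(ds, subsets, covariates = character()) {
  stopifnot(inherits(ds, "methyl_dataset"), is.list(subsets))
  adj <- adjusted_betas(ds, covariates)
  out <- lapply(names(subsets), function(lab) {
    ids <- subsets[[lab]]
    if (length(ids) == 0) stop("empty CpG subset: ", lab)
    miss <- setdiff(ids, rownames(adj))
    if (length(miss))
      stop("subset '", lab, "' contains CpGs absent from the dataset")
    e <- .entropy_per_sample(adj[ids, , drop = FALSE])
    data.frame(sample_id = colnames(adj), subset = lab,
               n_cpgs = length(ids), entropy = e,
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Entropy-age association per cohort and its meta-analysis
#'
#' For each cohort, computes covariate-adjusted per-sample entropy on each
#' CpG subset, regresses it on age, and pools the per-decade slopes across
#' cohorts with the inverse-variance fixed-effects meta-analysis.
#'
#' @param datasets Named list of [methyl_dataset()] cohorts.
#' @param subsets Named list of CpG-id vectors (see [entropy_by_subset()]);
#'   subsets are intersected with each cohort's CpGs.
#' @param covariates Covariates to adjust betas for.
#' @param cell_fractions Optional named list (per cohort) of type-by-sample
#'   fraction matrices added as regressors to the entropy-age model.
#' @return list with \code{slopes} (per cohort x subset) and \code{meta}
#'   (per subset pooled slope with Q and I2).
#' @export
entropy_analysis <- function(datasets, subsets, covariates = character(),
                             cell_fractions = NULL) {
  slopes <- do.call(rbind, lapply(names(datasets), function(d) {
    ds <- datasets[[d]]
    subs <- lapply(subsets, intersect, rownames(ds$beta))
    subs <- subs[vapply(subs, length, 1L) > 0]
    es <- entropy_by_subset(ds, subs, covariates)
    cf <- if (!is.null(cell_fractions)) {
      w <- cell_fractions[[d]]
      # drop one type to avoid the sum-to-one collinearity
      as.data.frame(t(w[-nrow(w), , drop = FALSE]))
    }
    do.call(rbind, lapply(split(es, es$subset), function(g) {
      sl <- entropy_vs_age(g$entropy, ds$sample_meta$age, covariates = cf)
      cbind(dataset = d, subset = g$subset[1], sl)
    }))
  }))
  rownames(slopes) <- NULL
  ok <- !slopes$degenerate
  meta <- do.call(rbind, lapply(split(slopes[ok, ], slopes$subset[ok]),
                                function(g) {
    cbind(subset = g$subset[1],
          meta_inverse_variance(g$slope_per_decade, g$se))
  }))
  rownames(meta) <- NULL
  list(slopes = slopes, meta = meta)
}
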