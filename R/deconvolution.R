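#' Reference-based cell-type deconvolution
#'
#' Estimates leukocyte proportions in bulk methylomes by constrained least
#' squares against a reference matrix of sorted-cell methylation profiles at
#' marker CpGs: for each sample, solve
#' \code{min || b - R w ||^2} subject to \code{w >= 0}, then project onto
#' the simplex by normalizing to sum 1 (the Houseman constrained-projection
#' approach; non-negative least squares plus normalization gives the same
#' solution as the quadratic program for well-conditioned references).
#'
#' @param bulk Beta matrix, CpGs x samples; must contain the reference's
#'   marker CpGs as rows (matched by rowname).
#' @param ref Reference matrix, marker CpGs x cell types, values in [0, 1].
#' @return List with \code{fractions} (cell types x samples, columns on the
#'   simplex) and \code{residual_norm} (per-sample residual of the NNLS
#'   fit).
#' @export
estimate_fractions <- function(bulk, ref) {
  ref <- as.matrix(ref)
  if (qr(ref)$rank < ncol(ref))
    stop("rank-deficient reference: cell-type profiles are collinear")
  markers <- rownames(ref)
  if (is.null(markers) || is.null(rownames(bulk)))
    stop("bulk and reference must carry CpG rownames")
  miss <- setdiff(markers, rownames(bulk))
  if (length(miss))
    stop(length(miss), " marker CpGs absent from the bulk matrix")
  B <- bulk[markers, , drop = FALSE]
  k <- ncol(ref)
  W <- matrix(0, k, ncol(B), dimnames = list(colnames(ref), colnames(B)))
  rn <- numeric(ncol(B))
  for (j in seq_len(ncol(B))) {
    fit <- pracma::lsqnonneg(ref, B[, j])
    w <- fit$x
    if (sum(w) <= 0) stop("degenerate NNLS solution (all-zero weights)")
    W[, j] <- w / sum(w)
    rn[j] <- sqrt(fit$resid.norm)
  }
  list(fractions = W, residual_norm = rn)
}

#' Append estimated cell-type fractions as model covariates
#'
#' Attaches the \code{k_largest} most abundant cell types (by dataset-mean
#' fraction) to a cohort's sample metadata so downstream regressions can
#' adjust for composition. Using all types would be collinear with the
#' intercept (fractions sum to one), so \code{k_largest} must be smaller
#' than the number of types; zero-variance fractions are dropped with a
#' warning.
#'
#' @param ds A [methyl_dataset()].
#' @param fractions Cell types x samples fraction matrix (column order must
#'   match the dataset's samples).
#' @param k_largest How many types to include (default 5).
#' @return The dataset with fraction columns added to \code{sample_meta} and
#'   their names in \code{attr(, "cell_covariates")}.
#' @export
adjust_for_celltypes <- function(ds, fractions, k_largest = 5) {
  stopifnot(inherits(ds, "methyl_dataset"))
  fractions <- as.matrix(fractions)
  if (ncol(fractions) != nrow(ds$sample_meta))
    stop("fractions and samples disagree")
  if (k_largest >= nrow(fractions))
    stop("k_largest must be smaller than the number of cell types ",
         "(fractions sum to 1: including all is collinear with the intercept)")
  keep <- names(sort(rowMeans(fractions), decreasing = TRUE))[seq_len(k_largest)]
  const <- keep[apply(fractions[keep, , drop = FALSE], 1, stats::sd) == 0]
  if (length(const)) {
    warning("zero-variance cell fractions dropped: ",
            paste(const, collapse = ", "))
    keep <- setdiff(keep, const)
  }
  for (ct in keep) ds$sample_meta[[ct]] <- fractions[ct, ]
  attr(ds, "cell_covariates") <- keep
  ds
}

#' Concordance between cell-adjusted and unadjusted meta-analyses
#'
#' Compares two meta-analysis result tables on their shared CpG universe:
#' Pearson correlation of the pooled effects (or z-scores), the cross-table
#' of significance calls, and the fractions of CpGs significant in only one
#' analysis.
#'
#' @param meta_a,meta_b Meta-analysis data.frames with \code{cpg}, \code{q}
#'   and an effect column.
#' @param effect_col Column to correlate (default \code{"pooled_effect"};
#'   use \code{"z"} for variance meta-analyses).
#' @param q_threshold Significance threshold (default 0.005).
#' @return List: \code{r}, \code{n_shared}, \code{calls} (2x2 table),
#'   \code{frac_only_a}, \code{frac_only_b}, \code{frac_both} (of the union
#'   of significant CpGs).
#' @export
compare_adjusted_unadjusted <- function(meta_a, meta_b,
                                        effect_col = "pooled_effect",
                                        q_threshold = 0.005) {
  shared <- intersect(meta_a$cpg, meta_b$cpg)
  if (length(shared) == 0) stop("disjoint CpG universes")
  ia <- match(shared, meta_a$cpg)
  ib <- match(shared, meta_b$cpg)
  r <- stats::cor(meta_a[[effect_col]][ia], meta_b[[effect_col]][ib])
  sig_a <- call_significant(meta_a$q[ia], q_threshold)
  sig_b <- call_significant(meta_b$q[ib], q_threshold)
  calls <- table(a = sig_a, b = sig_b)
  n_union <- sum(sig_a | sig_b)
  list(r = r, n_shared = length(shared), calls = calls,
       frac_only_a = if (n_union) sum(sig_a & !sig_b) / n_union else 0,
       frac_only_b = if (n_union) sum(!sig_a & sig_b) / n_union else 0,
       frac_both = if (n_union) sum(sig_a & sig_b) / n_union else 0)
}
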