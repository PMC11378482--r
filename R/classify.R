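#' Joint DMP/VMP classification from meta-analysis results
#'
#' Merges the mean and variance meta-analyses on their common CpG universe
#' and labels each CpG: \code{dmp} iff the mean-methylation q-value is below
#' the threshold, \code{vmp} iff the variance q-value is, with directions
#' taken from the pooled effect signs (hypo/hyper for the mean,
#' increase/decrease for the variance). The joint class is
#' \code{homoscedastic_DMP}, \code{constant_VMP}, \code{DMP_VMP} or
#' \code{none}. A CpG absent from one analysis (presence rules differ) is
#' treated as not significant there.
#'
#' @param meta_mean Result of [meta_ewas_mean()].
#' @param meta_var Result of [meta_ewas_variance()].
#' @param q_threshold FDR threshold (default 0.005).
#' @return data.frame: \code{cpg}, \code{dmp}, \code{vmp},
#'   \code{direction_mean}, \code{direction_var}, \code{joint_class},
#'   \code{effect_beta} (pooled fraction/year, NA if absent).
#' @export
assign_joint_class <- function(meta_mean, meta_var, q_threshold = 0.005) {
  cpgs <- union(meta_mean$cpg, meta_var$cpg)
  im <- match(cpgs, meta_mean$cpg)
  iv <- match(cpgs, meta_var$cpg)
  dmp <- !is.na(im) & call_significant(meta_mean$q[im], q_threshold)
  vmp <- !is.na(iv) & call_significant(meta_var$q[iv], q_threshold)
  eff <- meta_mean$pooled_effect_beta[im]
  dir_mean <- ifelse(dmp, ifelse(eff < 0, "hypo", "hyper"), "none")
  vdir <- sign(meta_var$z[iv])
  dir_var <- ifelse(vmp, ifelse(vdir > 0, "increase", "decrease"), "none")
  joint <- ifelse(dmp & vmp, "DMP_VMP",
                  ifelse(dmp, "homoscedastic_DMP",
                         ifelse(vmp, "constant_VMP", "none")))
  data.frame(cpg = cpgs, dmp = dmp, vmp = vmp,
             direction_mean = dir_mean, direction_var = dir_var,
             joint_class = joint, effect_beta = eff,
             stringsAsFactors = FALSE)
}

#' Baseline methylation categories
#'
#' Classifies mean methylation fractions as \code{"high"} (MF >= 0.75),
#' \code{"low"} (MF <= 0.25) or \code{"intermediate"}; both boundaries
#' inclusive.
#'
#' @param mf Mean methylation fractions.
#' @return Character vector of categories.
#' @export
baseline_class <- function(mf) {
  if (length(mf) == 0) stop("empty input")
  ifelse(mf >= 0.75, "high", ifelse(mf <= 0.25, "low", "intermediate"))
}

#' Mean methylation in a young reference stratum
#'
#' The baseline used to decide whether a DMP converges to or diverges from
#' 50% methylation. Samples younger than \code{max_age} (default 30 years)
#' form the stratum if at least \code{min_n} of them exist; otherwise the
#' youngest age tertile is used (small or old-skewed cohorts have no under-30
#' stratum).
#'
#' @param ds A [methyl_dataset()].
#' @param max_age Upper age bound of the young stratum (exclusive).
#' @param min_n Minimum stratum size before falling back to the tertile.
#' @return Named numeric vector of per-CpG mean methylation fractions.
#' @export
baseline_mf <- function(ds, max_age = 30, min_n = 30) {
  stopifnot(inherits(ds, "methyl_dataset"))
  age <- ds$sample_meta$age
  young <- age < max_age
  if (sum(young) < min_n)
    young <- age <= stats::quantile(age, 1 / 3)
  if (!any(young)) stop("empty young stratum")
  rowMeans(ds$beta[, young, drop = FALSE])
}

#' Entropic vs anti-entropic DMPs
#'
#' A DMP is \emph{entropic} when its age slope moves the methylation
#' fraction toward 0.5 — the direction that raises Shannon entropy — i.e.
#' slope > 0 from a baseline below 0.5 or slope < 0 from above 0.5. It is
#' \emph{anti-entropic} when it drifts away from 0.5 toward the fully
#' methylated or unmethylated state. At a baseline of exactly 0.5 any
#' nonzero slope diverges, so the CpG is anti-entropic.
#'
#' @param baseline Baseline methylation fractions (see [baseline_mf()]).
#' @param slope Pooled mean-methylation slopes (fraction per year).
#' @return Character vector: \code{"entropic"} or \code{"anti_entropic"}.
#' @export
entropic_class <- function(baseline, slope) {
  if (length(baseline) != length(slope)) stop("length mismatch")
  if (any(slope == 0))
    stop("entropic classification is defined only for DMPs (nonzero slope)")
  ifelse(baseline < 0.5 & slope > 0, "entropic",
         ifelse(baseline > 0.5 & slope < 0, "entropic", "anti_entropic"))
}

#' Assemble the full CpG class table
#'
#' Combines the joint DMP/VMP classification, baseline methylation
#' categories (from a reference cohort's young stratum) and the
#' entropic/anti-entropic partition of DMPs into one table.
#'
#' @param meta_mean,meta_var Meta-analysis results.
#' @param reference_ds Cohort used for baseline methylation (conventionally
#'   the largest).
#' @param q_threshold FDR threshold (default 0.005).
#' @return data.frame keyed by CpG with \code{joint_class},
#'   \code{direction_mean}, \code{direction_var}, \code{baseline_mf},
#'   \code{baseline_class} and \code{entropic_class} (\code{"not_DMP"} for
#'   non-DMPs).
#' @export
build_class_table <- function(meta_mean, meta_var, reference_ds,
                              q_threshold = 0.005) {
  cls <- assign_joint_class(meta_mean, meta_var, q_threshold)
  base <- baseline_mf(reference_ds)
  cls$baseline_mf <- unname(base[match(cls$cpg, names(base))])
  cls$baseline_class <- ifelse(is.na(cls$baseline_mf), NA_character_,
                               baseline_class(cls$baseline_mf))
  cls$entropic_class <- "not_DMP"
  i <- which(cls$dmp & !is.na(cls$baseline_mf) & cls$effect_beta != 0)
  cls$entropic_class[i] <- entropic_class(cls$baseline_mf[i],
                                          cls$effect_beta[i])
  cls
}
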