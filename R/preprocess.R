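#' Probe and sample filtering for a methylation cohort
#'
#' Applies the standard array-QC rules in a fixed order, samples first (their
#' removal changes the per-probe failure fractions that the probe rules use):
#' \enumerate{
#'   \item samples with more than \code{sample_fail_frac} of probes at a
#'     detection p-value above \code{detection_p} are removed;
#'   \item probes failing detection in any remaining sample are removed;
#'   \item probes with a bead count below \code{beadcount_min} in at least
#'     \code{beadcount_frac} of samples are removed;
#'   \item non-CG probes, multi-mapping probes, SNP-overlapping probes and
#'     cross-reactive probes are removed (annotation flags
#'     \code{noncg}, \code{multimap}, \code{snp}, \code{cross_reactive});
#'   \item probes on sex chromosomes are removed when the cohort contains
#'     both sexes.
#' }
#' Rules whose inputs are missing (no detection p-value matrix, no bead
#' counts, absent flag columns) are skipped with a warning and recorded as
#' skipped in the report. Filtering is idempotent.
#'
#' @param ds A [methyl_dataset()].
#' @param detection_p Detection p-value threshold above which a measurement
#'   counts as failed (default 0.01).
#' @param sample_fail_frac Maximum tolerated fraction of failed probes per
#'   sample (default 0.10; strictly greater is removed).
#' @param beadcount_min Minimum bead count (default 3; strictly fewer fails).
#' @param beadcount_frac Fraction of samples at which low bead count removes
#'   the probe (default 0.05, at-least).
#' @return A list with \code{dataset} (the filtered [methyl_dataset()]) and
#'   \code{report}, a data.frame with one row per rule: rule name, how many
#'   samples/probes it removed, and whether it was skipped.
#' @export
filter_probes <- function(ds, detection_p = 0.01, sample_fail_frac = 0.10,
                          beadcount_min = 3, beadcount_frac = 0.05) {
  stopifnot(inherits(ds, "methyl_dataset"))
  report <- data.frame(rule = character(), removed_samples = integer(),
                       removed_probes = integer(), skipped = logical(),
                       stringsAsFactors = FALSE)
  note <- function(rule, rs = 0L, rp = 0L, skipped = FALSE) {
    rbind(report, data.frame(rule = rule, removed_samples = as.integer(rs),
                             removed_probes = as.integer(rp),
                             skipped = skipped))
  }
  keep_s <- rep(TRUE, ncol(ds$beta))
  keep_p <- rep(TRUE, nrow(ds$beta))

  # 1. failed samples
  if (!is.null(ds$detection_p)) {
    fail_frac <- colMeans(ds$detection_p > detection_p)
    drop <- fail_frac > sample_fail_frac
    keep_s <- keep_s & !drop
    report <- note("sample_detection", rs = sum(drop))
  } else {
    warning("no detection p-value matrix: sample detection rule skipped")
    report <- note("sample_detection", skipped = TRUE)
  }

  # 2. probes failing detection anywhere (complete-case per probe)
  if (!is.null(ds$detection_p)) {
    drop <- rowSums(ds$detection_p[, keep_s, drop = FALSE] > detection_p) > 0
    keep_p <- keep_p & !drop
    report <- note("probe_detection", rp = sum(drop))
  } else {
    report <- note("probe_detection", skipped = TRUE)
  }

  # 3. low bead count
  if (!is.null(ds$beadcount)) {
    frac_low <- rowMeans(ds$beadcount[, keep_s, drop = FALSE] < beadcount_min)
    drop <- keep_p & frac_low >= beadcount_frac
    keep_p <- keep_p & !drop
    report <- note("beadcount", rp = sum(drop))
  } else {
    warning("no bead-count matrix: bead-count rule skipped")
    report <- note("beadcount", skipped = TRUE)
  }

  # 4. annotation flag rules
  for (flag in c("noncg", "multimap", "snp", "cross_reactive")) {
    if (flag %in% names(ds$probe_meta)) {
      drop <- keep_p & as.logical(ds$probe_meta[[flag]])
      keep_p <- keep_p & !drop
      report <- note(flag, rp = sum(drop))
    } else {
      warning(sprintf("probe annotation lacks '%s': rule skipped", flag))
      report <- note(flag, skipped = TRUE)
    }
  }

  # 5. sex chromosomes, only for mixed-sex cohorts
  if ("chrom" %in% names(ds$probe_meta)) {
    mixed <- "sex" %in% names(ds$sample_meta) &&
      length(unique(ds$sample_meta$sex[keep_s])) > 1
    if (mixed) {
      drop <- keep_p & ds$probe_meta$chrom %in% c("chrX", "chrY", "X", "Y")
      keep_p <- keep_p & !drop
      report <- note("sex_chromosomes", rp = sum(drop))
    } else {
      report <- note("sex_chromosomes", rp = 0L)
    }
  } else {
    warning("probe annotation lacks 'chrom': sex-chromosome rule skipped")
    report <- note("sex_chromosomes", skipped = TRUE)
  }

  out <- methyl_dataset(
    ds$beta[keep_p, keep_s, drop = FALSE],
    ds$sample_meta[keep_s, , drop = FALSE],
    ds$probe_meta[keep_p, , drop = FALSE],
    detection_p = if (!is.null(ds$detection_p))
      ds$detection_p[keep_p, keep_s, drop = FALSE],
    beadcount = if (!is.null(ds$beadcount))
      ds$beadcount[keep_p, keep_s, drop = FALSE])
  list(dataset = out, report = report)
}

#' Cohort inclusion gate
#'
#' A cohort enters the meta-analysis only if it has at least \code{min_n}
#' samples and an age standard deviation of at least \code{min_age_sd} years;
#' smaller or age-homogeneous cohorts cannot support the age regressions.
#' Both boundaries are inclusive.
#'
#' @param ds A [methyl_dataset()].
#' @param min_n Minimum sample size (default 30).
#' @param min_age_sd Minimum age standard deviation in years (default 5).
#' @return A list with \code{include} (logical) and \code{reason}
#'   (\code{"ok"}, \code{"n<30"}-style size reason, or \code{"age SD<5"}).
#' @export
gate_dataset <- function(ds, min_n = 30, min_age_sd = 5) {
  stopifnot(inherits(ds, "methyl_dataset"))
  n <- nrow(ds$sample_meta)
  if (n < min_n)
    return(list(include = FALSE, reason = sprintf("n<%d", min_n)))
  if (stats::sd(ds$sample_meta$age) < min_age_sd)
    return(list(include = FALSE, reason = sprintf("age SD<%g", min_age_sd)))
  list(include = TRUE, reason = "ok")
}
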