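#' Read and write methylation cohorts as delimited text
#'
#' A cohort is stored as three tab-separated files in one directory:
#' \code{beta.tsv} (CpGs x samples, rownames = CpG ids), \code{samples.tsv}
#' (per-sample metadata) and \code{probes.tsv} (per-CpG annotation whose
#' first three columns, chrom/start/end, are BED-compatible 0-based
#' half-open coordinates).
#'
#' @param ds A [methyl_dataset()].
#' @param dir Directory to write to / read from (created if missing).
#' @return \code{write_cohort} returns the directory invisibly;
#'   \code{read_cohort} returns a [methyl_dataset()].
#' @export
write_cohort <- function(ds, dir) {
  stopifnot(inherits(ds, "methyl_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(data.frame(cpg = rownames(ds$beta), ds$beta,
                                check.names = FALSE),
                     file.path(dir, "beta.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ds$sample_meta, file.path(dir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  pm <- ds$probe_meta
  bed_first <- intersect(c("chrom", "start", "end"), names(pm))
  pm <- pm[, c(bed_first, setdiff(names(pm), bed_first))]  # BED triple first
  utils::write.table(pm, file.path(dir, "probes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  bt <- utils::read.delim(file.path(dir, "beta.tsv"), check.names = FALSE)
  beta <- as.matrix(bt[, -1, drop = FALSE])
  rownames(beta) <- bt$cpg
  sm <- utils::read.delim(file.path(dir, "samples.tsv"),
                          stringsAsFactors = FALSE)
  for (f in intersect(c("sex", "batch"), names(sm))) sm[[f]] <- factor(sm[[f]])
  pm <- utils::read.delim(file.path(dir, "probes.tsv"),
                          stringsAsFactors = FALSE)
  pm <- pm[, c("cpg", setdiff(names(pm), "cpg"))]
  methyl_dataset(beta, sm, pm)
}

#' Write the ground truth of a simulation to TSV
#'
#' @param truth The \code{$truth} element returned by [generate_cohorts()].
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(truth$cpgs, file.path(dir, "truth_cpgs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (d in names(truth$cell_fractions)) {
    w <- truth$cell_fractions[[d]]
    utils::write.table(data.frame(celltype = rownames(w), w,
                                  check.names = FALSE),
                       file.path(dir, sprintf("cell_fractions_%s.tsv", d)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
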