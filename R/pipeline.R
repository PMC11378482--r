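#' Configuration for a full pipeline run
#'
#' @param covariates Covariate columns used by every per-dataset model
#'   (intersected with what each cohort actually has).
#' @param fdr Meta-analysis FDR threshold (default 0.005).
#' @param min_datasets Mean-methylation presence rule (default 3).
#' @param presence_frac Variance-analysis sample-coverage rule (default 0.15).
#' @param shapiro_p Shapiro-Wilk screen threshold (default 1e-5).
#' @param min_n,min_age_sd Cohort gating rules (defaults 30 samples, 5 years).
#' @param cell_adjust Also run the cell-type-adjusted branch (needs
#'   \code{reference}).
#' @param reference Marker-CpG x cell-type reference beta matrix for
#'   deconvolution.
#' @param k_largest Number of cell types used as covariates (default 5).
#' @param out_dir Directory for TSV outputs and the JSON manifest, or NULL
#'   to keep results in memory only.
#' @param seed Integer seed (the pipeline itself is deterministic; the seed
#'   is recorded in the manifest for provenance).
#' @return A validated list of class \code{"run_config"}.
#' @export
run_config <- function(covariates = c("sex", "batch", "bmi"),
                       fdr = 0.005, min_datasets = 3, presence_frac = 0.15,
                       shapiro_p = 1e-5, min_n = 30, min_age_sd = 5,
                       cell_adjust = FALSE, reference = NULL, k_largest = 5,
                       out_dir = NULL, seed = 1L) {
  for (th in c(fdr, presence_frac, shapiro_p))
    if (th <= 0 || th >= 1) stop("thresholds must lie in (0, 1)")
  if (cell_adjust && is.null(reference))
    stop("cell_adjust = TRUE needs a reference matrix")
  structure(list(covariates = covariates, fdr = fdr,
                 min_datasets = min_datasets, presence_frac = presence_frac,
                 shapiro_p = shapiro_p, min_n = min_n,
                 min_age_sd = min_age_sd, cell_adjust = cell_adjust,
                 reference = reference, k_largest = k_largest,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

#' Load a run or simulation configuration from YAML
#'
#' Reads a YAML mapping whose keys are the arguments of [run_config()] (or
#' [sim_config()]) and builds the corresponding validated configuration.
#'
#' @param path Path to a YAML file.
#' @return A \code{run_config} / \code{sim_config} object.
#' @export
run_config_from_yaml <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' @rdname run_config_from_yaml
#' @export
sim_config_from_yaml <- function(path) {
  do.call(sim_config, yaml::read_yaml(path))
}

# one unadjusted-or-adjusted pass: per-cohort EWAS -> empirical-null
# adjustment -> both meta-analyses
.ewas_meta_pass <- function(datasets, covariates, config) {
  mean_recs <- lapply(datasets, function(ds) {
    covs <- intersect(covariates, names(ds$sample_meta))
    extra <- attr(ds, "cell_covariates")
    rec <- fit_mean_ewas(ds, c(covs, extra))
    rec <- empirical_null_adjust(rec, "effect_beta", "se_beta")
    empirical_null_adjust(rec, "effect_m", "se_m")
  })
  var_recs <- lapply(datasets, function(ds) {
    covs <- intersect(covariates, names(ds$sample_meta))
    extra <- attr(ds, "cell_covariates")
    fit_variance_ewas(ds, c(covs, extra), shapiro_p = config$shapiro_p)
  })
  list(mean_records = mean_recs, var_records = var_recs,
       meta_mean = meta_ewas_mean(mean_recs, config$min_datasets),
       meta_var = meta_ewas_variance(var_recs, config$presence_frac))
}

# class-table derived CpG subsets for the entropy stage
.entropy_subsets <- function(classes) {
  subs <- list(
    genome_wide = classes$cpg,
    age_related = classes$cpg[classes$dmp | classes$vmp],
    non_age_related = classes$cpg[!classes$dmp & !classes$vmp],
    homoscedastic_DMP = classes$cpg[classes$joint_class == "homoscedastic_DMP"],
    DMP_VMP = classes$cpg[classes$joint_class == "DMP_VMP"],
    constant_VMP = classes$cpg[classes$joint_class == "constant_VMP"],
    entropic_DMP = classes$cpg[classes$entropic_class == "entropic"],
    anti_entropic_DMP = classes$cpg[classes$entropic_class == "anti_entropic"])
  subs[vapply(subs, length, 1L) > 0]
}

#' Run the full multi-cohort analysis
#'
#' Orchestrates the complete flow on a list of cohorts: gating, probe/sample
#' filtering, per-cohort mean and variance EWAS with empirical-null
#' correction, both meta-analyses with FDR, CpG classification (joint,
#' baseline and entropic classes), and the entropy-age analysis over the
#' class-derived CpG subsets. When \code{cell_adjust} is enabled and a
#' reference is supplied, cell-type fractions are deconvolved, the EWAS and
#' meta-analyses are repeated with the largest cell types as covariates, and
#' the two branches are compared. With an \code{out_dir}, every table is
#' written as TSV and a JSON manifest records each file with its MD5 hash;
#' a rerun with the same inputs and configuration reproduces the hashes.
#'
#' @param cohorts List of [methyl_dataset()] objects (e.g.
#'   \code{generate_cohorts(...)$datasets}), or a directory containing one
#'   cohort subdirectory per dataset in the [write_cohort()] layout.
#' @param config A [run_config()].
#' @return List: \code{gating} (per-cohort decision), \code{filter_reports},
#'   \code{unadjusted} (records + meta tables), \code{classes},
#'   \code{entropy}, and when enabled \code{adjusted},
#'   \code{cell_fractions}, \code{comparison_mean}, \code{comparison_var};
#'   plus \code{manifest} when \code{out_dir} is set.
#' @export
run_full <- function(cohorts, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  if (is.character(cohorts)) {
    dirs <- list.dirs(cohorts, recursive = FALSE)
    cohorts <- lapply(dirs, read_cohort)
    names(cohorts) <- basename(dirs)
  }
  if (is.null(names(cohorts)))
    names(cohorts) <- sprintf("d%02d", seq_along(cohorts))
  log <- character()
  say <- function(fmt, ...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                   sprintf(fmt, ...))
    log <<- c(log, msg)
  }
  stage <- function(name, cohort, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed for cohort '%s': %s",
                   name, cohort, conditionMessage(e)), call. = FALSE))
  }

  gating <- lapply(names(cohorts), function(d)
    c(dataset = d, gate_dataset(cohorts[[d]], config$min_n,
                                config$min_age_sd)))
  keep <- vapply(gating, function(g) isTRUE(g$include), logical(1))
  for (g in gating[!keep])
    say("cohort %s excluded: %s", g[["dataset"]], g[["reason"]])
  cohorts <- cohorts[keep]
  if (length(cohorts) == 0) stop("no cohort passes the inclusion gate")

  filtered <- lapply(names(cohorts), function(d)
    stage("filter", d, suppressWarnings(filter_probes(cohorts[[d]]))))
  names(filtered) <- names(cohorts)
  datasets <- lapply(filtered, `[[`, "dataset")
  reports <- lapply(filtered, `[[`, "report")
  say("%d cohorts gated and filtered", length(datasets))

  unadj <- stage("ewas/meta", "all",
                 .ewas_meta_pass(datasets, config$covariates, config))
  say("meta-analyses: %d CpGs (mean), %d CpGs (variance)",
      nrow(unadj$meta_mean), nrow(unadj$meta_var))

  ref_cohort <- datasets[[which.max(vapply(datasets, function(d)
    ncol(d$beta), numeric(1)))]]
  classes <- stage("classify", "all",
                   build_class_table(unadj$meta_mean, unadj$meta_var,
                                     ref_cohort, config$fdr))
  say("classes: %s",
      paste(names(table(classes$joint_class)),
            table(classes$joint_class), sep = "=", collapse = " "))

  entropy <- stage("entropy", "all",
                   entropy_analysis(datasets, .entropy_subsets(classes),
                                    covariates = intersect(
                                      config$covariates,
                                      names(datasets[[1]]$sample_meta))))

  out <- list(gating = gating, filter_reports = reports,
              unadjusted = unadj, classes = classes, entropy = entropy,
              config = config)

  if (config$cell_adjust) {
    fracs <- lapply(names(datasets), function(d)
      stage("deconvolution", d,
            estimate_fractions(datasets[[d]]$beta,
                               config$reference)$fractions))
    names(fracs) <- names(datasets)
    adj_ds <- lapply(names(datasets), function(d)
      stage("cell-adjust", d,
            adjust_for_celltypes(datasets[[d]], fracs[[d]],
                                 config$k_largest)))
    names(adj_ds) <- names(datasets)
    adj <- stage("ewas/meta adjusted", "all",
                 .ewas_meta_pass(adj_ds, config$covariates, config))
    out$cell_fractions <- fracs
    out$adjusted <- adj
    out$comparison_mean <- compare_adjusted_unadjusted(
      adj$meta_mean, unadj$meta_mean, "pooled_effect", config$fdr)
    out$comparison_var <- compare_adjusted_unadjusted(
      adj$meta_var, unadj$meta_var, "z", config$fdr)
    say("cell-adjusted branch complete (mean-effect r = %.3f)",
        out$comparison_mean$r)
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(obj, name) {
      path <- file.path(config$out_dir, name)
      utils::write.table(obj, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      path
    }
    paths <- c(wr(unadj$meta_mean, "meta_mean.tsv"),
               wr(unadj$meta_var, "meta_variance.tsv"),
               wr(classes, "cpg_classes.tsv"),
               wr(entropy$slopes, "entropy_slopes.tsv"),
               wr(entropy$meta, "entropy_meta.tsv"))
    if (config$cell_adjust)
      paths <- c(paths,
                 wr(out$adjusted$meta_mean, "meta_mean_celladj.tsv"),
                 wr(out$adjusted$meta_var, "meta_variance_celladj.tsv"))
    manifest <- list(seed = config$seed,
                     files = lapply(paths, function(p)
                       list(path = basename(p),
                            md5 = unname(tools::md5sum(p)))))
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    writeLines(log, file.path(config$out_dir, "log.txt"))
    out$manifest <- manifest
  }
  out$log <- log
  out
}
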