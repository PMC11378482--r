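#' Simulation configuration for multi-cohort synthetic methylomes
#'
#' Bundles and validates every knob of the synthetic-data generator. Defaults
#' describe a 20-cohort blood-methylome study: cohort sizes between 100 and
#' 2000 samples, cohort-specific age windows of 30-60 years inside a global
#' 20-90 year range, 48% of CpGs with an age-linear mean drift (DMPs), 37%
#' with an age-linear variance increase (VMPs), 59% of DMPs also VMPs, 73% of
#' DMPs drifting toward 50% methylation (entropic) and 66% losing methylation
#' (hypomethylating). Mean slopes are drawn between 0.01% and 0.055%
#' methylation per year; variance slopes target 0.001%-0.01% (fraction^2)
#' per year, capped by a Beta-precision floor so the generated distributions
#' stay realistic (see the methods vignette).
#'
#' @param n_datasets Number of cohorts.
#' @param n_samples Integer vector of per-cohort sample sizes (recycled), or
#'   NULL to draw each uniformly from \code{n_samples_range}.
#' @param n_samples_range Range cohort sizes are drawn from when
#'   \code{n_samples} is NULL.
#' @param age_range Global (min, max) age in years; cohort windows live inside.
#' @param age_window_width Range of cohort age-window widths in years.
#' @param n_cpgs CpGs per cohort (all cohorts share the CpG universe).
#' @param frac_dmp,frac_vmp Fractions of CpGs with mean / variance age effects.
#' @param frac_overlap Fraction of DMPs that are also VMPs.
#' @param frac_entropic Fraction of DMPs whose mean drifts toward 0.5.
#' @param frac_hypo Fraction of entropic/extreme-baseline DMPs placed at a
#'   high baseline (these lose methylation with age).
#' @param mean_slope_range Magnitude range of the mean drift, methylation
#'   fraction per year (0.00027 = 0.027% per year).
#' @param var_slope_range Target magnitude range of the variance drift,
#'   fraction-squared units per year.
#' @param n_celltypes Number of leukocyte types mixed into marker CpGs.
#' @param celltype_age_drift Per-year increase in the summed proportion of the
#'   drifting types (granulocytes + monocytes); 0 disables composition
#'   confounding.
#' @param frac_markers Fraction of CpGs that are cell-identity markers
#'   (lowly methylated in one type, highly in the rest); drawn from the
#'   age-null class.
#' @param covariate_effects Named logit-scale effect sizes for
#'   \code{sex}, \code{batch} (group contrasts) and \code{bmi} (per unit).
#' @param frac_cov_affected Fraction of CpGs carrying each covariate effect.
#' @param seed Integer seed; fully determines the generated data.
#' @return A validated list of class \code{"sim_config"}.
#' @seealso [generate_cohorts()]
#' @export
sim_config <- function(n_datasets = 20L,
                       n_samples = NULL,
                       n_samples_range = c(100L, 2000L),
                       age_range = c(20, 90),
                       age_window_width = c(30, 60),
                       n_cpgs = 2000L,
                       frac_dmp = 0.48,
                       frac_vmp = 0.37,
                       frac_overlap = 0.59,
                       frac_entropic = 0.73,
                       frac_hypo = 0.66,
                       mean_slope_range = c(1e-4, 5.5e-4),
                       var_slope_range = c(1e-5, 1e-4),
                       n_celltypes = 6L,
                       celltype_age_drift = 0,
                       frac_markers = 0.05,
                       covariate_effects = c(sex = 0.15, batch = 0.2, bmi = 0.01),
                       frac_cov_affected = 0.10,
                       seed = 1L) {
  fr <- c(frac_dmp = frac_dmp, frac_vmp = frac_vmp, frac_overlap = frac_overlap,
          frac_entropic = frac_entropic, frac_hypo = frac_hypo,
          frac_markers = frac_markers, frac_cov_affected = frac_cov_affected)
  if (any(fr < 0 | fr > 1))
    stop("all fractions must lie in [0, 1]")
  if (n_datasets < 1 || n_cpgs < 1)
    stop("n_datasets and n_cpgs must be >= 1")
  if (!is.null(n_samples) && any(n_samples < 1))
    stop("n_samples must be >= 1")
  if (diff(age_range) <= 0)
    stop("age max must exceed age min")
  if (diff(range(mean_slope_range)) < 0 || any(mean_slope_range < 0))
    stop("mean_slope_range must be non-negative magnitudes")
  # signal mis-specification: a maximal slope over the full age span may not
  # push any admissible baseline out of (0, 1)
  if (max(mean_slope_range) * diff(age_range) >= 0.94)
    stop("mean slope times age span exits (0,1): mis-specified signal")
  if (n_celltypes < 2)
    stop("need at least 2 cell types")
  cfg <- list(n_datasets = as.integer(n_datasets), n_samples = n_samples,
              n_samples_range = n_samples_range, age_range = age_range,
              age_window_width = age_window_width, n_cpgs = as.integer(n_cpgs),
              frac_dmp = frac_dmp, frac_vmp = frac_vmp,
              frac_overlap = frac_overlap, frac_entropic = frac_entropic,
              frac_hypo = frac_hypo, mean_slope_range = mean_slope_range,
              var_slope_range = var_slope_range,
              n_celltypes = as.integer(n_celltypes),
              celltype_age_drift = celltype_age_drift,
              frac_markers = frac_markers,
              covariate_effects = covariate_effects,
              frac_cov_affected = frac_cov_affected, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Construct a methylation dataset
#'
#' A \code{methyl_dataset} holds one cohort: a CpG-by-sample matrix of
#' methylation fractions, per-sample metadata (age in years plus any
#' covariates) and per-CpG probe annotation.
#'
#' @param beta Numeric matrix, CpGs in rows, samples in columns, values in
#'   \code{[0, 1]}; rownames are CpG ids, colnames sample ids.
#' @param sample_meta data.frame with one row per sample; must contain
#'   \code{sample_id} and numeric \code{age}.
#' @param probe_meta data.frame with one row per CpG; must contain \code{cpg}.
#' @param detection_p Optional matrix of detection p-values, same shape as
#'   \code{beta}.
#' @param beadcount Optional matrix of bead counts, same shape as \code{beta}.
#' @return An object of class \code{"methyl_dataset"}.
#' @export
methyl_dataset <- function(beta, sample_meta, probe_meta,
                           detection_p = NULL, beadcount = NULL) {
  beta <- as.matrix(beta)
  if (ncol(beta) != nrow(sample_meta))
    stop("beta columns and sample_meta rows disagree")
  if (nrow(beta) != nrow(probe_meta))
    stop("beta rows and probe_meta rows disagree")
  if (!all(c("sample_id", "age") %in% names(sample_meta)))
    stop("sample_meta needs 'sample_id' and 'age' columns")
  if (!"cpg" %in% names(probe_meta))
    stop("probe_meta needs a 'cpg' column")
  if (any(beta < 0 | beta > 1, na.rm = TRUE))
    stop("beta values must lie in [0, 1]")
  rownames(beta) <- probe_meta$cpg
  colnames(beta) <- sample_meta$sample_id
  structure(list(beta = beta, sample_meta = sample_meta,
                 probe_meta = probe_meta, detection_p = detection_p,
                 beadcount = beadcount),
            class = "methyl_dataset")
}

#' @export
print.methyl_dataset <- function(x, ...) {
  cat(sprintf("methyl_dataset: %d CpGs x %d samples\n",
              nrow(x$beta), ncol(x$beta)))
  cat(sprintf("  ages %.1f-%.1f (sd %.1f)\n",
              min(x$sample_meta$age), max(x$sample_meta$age),
              stats::sd(x$sample_meta$age)))
  covs <- setdiff(names(x$sample_meta), c("sample_id", "age", "dataset"))
  if (length(covs)) cat("  covariates:", paste(covs, collapse = ", "), "\n")
  invisible(x)
}

# baseline feasibility margin for mean trajectories
.MU_MIN <- 0.03
.MU_MAX <- 0.97

# Beta-precision floors: the generated variance never exceeds
# m(1-m)/(floor+1), so M-value residuals stay near-normal (symmetric CpGs
# tolerate a lower floor than skewed extreme-baseline ones).
.PHI_FLOOR_EXTREME <- 120
.PHI_FLOOR_MID <- 40

# plant per-CpG ground truth (classes, baselines, slopes, precision schedule)
.plant_truth <- function(cfg) {
  n <- cfg$n_cpgs
  span <- diff(cfg$age_range)
  n_dmp <- round(cfg$frac_dmp * n)
  n_vmp <- round(cfg$frac_vmp * n)
  n_both <- round(cfg$frac_overlap * n_dmp)
  if (n_both > n_vmp)
    stop("frac_overlap * frac_dmp exceeds frac_vmp: inconsistent class sizes")
  if (n_dmp + (n_vmp - n_both) > n)
    stop("class fractions exceed the CpG universe")
  idx <- sample.int(n)
  i_dmp <- idx[seq_len(n_dmp)]
  i_both <- i_dmp[seq_len(n_both)]
  i_vmponly <- idx[n_dmp + seq_len(n_vmp - n_both)]
  cls <- rep("none", n)
  cls[i_dmp] <- "DMP"
  cls[i_both] <- "DMP-VMP"
  cls[i_vmponly] <- "VMP"

  baseline <- numeric(n)
  entropic <- rep(NA, n)
  slope <- numeric(n)

  # null CpGs: bimodal methylome, ~1% intermediate
  i_none <- which(cls == "none")
  u <- stats::runif(length(i_none))
  baseline[i_none] <- ifelse(
    u < 0.495, stats::runif(length(i_none), 0.03, 0.15),
    ifelse(u < 0.99, stats::runif(length(i_none), 0.85, 0.97),
           stats::runif(length(i_none), 0.30, 0.70)))

  # VMP-only CpGs: mostly extreme baselines, some intermediate
  if (length(i_vmponly)) {
    u <- stats::runif(length(i_vmponly))
    lo <- stats::runif(length(i_vmponly), 0.08, 0.25)
    hi <- stats::runif(length(i_vmponly), 0.75, 0.92)
    mid <- stats::runif(length(i_vmponly), 0.30, 0.70)
    baseline[i_vmponly] <- ifelse(u < 0.4, lo, ifelse(u < 0.8, hi, mid))
  }

  # DMPs: entropic ones sit at extreme baselines and drift toward 0.5
  # (high baseline => hypomethylating); anti-entropic ones sit at
  # intermediate baselines and drift away from 0.5
  if (length(i_dmp)) {
    ent <- stats::runif(length(i_dmp)) < cfg$frac_entropic
    entropic[i_dmp] <- ent
    hypo <- stats::runif(length(i_dmp)) < cfg$frac_hypo
    b <- numeric(length(i_dmp))
    sgn <- numeric(length(i_dmp))
    b[ent & hypo] <- stats::runif(sum(ent & hypo), 0.75, 0.92)
    sgn[ent & hypo] <- -1
    b[ent & !hypo] <- stats::runif(sum(ent & !hypo), 0.08, 0.25)
    sgn[ent & !hypo] <- +1
    b[!ent] <- stats::runif(sum(!ent), 0.30, 0.70)
    sgn[!ent] <- ifelse(b[!ent] >= 0.5, +1, -1)  # diverge from 0.5
    mag <- stats::runif(length(i_dmp), cfg$mean_slope_range[1],
                        cfg$mean_slope_range[2])
    # keep the full-span trajectory inside the feasible band
    room <- ifelse(sgn > 0, .MU_MAX - b, b - .MU_MIN) / span
    baseline[i_dmp] <- b
    slope[i_dmp] <- sgn * pmin(mag, room)
  }

  # precision schedule: baseline precision for every CpG; variance slope
  # (capped by the precision floor) for VMP-carrying CpGs
  phi0 <- stats::runif(n, 250, 400)
  vs <- numeric(n)
  i_vmp <- which(cls %in% c("VMP", "DMP-VMP"))
  if (length(i_vmp)) {
    b0 <- baseline[i_vmp]
    b1 <- pmin(pmax(b0 + slope[i_vmp] * span, .MU_MIN), .MU_MAX)
    mm0 <- b0 * (1 - b0)
    mm_min <- pmin(mm0, b1 * (1 - b1))
    floorv <- ifelse(b0 > 0.28 & b0 < 0.72 & b1 > 0.28 & b1 < 0.72,
                     .PHI_FLOOR_MID, .PHI_FLOOR_EXTREME)
    v0 <- mm0 / (phi0[i_vmp] + 1)
    vmax <- mm_min / (floorv + 1)
    target <- stats::runif(length(i_vmp), cfg$var_slope_range[1],
                           cfg$var_slope_range[2])
    vs[i_vmp] <- pmin(target, pmax((vmax - v0) / span, 0))
    if (any(vs[i_vmp] <= 0))
      stop("variance-slope planting infeasible for some VMPs; ",
           "loosen var_slope_range or baseline precision")
  }

  # covariate-affected CpGs: independent sparse indicator per covariate,
  # with a random sign
  cov_eff <- lapply(cfg$covariate_effects, function(e) {
    hit <- stats::runif(n) < cfg$frac_cov_affected
    ifelse(hit, sample(c(-1, 1), n, replace = TRUE) * e, 0)
  })

  # cell-identity markers come from the age-null class
  n_marker <- round(cfg$frac_markers * n)
  if (n_marker > length(i_none))
    stop("not enough age-null CpGs to host the requested marker fraction")
  i_marker <- sample(i_none, n_marker)
  marker_type <- integer(n)
  marker_type[i_marker] <- sample.int(cfg$n_celltypes, n_marker, replace = TRUE)

  cpg <- sprintf("cg%07d", seq_len(n))
  list(cpg = cpg, class = cls, baseline = baseline, slope = slope,
       var_slope = vs, phi0 = phi0, entropic = entropic,
       cov_eff = cov_eff, marker_type = marker_type)
}

# reference profile matrix for the marker CpGs: lowly methylated in the
# identity type, highly methylated in the others
.marker_profiles <- function(truth, n_celltypes) {
  i_marker <- which(truth$marker_type > 0)
  prof <- matrix(stats::runif(length(i_marker) * n_celltypes, 0.82, 0.95),
                 nrow = length(i_marker), ncol = n_celltypes)
  for (j in seq_along(i_marker))
    prof[j, truth$marker_type[i_marker[j]]] <- stats::runif(1, 0.05, 0.18)
  rownames(prof) <- truth$cpg[i_marker]
  colnames(prof) <- .celltype_names(n_celltypes)
  prof
}

.celltype_names <- function(k) {
  base <- c("Gran", "CD4T", "CD8T", "Bcell", "NK", "Mono")
  if (k <= 6) base[seq_len(k)] else c(base, paste0("CT", seq_len(k - 6)))
}

# whole-blood style base proportions
.base_props <- function(k) {
  base <- c(Gran = 0.58, CD4T = 0.15, CD8T = 0.08, Bcell = 0.05,
            NK = 0.06, Mono = 0.08)
  p <- if (k <= 6) base[seq_len(k)] else c(base, rep(0.02, k - 6))
  p / sum(p)
}

# Dirichlet draw via normalized gammas
.rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  g / rowSums(g)
}

#' Generate synthetic methylation cohorts with ground truth
#'
#' Draws, per cohort, per-CpG, per-sample methylation fractions from a Beta
#' distribution whose mean is age-linear on the raw scale
#' (\code{baseline + slope * (age - age_min)}) and whose precision for VMPs
#' decreases with age so that \code{Var(beta | age)} grows approximately
#' linearly at the planted variance slope. Covariate effects (sex, batch,
#' BMI) act on the logit scale at a sparse subset of CpGs. A fraction of
#' age-null CpGs are cell-identity markers whose bulk signal is a mixture of
#' cell-type profiles with per-sample leukocyte proportions (optionally
#' drifting with age, which plants composition confounding).
#'
#' @param config A [sim_config()] object.
#' @return A list with elements:
#'   \describe{
#'     \item{datasets}{list of [methyl_dataset()] cohorts,}
#'     \item{truth}{ground truth: \code{$cpgs} (per-CpG class, slopes,
#'       baseline, entropic flag, marker type), \code{$cell_fractions}
#'       (per-cohort type-by-sample proportion matrices),
#'       \code{$reference} (marker-CpG-by-type profile matrix),}
#'     \item{config}{the configuration used.}
#'   }
#' @examples
#' sim <- generate_cohorts(sim_config(n_datasets = 2, n_samples = 60,
#'                                    n_cpgs = 100, seed = 7))
#' sim$datasets[[1]]
#' table(sim$truth$cpgs$true_class)
#' @export
generate_cohorts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  amin <- config$age_range[1]
  tr <- .plant_truth(config)
  prof <- .marker_profiles(tr, config$n_celltypes)
  i_marker <- which(tr$marker_type > 0)
  p0 <- .base_props(config$n_celltypes)
  # drifting types gain proportion with age at the expense of the others
  drift <- rep(0, config$n_celltypes)
  names(drift) <- .celltype_names(config$n_celltypes)
  if (config$celltype_age_drift != 0) {
    up <- intersect(c("Gran", "Mono"), names(drift))
    drift[up] <- config$celltype_age_drift / length(up)
    dn <- setdiff(names(drift), up)
    drift[dn] <- -config$celltype_age_drift * p0[dn] / sum(p0[dn])
  }

  ns <- if (is.null(config$n_samples)) {
    round(stats::runif(config$n_datasets, config$n_samples_range[1],
                       config$n_samples_range[2]))
  } else {
    rep_len(config$n_samples, config$n_datasets)
  }

  datasets <- vector("list", config$n_datasets)
  fractions <- vector("list", config$n_datasets)
  for (d in seq_len(config$n_datasets)) {
    n <- ns[d]
    width <- stats::runif(1, config$age_window_width[1],
                          min(config$age_window_width[2], diff(config$age_range)))
    start <- stats::runif(1, config$age_range[1], config$age_range[2] - width)
    age <- stats::runif(n, start, start + width)
    sex <- factor(sample(c("F", "M"), n, replace = TRUE), levels = c("F", "M"))
    batch <- factor(sample(c("b1", "b2"), n, replace = TRUE),
                    levels = c("b1", "b2"))
    bmi <- stats::rnorm(n, 27, 4)

    da <- age - amin
    mu <- pmin(pmax(outer(tr$slope, da) + tr$baseline, .MU_MIN), .MU_MAX)
    eta <- stats::qlogis(mu)
    eta <- eta + outer(tr$cov_eff[["sex"]] %||% numeric(config$n_cpgs),
                       as.numeric(sex == "M") - 0.5)
    eta <- eta + outer(tr$cov_eff[["batch"]] %||% numeric(config$n_cpgs),
                       as.numeric(batch == "b2") - 0.5)
    eta <- eta + outer(tr$cov_eff[["bmi"]] %||% numeric(config$n_cpgs),
                       bmi - 27)
    mu <- stats::plogis(eta)

    mm0 <- tr$baseline * (1 - tr$baseline)
    v0 <- mm0 / (tr$phi0 + 1)
    is_v <- tr$var_slope > 0
    v <- matrix(v0, config$n_cpgs, n)
    # VMP CpGs: variance grows linearly with age at the planted slope.
    # All others: hold the M-scale residual variance constant along the mean
    # trajectory (beta-scale variance tracks (m(1-m))^2), so a mean drift
    # alone does not manufacture heteroscedasticity on the testing scale.
    v[is_v, ] <- v0[is_v] + outer(tr$var_slope[is_v], da)
    v[!is_v, ] <- v0[!is_v] * (mu[!is_v, , drop = FALSE] *
                               (1 - mu[!is_v, , drop = FALSE]) /
                               mm0[!is_v])^2
    phi <- pmax(mu * (1 - mu) / v - 1, 5)
    beta <- matrix(stats::rbeta(config$n_cpgs * n, mu * phi, (1 - mu) * phi),
                   config$n_cpgs, n)

    # cell-identity markers: bulk mixture of pure profiles
    pa <- pmax(outer(rep(1, n), p0) + outer(da, drift), 1e-4)
    pa <- pa / rowSums(pa)
    w <- t(.rdirichlet_rows(pa, 200))          # types x samples
    if (length(i_marker)) {
      bulk <- mix_celltypes(prof, w)
      bulk <- bulk + stats::rnorm(length(bulk), 0, 0.015)
      beta[i_marker, ] <- bulk
    }
    beta <- clip_beta(beta)

    did <- sprintf("d%02d", d)
    sample_meta <- data.frame(
      sample_id = sprintf("%s_s%04d", did, seq_len(n)),
      age = age, sex = sex, batch = batch, bmi = bmi, dataset = did,
      stringsAsFactors = FALSE)
    probe_meta <- data.frame(
      cpg = tr$cpg,
      chrom = sprintf("chr%d", 1 + (seq_len(config$n_cpgs) - 1) %% 22),
      start = 1000L * seq_len(config$n_cpgs),
      end = 1000L * seq_len(config$n_cpgs) + 1L,
      noncg = FALSE, multimap = FALSE, snp = FALSE, cross_reactive = FALSE,
      stringsAsFactors = FALSE)
    colnames(w) <- sample_meta$sample_id
    rownames(w) <- .celltype_names(config$n_celltypes)
    datasets[[d]] <- methyl_dataset(beta, sample_meta, probe_meta)
    fractions[[d]] <- w
  }
  names(datasets) <- sprintf("d%02d", seq_len(config$n_datasets))
  names(fractions) <- names(datasets)

  truth_cpgs <- data.frame(
    cpg = tr$cpg,
    true_class = tr$class,
    true_mean_slope = tr$slope,
    true_var_slope = tr$var_slope,
    true_baseline_mf = tr$baseline,
    true_entropic = tr$entropic,
    marker_type = ifelse(tr$marker_type > 0,
                         .celltype_names(config$n_celltypes)[tr$marker_type],
                         NA_character_),
    stringsAsFactors = FALSE)
  list(datasets = datasets,
       truth = list(cpgs = truth_cpgs, cell_fractions = fractions,
                    reference = prof),
       config = config)
}

# row-wise Dirichlet: row i drawn with concentration conc * target[i, ]
.rdirichlet_rows <- function(target, conc) {
  g <- matrix(stats::rgamma(length(target), shape = conc * target),
              nrow = nrow(target))
  g / rowSums(g)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mix pure cell-type methylation profiles into bulk signal
#'
#' Bulk methylation at a CpG is the proportion-weighted average of the
#' methylation of the constituent cell types:
#' \code{bulk = profiles \%*\% fractions}, clipped into the open unit
#' interval.
#'
#' @param pure_profiles Matrix, CpGs x cell types, values in \code{[0, 1]}.
#' @param fractions Matrix, cell types x samples; columns on the simplex
#'   (non-negative, summing to 1).
#' @return Bulk beta matrix, CpGs x samples.
#' @export
mix_celltypes <- function(pure_profiles, fractions) {
  pure_profiles <- as.matrix(pure_profiles)
  fractions <- as.matrix(fractions)
  if (ncol(pure_profiles) != nrow(fractions))
    stop("dimension mismatch: profiles have ", ncol(pure_profiles),
         " cell types but fractions have ", nrow(fractions))
  if (any(fractions < -1e-9))
    stop("fractions must be non-negative")
  if (any(abs(colSums(fractions) - 1) > 1e-6))
    stop("fraction columns must sum to 1")
  clip_beta(pure_profiles %*% fractions)
}

#' Generate a synthetic cell-type reference matrix
#'
#' Builds a marker-CpG-by-cell-type beta matrix in which each marker is lowly
#' methylated in its identity type and highly methylated elsewhere — the
#' signal structure reference-based deconvolution relies on. Labelled
#' synthetic: it emulates the shape of sorted-cell references, not any
#' measured one.
#'
#' @param n_markers Number of marker CpGs.
#' @param n_celltypes Number of cell types (default 6, whole-blood set).
#' @param low,high Ranges for the identity-type and other-type methylation.
#' @param seed Integer seed.
#' @return Matrix of beta values, markers x cell types.
#' @export
synthetic_reference <- function(n_markers = 120, n_celltypes = 6,
                                low = c(0.05, 0.18), high = c(0.82, 0.95),
                                seed = 1L) {
  set.seed(seed)
  prof <- matrix(stats::runif(n_markers * n_celltypes, high[1], high[2]),
                 n_markers, n_celltypes)
  idtype <- rep_len(seq_len(n_celltypes), n_markers)
  for (j in seq_len(n_markers))
    prof[j, idtype[j]] <- stats::runif(1, low[1], low[2])
  rownames(prof) <- sprintf("mk%05d", seq_len(n_markers))
  colnames(prof) <- .celltype_names(n_celltypes)
  prof
}
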