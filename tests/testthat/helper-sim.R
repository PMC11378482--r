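# small simulation configs and hand-built datasets shared across tests

small_sim <- function(..., seed = 1L) {
  generate_cohorts(sim_config(n_datasets = 2, n_samples = 120, n_cpgs = 150,
                              seed = seed, ...))
}

# a minimal dataset from a beta matrix and ages (plus optional covariates)
make_ds <- function(beta, age, ...) {
  beta <- as.matrix(beta)
  sm <- data.frame(sample_id = sprintf("s%04d", seq_len(ncol(beta))),
                   age = age, ...)
  pm <- data.frame(cpg = sprintf("cg%05d", seq_len(nrow(beta))),
                   chrom = "chr1",
                   start = seq_len(nrow(beta)) * 100L,
                   end = seq_len(nrow(beta)) * 100L + 1L)
  methyl_dataset(beta, sm, pm)
}

# map generator truth classes onto the classifier's joint labels
truth_joint <- function(true_class) {
  c(DMP = "homoscedastic_DMP", `DMP-VMP` = "DMP_VMP",
    VMP = "constant_VMP", none = "none")[true_class]
}

# n x k Dirichlet draws (normalized gammas), for mixture fixtures
.rdirichlet_compat <- function(n, alpha) {
  g <- matrix(rgamma(n * length(alpha), shape = rep(alpha, each = n)),
              nrow = n)
  g / rowSums(g)
}

# run the standard per-cohort EWAS + meta pass used in several tests
ewas_meta <- function(datasets, covariates = c("sex", "batch", "bmi"),
                      adjust = TRUE) {
  mrec <- lapply(datasets, function(d) {
    r <- fit_mean_ewas(d, covariates)
    if (adjust) {
      r <- empirical_null_adjust(r, "effect_beta", "se_beta")
      r <- empirical_null_adjust(r, "effect_m", "se_m")
    }
    r
  })
  vrec <- lapply(datasets, fit_variance_ewas, covariates = covariates)
  list(mean = mrec, var = vrec,
       meta_mean = meta_ewas_mean(mrec, min_datasets = min(3, length(datasets))),
       meta_var = meta_ewas_variance(vrec))
}
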