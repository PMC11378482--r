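test_that("the generator is fully determined by its seed", {
  a <- small_sim(seed = 9)
  b <- small_sim(seed = 9)
  expect_identical(a$datasets[[1]]$beta, b$datasets[[1]]$beta)
  expect_identical(a$truth$cpgs, b$truth$cpgs)
  c_ <- small_sim(seed = 10)
  expect_false(identical(a$datasets[[1]]$beta, c_$datasets[[1]]$beta))
})

test_that("config invariants are enforced", {
  expect_error(sim_config(frac_dmp = 1.2), "fractions")
  expect_error(sim_config(age_range = c(50, 50)), "age max")
  expect_error(sim_config(n_samples = 0), "n_samples")
  expect_error(sim_config(mean_slope_range = c(0.001, 0.02)),
               "exits \\(0,1\\)")
  # overlap cannot exceed the VMP budget
  expect_error(generate_cohorts(sim_config(frac_dmp = 0.9, frac_vmp = 0.1,
                                           frac_overlap = 0.9)),
               "inconsistent class sizes")
})

test_that("ground truth is internally consistent", {
  sim <- small_sim(seed = 3)
  tr <- sim$truth$cpgs
  expect_true(all((tr$true_mean_slope != 0) ==
                    (tr$true_class %in% c("DMP", "DMP-VMP"))))
  expect_true(all((tr$true_var_slope > 0) ==
                    (tr$true_class %in% c("VMP", "DMP-VMP"))))
  expect_true(all(is.na(tr$true_entropic[!tr$true_class %in%
                                           c("DMP", "DMP-VMP")])))
  # entropic flag matches the planted slope direction relative to 0.5
  i <- which(!is.na(tr$true_entropic))
  toward <- (tr$true_baseline_mf[i] < 0.5) == (tr$true_mean_slope[i] > 0)
  expect_identical(unname(toward), unname(tr$true_entropic[i]))
  # cell fractions on the simplex
  w <- sim$truth$cell_fractions[[1]]
  expect_true(all(w >= 0))
  expect_equal(unname(colSums(w)), rep(1, ncol(w)), tolerance = 1e-12)
  # betas strictly inside (0,1), ages inside the configured range
  expect_true(all(sim$datasets[[1]]$beta > 0 & sim$datasets[[1]]$beta < 1))
  ages <- sim$datasets[[1]]$sample_meta$age
  expect_true(all(ages >= 20 & ages <= 90))
})

test_that("null configuration yields uniform mean-EWAS p-values", {
  sim <- generate_cohorts(sim_config(n_datasets = 1, n_samples = 200,
                                     n_cpgs = 600, frac_dmp = 0,
                                     frac_vmp = 0, seed = 21))
  expect_true(all(sim$truth$cpgs$true_class == "none"))
  rec <- fit_mean_ewas(sim$datasets[[1]], c("sex", "batch", "bmi"))
  ks <- suppressWarnings(ks.test(rec$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("generated mean slopes are recovered by OLS", {
  # constant planted slope of 0.3% per year; OLS on beta values should land
  # within 3 SE of the generating value
  sim <- generate_cohorts(sim_config(
    n_datasets = 1, n_samples = 500, n_cpgs = 40, frac_dmp = 1,
    frac_vmp = 0, frac_overlap = 0, frac_markers = 0,
    mean_slope_range = c(3e-3, 3e-3), frac_cov_affected = 0, seed = 5))
  ds <- sim$datasets[[1]]
  tr <- sim$truth$cpgs
  rec <- fit_mean_ewas(ds, moderate = FALSE)
  z <- abs(rec$effect_beta - tr$true_mean_slope) / rec$se_beta
  expect_gt(mean(z <= 3), 0.95)
})

test_that("detection power increases with the planted slope magnitude", {
  power_at <- function(s) {
    sim <- generate_cohorts(sim_config(
      n_datasets = 1, n_samples = 250, n_cpgs = 200, frac_dmp = 0.5,
      frac_vmp = 0, frac_overlap = 0, mean_slope_range = c(s, s),
      frac_markers = 0, seed = 33))
    rec <- fit_mean_ewas(sim$datasets[[1]], c("sex", "batch", "bmi"))
    dmp <- sim$truth$cpgs$true_class == "DMP"
    mean(rec$p[dmp] < 0.05)
  }
  pw <- vapply(c(5e-5, 2e-4, 8e-4), power_at, numeric(1))
  expect_true(all(diff(pw) > 0))
})

test_that("planted VMPs gain variance from the youngest to oldest tertile", {
  sim <- generate_cohorts(sim_config(
    n_datasets = 1, n_samples = 300, n_cpgs = 200, frac_dmp = 0,
    frac_vmp = 0.5, age_window_width = c(55, 65), seed = 8))
  ds <- sim$datasets[[1]]
  age <- ds$sample_meta$age
  young <- age <= quantile(age, 1 / 3)
  old <- age >= quantile(age, 2 / 3)
  vmp <- sim$truth$cpgs$true_class == "VMP"
  v_y <- apply(ds$beta[vmp, young], 1, var)
  v_o <- apply(ds$beta[vmp, old], 1, var)
  expect_gt(mean(v_o > v_y), 0.9)
  expect_gt(mean(v_o - v_y), 0)
})

test_that("cell-type mixing is the exact proportion-weighted average", {
  prof <- matrix(c(0.1, 0.9, 0.2, 0.8), nrow = 2,
                 dimnames = list(c("cgA", "cgB"), c("t1", "t2")))
  onehot <- diag(2)
  expect_equal(unname(mix_celltypes(prof, onehot)), unname(prof))
  half <- matrix(c(0.5, 0.5), 2, 1)
  expect_equal(unname(mix_celltypes(matrix(c(0.1, 0.9), 1), half))[1, 1], 0.5)
  expect_error(mix_celltypes(prof, matrix(1, 3, 1)), "dimension mismatch")
  expect_error(mix_celltypes(prof, matrix(c(0.7, 0.7), 2, 1)), "sum to 1")
})
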