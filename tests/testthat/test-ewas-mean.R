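test_that("a noiseless linear CpG is recovered exactly", {
  age <- seq(20, 80, length.out = 50)
  M <- rbind(0.05 * age - 2, -0.02 * age + 1)
  ds <- make_ds(m_to_beta(M), age)
  rec <- fit_mean_ewas(ds, moderate = FALSE)
  expect_equal(rec$effect_m, c(0.05, -0.02), tolerance = 1e-10)
  expect_true(all(rec$p < 1e-30))
})

test_that("unmoderated statistics match a normal-equations OLS oracle", {
  set.seed(41)
  n <- 60
  age <- runif(n, 20, 85)
  bmi <- rnorm(n, 27, 3)
  beta <- matrix(runif(40 * n, 0.05, 0.95), 40, n)
  ds <- make_ds(beta, age, bmi = bmi)
  rec <- fit_mean_ewas(ds, "bmi", moderate = FALSE)
  X <- cbind(1, age, bmi)
  M <- beta_to_m(clip_beta(beta))
  XtXi <- solve(t(X) %*% X)
  for (i in c(1, 17, 40)) {
    bh <- XtXi %*% t(X) %*% M[i, ]
    res <- M[i, ] - X %*% bh
    s2 <- sum(res^2) / (n - 3)
    se <- sqrt(s2 * XtXi[2, 2])
    expect_equal(rec$effect_m[i], bh[2], tolerance = 1e-8)
    expect_equal(rec$se_m[i], se, tolerance = 1e-8)
    expect_equal(rec$t[i], bh[2] / se, tolerance = 1e-8)
  }
})

test_that("moderated statistics agree with an independent limma fit", {
  sim <- small_sim(seed = 14)
  ds <- sim$datasets[[1]]
  rec <- fit_mean_ewas(ds, c("sex", "bmi"))
  X <- model.matrix(~ age + sex + bmi, ds$sample_meta)
  fit <- limma::eBayes(limma::lmFit(beta_to_m(clip_beta(ds$beta)), X))
  expect_equal(rec$t, fit$t[, "age"], tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(rec$p, fit$p.value[, "age"], tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("moderated and unmoderated inference converge at large n", {
  set.seed(7)
  n <- 5000
  age <- runif(n, 20, 80)
  # heterogeneous residual scales so the shrinkage prior stays finite
  sds <- runif(100, 0.1, 1)
  M <- matrix(rnorm(100 * n, 0, sds), 100, n)
  ds <- make_ds(m_to_beta(M), age)
  p_mod <- fit_mean_ewas(ds)$p
  p_raw <- fit_mean_ewas(ds, moderate = FALSE)$p
  expect_lt(max(abs(p_mod - p_raw)), 0.01)
})

test_that("age-permuted data give calibrated p-values", {
  sim <- generate_cohorts(sim_config(n_datasets = 1, n_samples = 150,
                                     n_cpgs = 500, seed = 19))
  ds <- sim$datasets[[1]]
  set.seed(20)
  ds$sample_meta$age <- sample(ds$sample_meta$age)
  rec <- fit_mean_ewas(ds, c("sex", "batch", "bmi"))
  frac <- mean(rec$p < 0.05)
  bound <- 2.576 * sqrt(0.05 * 0.95 / 500)
  expect_lt(abs(frac - 0.05), bound)
})

test_that("M-scale and beta-scale effects agree in sign away from 0/1", {
  sim <- small_sim(seed = 4)
  rec <- fit_mean_ewas(sim$datasets[[1]], c("sex", "batch", "bmi"))
  mid <- rowMeans(sim$datasets[[1]]$beta)
  i <- mid > 0.01 & mid < 0.99 & abs(rec$t) > 2
  expect_true(all(sign(rec$effect_m[i]) == sign(rec$effect_beta[i])))
})

test_that("design problems are rejected with informative errors", {
  age <- seq(20, 80, length.out = 30)
  ds <- make_ds(matrix(runif(60), 2, 30), age, age2 = age)
  expect_error(fit_mean_ewas(ds, "age2"), "collinear.*age2")
  ds2 <- make_ds(matrix(runif(8), 2, 4), c(20, 30, 40, 50))
  expect_error(fit_mean_ewas(ds2), "too few samples")
  expect_error(fit_mean_ewas(make_ds(matrix(0.5, 2, 30), age), "nope"),
               "absent from sample metadata")
})

test_that("the empirical null recovers known bias and inflation", {
  set.seed(101)
  z0 <- rnorm(5000)
  null0 <- estimate_empirical_null(z0)
  expect_lt(abs(null0["bias"]), 0.05)
  expect_lt(abs(null0["inflation"] - 1), 0.05)
  z1 <- rnorm(5000, 0.5, 1.4)
  null1 <- estimate_empirical_null(z1)
  expect_lt(abs(null1["bias"] - 0.5), 0.05)
  expect_lt(abs(null1["inflation"] - 1.4), 0.05)
})

test_that("empirical-null adjustment is invariant to a constant z shift", {
  set.seed(55)
  rec <- data.frame(cpg = sprintf("cg%03d", 1:500),
                    effect_m = rnorm(500, 0, 0.02), se_m = rep(0.01, 500))
  a <- empirical_null_adjust(rec)
  shifted <- rec
  shifted$effect_m <- shifted$effect_m + 3 * shifted$se_m  # z + 3
  b <- empirical_null_adjust(shifted)
  expect_equal(a$t, b$t, tolerance = 1e-10)
  expect_equal(a$p, b$p, tolerance = 1e-10)
  expect_error(empirical_null_adjust(rec[1:50, ]), "at least 100")
})
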