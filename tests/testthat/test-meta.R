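test_that("inverse-variance pooling matches closed-form arithmetic", {
  m <- meta_inverse_variance(c(1, 3), c(1, 1))
  expect_equal(m$pooled_effect, 2)
  expect_equal(m$pooled_se, 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(m$Q, 2)
  # identical studies: no heterogeneity
  m2 <- meta_inverse_variance(rep(0.7, 4), rep(0.2, 4))
  expect_equal(m2$pooled_effect, 0.7)
  expect_equal(m2$Q, 0)
  expect_equal(m2$I2, 0)
  # degenerate single study
  m3 <- meta_inverse_variance(1.5, 0.3)
  expect_equal(m3$pooled_effect, 1.5)
  expect_true(m3$k1)
  expect_equal(m3$I2, 0)
  expect_error(meta_inverse_variance(c(1, 2), c(1, 0)), "positive")
})

test_that("inverse-variance pooling equals a weighted-least-squares oracle", {
  set.seed(91)
  for (i in 1:100) {
    k <- sample(2:8, 1)
    e <- rnorm(k)
    se <- runif(k, 0.1, 2)
    m <- meta_inverse_variance(e, se)
    wls <- lm(e ~ 1, weights = 1 / se^2)
    expect_equal(m$pooled_effect, unname(coef(wls)), tolerance = 1e-10)
    expect_lte(m$pooled_se, min(se))  # pooling never loses information
  }
})

test_that("inverse-variance pooling agrees with metafor fixed effects", {
  skip_if_not_installed("metafor")
  set.seed(92)
  e <- rnorm(6, 0.3, 0.5)
  se <- runif(6, 0.1, 0.6)
  m <- meta_inverse_variance(e, se)
  rma <- metafor::rma(yi = e, sei = se, method = "FE")
  expect_equal(m$pooled_effect, as.numeric(rma$beta), tolerance = 1e-8)
  expect_equal(m$pooled_se, rma$se, tolerance = 1e-8)
  expect_equal(m$Q, rma$QE, tolerance = 1e-8)
})

test_that("sample-size pooling follows the signed Stouffer formula", {
  p <- 2 * pnorm(1.96, lower.tail = FALSE)
  m <- meta_sample_size(c(p, p), c(1, 1), c(100, 100))
  expect_equal(m$z, 1.96 * sqrt(2), tolerance = 1e-4)
  # opposite directions cancel exactly at equal n
  m2 <- meta_sample_size(c(p, p), c(1, -1), c(50, 50))
  expect_equal(m2$z, 0)
  # single study passes through
  m3 <- meta_sample_size(0.01, -1, 80)
  expect_equal(m3$z, -qnorm(1 - 0.005), tolerance = 1e-10)
  # equal n reduces to the unweighted mean of z over sqrt(k)
  set.seed(8)
  ps <- runif(5, 1e-6, 0.9)
  dir <- sample(c(-1, 1), 5, replace = TRUE)
  m4 <- meta_sample_size(ps, dir, rep(200, 5))
  z_i <- dir * qnorm(1 - ps / 2)
  expect_equal(m4$z, sum(z_i) / sqrt(5), tolerance = 1e-10)
  expect_warning(meta_sample_size(c(0, 0.5), c(1, 1), c(10, 10)), "clamped")
  expect_error(meta_sample_size(c(0.5, 0.5), c(1, 0), c(10, 10)), "nonzero")
})

test_that("log-p pooling avoids the p-value floor", {
  # two huge chi-square statistics whose p underflows double precision
  lp <- pchisq(c(400, 420), df = 1, lower.tail = FALSE, log.p = TRUE)
  m <- meta_sample_size(p = NULL, direction = c(1, 1), n = c(500, 500),
                        log_p = lp)
  expect_true(is.finite(m$z) && m$z > 25)
  expect_true(m$log_p < -300)  # carried in log space, no 2.2e-16 ceiling
})

test_that("presence rules follow the dataset-count and coverage contracts", {
  expect_false(presence_filter(2, 500, 1000, "mean"))
  expect_true(presence_filter(3, 500, 1000, "mean"))
  expect_false(presence_filter(5, 149, 1000, "variance"))
  expect_true(presence_filter(1, 150, 1000, "variance"))
})

test_that("BH q-values match the step-up computation", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(numeric(0)), numeric(0))
  expect_false(any(call_significant(bh_fdr(rep(1, 5)))))
  # q >= p always
  set.seed(3)
  p <- runif(50)
  expect_true(all(bh_fdr(p) >= p))
})

test_that("per-CpG meta tables equal a direct per-CpG loop", {
  sim <- small_sim(seed = 17)
  res <- ewas_meta(sim$datasets, adjust = FALSE)
  # mean mode: pick CpGs and rebuild from the per-dataset records
  for (cg in res$meta_mean$cpg[c(1, 50, 120)]) {
    e <- vapply(res$mean, function(r) r$effect_m[r$cpg == cg], numeric(1))
    se <- vapply(res$mean, function(r) r$se_m[r$cpg == cg], numeric(1))
    direct <- meta_inverse_variance(e, se)
    row <- res$meta_mean[res$meta_mean$cpg == cg, ]
    expect_equal(row$pooled_effect, direct$pooled_effect, tolerance = 1e-10)
    expect_equal(row$z, direct$z, tolerance = 1e-10)
    expect_equal(row$Q, direct$Q, tolerance = 1e-8)
  }
  # variance mode
  ok_cpgs <- res$meta_var$cpg[c(1, 30)]
  for (cg in ok_cpgs) {
    recs <- lapply(res$var, function(r) r[r$cpg == cg & !r$filtered, ])
    recs <- do.call(rbind, recs)
    direct <- meta_sample_size(p = NULL, direction = recs$direction,
                               n = recs$n, log_p = recs$log_p)
    row <- res$meta_var[res$meta_var$cpg == cg, ]
    expect_equal(row$z, direct$z, tolerance = 1e-10)
  }
})
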