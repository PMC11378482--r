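test_that("entropy hits its endpoints and known values", {
  expect_identical(shannon_entropy(rep(0.5, 1000)), 1)
  expect_identical(shannon_entropy(rep(c(0, 1), 500)), 0)
  expect_identical(shannon_entropy(c(0, 1, 1, 0)), 0)
  # single CpG at 0.25: the binary entropy function
  h025 <- -(0.25 * log2(0.25) + 0.75 * log2(0.75))
  expect_equal(shannon_entropy(0.25), h025, tolerance = 1e-12)
  expect_equal(shannon_entropy(0.25), 0.811278, tolerance = 1e-6)
  expect_error(shannon_entropy(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(shannon_entropy(numeric(0)), "at least one")
})

test_that("entropy is a permutation-invariant mean over CpGs", {
  set.seed(2)
  mf <- runif(200)
  expect_equal(shannon_entropy(mf), shannon_entropy(sample(mf)))
  # disjoint-union linearity: H(A u B) is the size-weighted mean
  a <- runif(150)
  b <- runif(50)
  expect_equal(shannon_entropy(c(a, b)),
               (150 * shannon_entropy(a) + 50 * shannon_entropy(b)) / 200,
               tolerance = 1e-12)
  # moving every CpG toward 0.5 raises entropy monotonically
  path <- vapply(seq(0, 1, 0.1), function(t)
    shannon_entropy(mf + t * (0.5 - mf)), numeric(1))
  expect_true(all(diff(path) > 0))
})

test_that("covariate adjustment reconstructs data when there is nothing to remove", {
  sim <- small_sim(seed = 6)
  ds <- sim$datasets[[1]]
  adj <- adjusted_betas(ds)
  expect_equal(adj, clip_beta(ds$beta), tolerance = 1e-12)
  expect_error(adjusted_betas(ds, c("age", "sex")), "age must not")
})

test_that("a balanced additive batch effect is removed exactly", {
  set.seed(23)
  n <- 100
  age <- runif(n, 20, 80)
  batch <- factor(rep(c("b1", "b2"), each = n / 2))
  M <- matrix(rnorm(30 * n, 0, 0.3), 30, n)
  M_batched <- M + matrix(rep(as.numeric(batch == "b2"), each = 30), 30, n)
  ds <- make_ds(m_to_beta(M_batched), age, batch = batch)
  adj <- adjusted_betas(ds, "batch")
  adj_m <- beta_to_m(adj)
  gap <- rowMeans(adj_m[, batch == "b2"]) - rowMeans(adj_m[, batch == "b1"])
  expect_lt(max(abs(gap)), 1e-8)
  # adjusted values always respect the (0,1) bounds
  extreme <- make_ds(matrix(runif(20 * 10, 0.9999, 1 - 1e-7), 20, 10),
                     seq(20, 80, length.out = 10),
                     batch = factor(rep(c("b1", "b2"), 5)))
  adj2 <- adjusted_betas(extreme, "batch")
  expect_true(all(adj2 > 0 & adj2 < 1))
})

test_that("the entropy-age slope is reported per decade", {
  age <- seq(20, 80, length.out = 60)
  ent <- 0.5 + 5e-5 * age        # exactly linear, 5e-5 per year
  sl <- entropy_vs_age(ent + rnorm(60, 0, 1e-9), age)
  expect_equal(sl$slope_per_decade, 5e-4, tolerance = 1e-4)
  # degenerate constant entropy
  sl2 <- entropy_vs_age(rep(0.4, 60), age)
  expect_true(sl2$degenerate)
  expect_equal(sl2$slope_per_decade, 0)
})

test_that("age-permuted entropy gives calibrated regression p-values", {
  set.seed(44)
  p <- replicate(150, {
    age <- runif(40, 20, 80)
    entropy_vs_age(runif(40, 0.3, 0.5), age)$p
  })
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("subset entropies respect identity and pinning", {
  sim <- small_sim(seed = 13)
  ds <- sim$datasets[[1]]
  all_cpgs <- rownames(ds$beta)
  es <- entropy_by_subset(ds, list(gw = all_cpgs, half = all_cpgs[1:75]))
  gw <- es$entropy[es$subset == "gw"]
  manual <- apply(clip_beta(ds$beta), 2, shannon_entropy)
  expect_equal(gw, unname(manual), tolerance = 1e-12)
  # a subset pinned at 0.5 scores 1 for every sample
  ds$beta[1:10, ] <- 0.5
  es2 <- entropy_by_subset(ds, list(pinned = all_cpgs[1:10]))
  expect_true(all(es2$entropy == 1))
  expect_error(entropy_by_subset(ds, list(bad = character(0))), "empty")
  expect_error(entropy_by_subset(ds, list(bad = "cg_nope")), "absent")
})

test_that("converging DMPs raise entropy faster than the genome-wide set", {
  sim <- generate_cohorts(sim_config(n_datasets = 3, n_samples = 200,
                                     n_cpgs = 400, seed = 27))
  tr <- sim$truth$cpgs
  subs <- list(genome_wide = tr$cpg,
               entropic = tr$cpg[which(tr$true_entropic)],
               non_age = tr$cpg[tr$true_class == "none"])
  ea <- entropy_analysis(sim$datasets, subs, covariates = c("sex", "batch"))
  slopes <- setNames(ea$meta$pooled_effect, ea$meta$subset)
  expect_gt(slopes["entropic"], 0)
  expect_gt(slopes["entropic"], slopes["genome_wide"])
  expect_lt(abs(slopes["non_age"]), abs(slopes["entropic"]))
})
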