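test_that("generators are pure functions of (config, seed)", {
  cfg <- sim_config(n_neutral_loci = 100, n_adaptive_loci = 5, seed = 9)
  a <- simulate_genotypes(cfg)
  b <- simulate_genotypes(cfg)
  expect_identical(a$dataset$dosage, b$dataset$dosage)
  expect_identical(a$truth$env, b$truth$env)
  cfg2 <- sim_config(n_neutral_loci = 100, n_adaptive_loci = 5, seed = 10)
  expect_false(identical(a$dataset$dosage,
                         simulate_genotypes(cfg2)$dataset$dosage))
  expect_identical(simulate_climate(cfg), simulate_climate(cfg))
  expect_identical(simulate_rings(cfg)$rings, simulate_rings(cfg)$rings)
})

test_that("SimTruth covers every sample and locus; missingness matches", {
  cfg <- sim_config(n_neutral_loci = 300, n_adaptive_loci = 10,
                    missing_rate = 0.05, seed = 2)
  sim <- simulate_genotypes(cfg)
  ds <- sim$dataset
  expect_setequal(names(sim$truth$locus_class), ds$loci$id)
  expect_setequal(rownames(sim$truth$ancestry), ds$samples)
  expect_true(all(rowSums(sim$truth$ancestry) == 1))
  expect_equal(sum(sim$truth$locus_class == "adaptive"), 10)
  expect_true(all(sim$truth$effect[sim$truth$locus_class == "neutral"] == 0))
  expect_equal(mean(is.na(ds$dosage)), 0.05, tolerance = 0.15)
  expect_error(simulate_genotypes(
    sim_config(demes_per_group = 1, n_groups = 1, samples_per_deme = 2,
               n_related_pairs = 5)), "infeasible")
})

test_that("panmixia yields global Weir-Cockerham FST near zero", {
  cfg <- sim_config(n_groups = 2, demes_per_group = 4, samples_per_deme = 15,
                    n_neutral_loci = 800, n_adaptive_loci = 0,
                    F_CT = 0, F_SC = 0, missing_rate = 0, seed = 21)
  sim <- simulate_genotypes(cfg)
  fr <- wc_fst(sim$dataset)
  expect_lt(abs(fr$global), 0.01)
})

test_that("mean per-locus FST recovers the nominal value (beta-binomial oracle)", {
  cfg <- sim_config(n_groups = 2, demes_per_group = 8, samples_per_deme = 10,
                    n_neutral_loci = 1000, n_adaptive_loci = 0,
                    F_CT = 0, F_SC = 0.1, missing_rate = 0, seed = 31)
  sim <- simulate_genotypes(cfg)
  fst_pkg <- wc_fst(sim$dataset)$fst
  fst_pkg <- fst_pkg[!is.na(fst_pkg)]
  fst_or <- oracle_bn_mean_fst(n_loci = 1500, n_demes = 16, n_per_deme = 10,
                               F = 0.1, seed = 77)
  se <- sqrt(var(fst_pkg) / length(fst_pkg) + var(fst_or) / length(fst_or))
  expect_lt(abs(mean(fst_pkg) - mean(fst_or)), 3 * se + 0.005)
})

test_that("planted parent-offspring pairs estimate kinship near 0.25", {
  # near-panmictic world: the pedigree expectation phi = 0.25 assumes the
  # reference allele frequencies are unconfounded by structure
  cfg <- sim_config(n_groups = 1, demes_per_group = 4, samples_per_deme = 12,
                    n_neutral_loci = 1200, n_adaptive_loci = 0,
                    F_CT = 0, F_SC = 0.02, missing_rate = 0,
                    n_related_pairs = 3, seed = 13)
  sim <- simulate_genotypes(cfg)
  kin <- ibd_kinship(sim$dataset)
  rp <- sim$truth$related_pairs
  for (i in seq_len(nrow(rp))) {
    phi <- kin$phi[rp$parent[i], rp$offspring[i]]
    expect_gt(phi, 0.2)
    expect_lt(phi, 0.3)
  }
})

test_that("climate table has the tuned low-rank latent structure", {
  cfg <- sim_config(seed = 5)
  cl <- simulate_climate(cfg)
  expect_equal(dim(cl), c(16L, 247L))
  pcs <- climate_pca(cl)
  frac12 <- 100 * sum(pcs$explained[1:2])
  expect_gt(frac12, 70)
  expect_lt(frac12, 90)
  # noise -> 0: exactly rank 4
  cl0 <- simulate_climate(cfg, noise_sd = 1e-9)
  p0 <- climate_pca(cl0, n_components = 4)
  expect_equal(sum(p0$explained[1:4]), 1, tolerance = 1e-9)
  # PCA eigenvalues are invariant to row permutation
  perm <- sample(nrow(cl))
  expect_equal(climate_pca(cl[perm, ])$explained, pcs$explained,
               tolerance = 1e-12)
  # latent axis 1 is the genotype simulator's gradient: PC1 recovers it
  sim <- simulate_genotypes(sim_config(seed = 5, n_neutral_loci = 10))
  e <- sim$truth$env[rownames(pcs$scores)]
  expect_gt(abs(cor(pcs$scores[, 1], e)), 0.95)
})

test_that("ring series carry the planted sensitivity cline", {
  cfg <- sim_config(seed = 3)
  rr <- simulate_rings(cfg)
  expect_true(all(rr$rings$earlywood >= 0))
  expect_true(all(rr$rings$total >= rr$rings$earlywood))
  sp <- split(rr$rings$year, rr$rings$tree)
  expect_true(all(vapply(sp, function(y) all(diff(sort(y)) == 1),
                         logical(1))))
  # deterministic signal: no noise, beta = 0.4 -> response ~ 1, significant
  rr0 <- simulate_rings(cfg, c0 = 0.4, c1 = 0, noise_sd = 1e-8,
                        year_effect_sd = 0, trees_per_prov = 4)
  tr0 <- response_cline_traits(rr0$rings, rr0$site_climate, n_boot = 200,
                               seed = 1)
  # Pearson r of the monotone (exponential) transform sits just below 1
  expect_true(all(tr0$coef > 0.9))
  expect_true(all(tr0$significant))
  # c1 = 0: cline regression is null-calibrated (few significant replicates)
  sig <- vapply(1:12, function(s) {
    cfgs <- sim_config(seed = 100 + s)
    r <- simulate_rings(cfgs, c1 = 0, trees_per_prov = 5)
    tr <- response_cline_traits(r$rings, r$site_climate, n_boot = 50,
                                seed = s)
    e <- simulate_genotypes(
      sim_config(seed = 100 + s, n_neutral_loci = 10))$truth$env
    cline_regression(setNames(tr$coef, tr$provenance), e)$p < 0.05
  }, logical(1))
  expect_lte(mean(sig), 0.25)
  # default c1 > 0: recovered coefficients correlate positively with source
  # environment in nearly all replicates
  pos <- vapply(1:10, function(s) {
    cfgs <- sim_config(seed = 200 + s)
    r <- simulate_rings(cfgs, trees_per_prov = 5)
    tr <- response_cline_traits(r$rings, r$site_climate, n_boot = 50,
                                seed = s)
    e <- simulate_genotypes(
      sim_config(seed = 200 + s, n_neutral_loci = 10))$truth$env
    cor(tr$coef, e[tr$provenance]) > 0
  }, logical(1))
  expect_gte(sum(pos), 9)
})
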