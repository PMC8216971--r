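# helper: build a dataset from a dosage matrix with generic metadata
make_ds <- function(d, prov = NULL) {
  d <- as.matrix(d)
  samples <- sprintf("s%02d", seq_len(nrow(d)))
  if (is.null(prov)) prov <- rep("p1", nrow(d))
  loci <- data.frame(id = sprintf("l%03d", seq_len(ncol(d))),
                     scaffold = "sc1", position = seq_len(ncol(d)),
                     ref = "A", alt = "T")
  genotype_dataset(d, samples, loci, setNames(prov, samples))
}

test_that("qc defaults match the strict published filter settings", {
  cfg <- qc_config()
  expect_equal(cfg$maf_min, 0.05)
  expect_equal(cfg$site_callrate_min, 0.95)
  expect_equal(cfg$hwe_alpha, 1e-6)
  expect_equal(cfg$ld_r_max, 0.2)
  expect_equal(cfg$kinship_max, 0.25)
  expect_equal(cfg$het_deficit_max, 0.1)
  expect_equal(cfg$sample_callrate_min, 0.95)
  expect_equal(cfg$neutral_subset_size, 1500L)
})

test_that("site filters remove engineered MAF and call-rate failures", {
  set.seed(4)
  n <- 40
  d <- matrix(rbinom(n * 20, 2, 0.4), n, 20)
  # 4 low-MAF loci, 3 low-call-rate loci
  d[, 1:4] <- 0L; d[1, 1:4] <- 1L                  # MAF 1/80 < 0.05
  d[seq_len(ceiling(0.06 * n) + 1), 5:7] <- NA     # call rate < 0.95
  ds <- make_ds(d)
  res <- site_filters(ds, qc_config())
  expect_equal(res$report$n_removed, 7)
  expect_equal(nrow(res$dataset$loci), 13)
  expect_equal(res$report$n_in - res$report$n_removed, res$report$n_out)
  # MAF 0.125 on 4 samples is retained at maf_min 0.05
  ds2 <- make_ds(rbind(c(0), c(0), c(0), c(1)))
  expect_equal(nrow(site_filters(ds2,
    qc_config(site_callrate_min = 0.5))$dataset$loci), 1)
  # removing everything is an explicit error
  expect_error(site_filters(make_ds(matrix(0L, 10, 3)), qc_config()),
               "all loci")
})

test_that("hwe_exact_test matches full enumeration", {
  # worked example: 2 individuals, both het -> only configurations are
  # {2 het} (prob 2/3) and {1 hom each} (prob 1/3); p = 1
  expect_equal(hwe_exact_test(0, 2, 0), 1)
  expect_equal(oracle_hwe_exact(0, 2, 0), 1)
  # monomorphic
  expect_equal(hwe_exact_test(5, 0, 0), 1)
  expect_equal(hwe_exact_test(0, 0, 7), 1)
  # random counts up to n = 50
  set.seed(11)
  for (i in 1:300) {
    n <- sample(1:50, 1)
    cnt <- as.vector(rmultinom(1, n, prob = runif(3)))
    expect_equal(hwe_exact_test(cnt[1], cnt[2], cnt[3]),
                 oracle_hwe_exact(cnt[1], cnt[2], cnt[3]),
                 tolerance = 1e-12)
  }
  # strong Wahlund deficit is detected
  expect_lt(hwe_exact_test(60, 5, 60), 1e-6)
})

test_that("ld_prune keeps one of duplicated loci and respects the threshold", {
  set.seed(7)
  base <- matrix(rbinom(60 * 30, 2, 0.5), 60, 30)
  d <- cbind(base, base[, 3])  # duplicate of locus 3 (r = 1)
  ds <- make_ds(d)
  kept <- ld_prune(ds, qc_config())
  expect_true(xor("l003" %in% kept, "l031" %in% kept))
  # post-hoc property: every retained within-window pair has |r| <= 0.2
  dd <- ds$dosage[, kept]
  ord <- order(match(kept, ds$loci$id))
  r <- suppressWarnings(cor(dd, use = "pairwise.complete.obs"))
  diag(r) <- 0
  w <- qc_config()$ld_window
  for (i in seq_along(kept)) {
    js <- seq(max(1, i - w), i - 1)
    if (length(js) && i > 1)
      expect_true(all(abs(r[i, js]) <= 0.2 + 1e-12))
  }
  # independent loci with tiny sample correlation are all retained
  set.seed(8)
  big <- matrix(rbinom(5000 * 10, 2, 0.5), 5000, 10)
  ds2 <- make_ds(big)
  expect_equal(length(ld_prune(ds2, qc_config())), 10)
})

test_that("ibd_kinship: self comparisons, unrelated pairs, overlap flag", {
  cfg <- sim_config(n_groups = 1, demes_per_group = 2, samples_per_deme = 10,
                    n_neutral_loci = 1000, n_adaptive_loci = 0,
                    F_CT = 0, F_SC = 0, missing_rate = 0, seed = 3)
  ds <- simulate_genotypes(cfg)$dataset
  kin <- ibd_kinship(ds)
  expect_equal(unname(diag(kin$phi)), rep(0.5, 20), tolerance = 1e-9)
  # a typical unrelated pair estimates within +/- 0.03 of zero (the per-pair
  # sampling sd at 1,000 loci is ~0.025, so the max over 190 pairs is larger)
  expect_lt(median(abs(kin$ibd$phi)), 0.03)
  expect_gte(mean(abs(kin$ibd$phi) < 0.03), 0.7)
  expect_lt(max(abs(kin$ibd$phi)), 0.12)
  expect_lt(abs(mean(kin$ibd$phi)), 0.02)
  expect_true(all(kin$ibd$P0 + kin$ibd$P1 + kin$ibd$P2 <= 1 + 1e-9))
  # low-overlap pairs are flagged unreliable
  d2 <- ds$dosage
  d2[1, 31:1000] <- NA
  kin2 <- ibd_kinship(make_ds(d2))
  row1 <- kin2$ibd[kin2$ibd$sample1 == "s01" | kin2$ibd$sample2 == "s01", ]
  expect_true(all(!row1$reliable))
})

test_that("het deficit is signed correctly and flags planted inbreds", {
  # a fully heterozygous sample at p = 0.5 loci has F ~ -1 (excess)
  set.seed(12)
  d <- matrix(rbinom(30 * 200, 2, 0.5), 30, 200)
  d[1, ] <- 1L
  f <- het_deficit(make_ds(d))
  expect_lt(f[1], -0.8)
  # planted selfed samples exceed the 0.1 threshold and are removed
  # near-panmictic, many loci: the per-sample F sampling error (~0.02) and
  # Wahlund offset stay well below the 0.1 threshold, so only the planted
  # inbreds are removed
  cfg <- sim_config(n_groups = 2, demes_per_group = 8, samples_per_deme = 11,
                    F_CT = 0.005, F_SC = 0.005, n_inbred = 5,
                    n_adaptive_loci = 0, n_neutral_loci = 4000, seed = 8)
  sim <- simulate_genotypes(cfg)
  expect_equal(length(sim$dataset$samples), 176)
  ds <- site_filters(sim$dataset, qc_config())$dataset
  f <- het_deficit(ds)
  expect_true(all(f[sim$truth$inbred$sample] > 0.1))
  sf <- sample_filters(ds, qc_config())
  expect_true(all(sim$truth$inbred$sample %in% sf$removed$sample))
  # count structure: exactly the planted inbreds are removed (n - 5 retained)
  expect_equal(length(sf$dataset$samples), 176 - 5)
})

test_that("kinship filtering removes the lower-call-rate pair member", {
  set.seed(5)
  d <- matrix(rbinom(6 * 300, 2, 0.5), 6, 300)
  d[2, ] <- d[1, ]                      # duplicate pair (phi ~ 0.5)
  d[2, 1:5] <- NA                       # member 2 has (slightly) lower call rate
  ds <- make_ds(d)
  kin <- ibd_kinship(ds)
  sf <- sample_filters(ds, qc_config(), kinship = kin$phi)
  expect_true("s02" %in% sf$removed$sample)
  expect_false("s01" %in% sf$removed$sample)
  expect_equal(sf$removed$reason[sf$removed$sample == "s02"], "kinship")
  # tie on call rate: the later sample id goes
  d[2, 1:5] <- d[1, 1:5]
  ds2 <- make_ds(d)
  sf2 <- sample_filters(ds2, qc_config(), kinship = ibd_kinship(ds2)$phi)
  expect_true("s02" %in% sf2$removed$sample)
})

test_that("neutral subset is seeded, capped and warns when short", {
  cfg <- sim_config(n_neutral_loci = 2000, n_adaptive_loci = 0, seed = 6)
  ds <- simulate_genotypes(cfg)$dataset
  s1 <- neutral_subset(ds, qc_config(seed = 42))
  s2 <- neutral_subset(ds, qc_config(seed = 42))
  expect_identical(s1, s2)
  expect_equal(length(s1), 1500)
  small <- subset_dataset(ds, loci = ds$loci$id[1:800])
  expect_warning(s3 <- neutral_subset(small, qc_config()), "800")
  expect_equal(length(s3), 800)
})

test_that("the QC cascade telescopes in the fixed stage order", {
  cfg <- sim_config(seed = 4, n_neutral_loci = 800, n_adaptive_loci = 10)
  sim <- simulate_genotypes(cfg)
  qc <- suppressWarnings(run_qc(sim$dataset, qc_config()))
  rep <- qc$report
  expect_equal(rep$stage, c("maf+site_callrate", "hwe", "ld_prune",
                            "sample_callrate", "het_deficit", "kinship"))
  expect_true(all(rep$n_in - rep$n_removed == rep$n_out))
  loci_rows <- rep[rep$unit == "loci", ]
  expect_equal(loci_rows$n_in[-1], loci_rows$n_out[-nrow(loci_rows)])
  samp_rows <- rep[rep$unit == "samples", ]
  expect_equal(samp_rows$n_in[-1], samp_rows$n_out[-nrow(samp_rows)])
  expect_equal(nrow(qc$dataset$loci), loci_rows$n_out[nrow(loci_rows)])
  expect_equal(length(qc$dataset$samples),
               samp_rows$n_out[nrow(samp_rows)])
  expect_true(all(qc$neutral_loci %in% qc$dataset$loci$id))
  # report serializes
  f <- tempfile(fileext = ".json")
  write_qc_report(qc, f)
  expect_true(jsonlite::validate(paste(readLines(f), collapse = "")))
})
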