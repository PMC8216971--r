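test_that("shortlists recompute by brute-force threshold application", {
  set.seed(2)
  loci <- sprintf("snp%03d", 1:60)
  fst_calls <- data.frame(locus = loci, p = runif(60))
  fst_calls$outlier <- fst_calls$p < 0.05
  lfmm_tab <- data.frame(locus = loci, axis = 1, p_cal = runif(60))
  bayenv <- data.frame(locus = loci, bf = exp(rnorm(60, 0, 3)),
                       rho = runif(60, -1, 1))
  bayenv$shortlist <- bayenv$bf > 30 & abs(bayenv$rho) > 0.4
  fmodel <- data.frame(locus = loci, q = runif(60))
  fmodel$shortlist <- fmodel$q < 0.05
  sl <- build_shortlists(fst_calls, lfmm_tab, bayenv, fmodel)
  expect_setequal(sl$arlequin, loci[fst_calls$p < 0.05])
  expect_setequal(sl$lfmm, loci[-log10(lfmm_tab$p_cal) > 1.3])
  expect_setequal(sl$bayenv, loci[bayenv$bf > 30 & abs(bayenv$rho) > 0.4])
  expect_setequal(sl$bayscenv, loci[fmodel$q < 0.05])
  # empty scans produce empty shortlists
  sl0 <- build_shortlists(fst_calls[0, ], lfmm_tab[0, ], bayenv[0, ],
                          fmodel[0, ])
  expect_true(all(lengths(sl0[c("arlequin", "lfmm", "bayenv",
                                "bayscenv")]) == 0))
  # mismatched locus sets error
  expect_error(build_shortlists(fst_calls[-1, ], lfmm_tab, bayenv, fmodel),
               "differ")
})

test_that("the printed PC2 intersection structure yields a consensus of 7", {
  # 46 loci shared by the FST scan and LFMM, 2 shared by LFMM and the
  # Bayes-factor scan, empty F-model shortlist, no triple memberships
  al <- sprintf("al%02d", 1:46)
  lb <- c("#51115", "#69292")
  sl <- list(arlequin = c(al, sprintf("only_a%02d", 1:30)),
             lfmm = c(al, lb, sprintf("only_l%02d", 1:40)),
             bayenv = c(lb, sprintf("only_b%02d", 1:16)),
             bayscenv = character(0),
             lfmm_rank = setNames(seq(5, 0.5, length.out = 48), c(al, lb)))
  cr <- consensus_sets(sl, cap = 5)
  expect_equal(length(cr$consensus), 7)
  expect_setequal(cr$consensus, c(al[1:5], lb))
  expect_equal(unname(cr$venn_pairs["arlequin&lfmm"]), 46L)
  expect_equal(unname(cr$venn_pairs["lfmm&bayenv"]), 2L)
  expect_true(all(cr$venn_triples == 0))
})

test_that("triple-membership loci are deduplicated and survive the cap", {
  sl <- list(arlequin = c("x", paste0("a", 1:10)),
             lfmm = c("x", paste0("a", 1:10), "y"),
             bayenv = c("x", "y"),
             bayscenv = character(0),
             lfmm_rank = setNames(c(0.1, seq(10, 1, length.out = 10), 5),
                                  c("x", paste0("a", 1:10), "y")))
  cr <- consensus_sets(sl, cap = 5)
  # "x" ranks last in the arlequin&lfmm pair (capped out) but qualifies
  # through arlequin&bayenv and lfmm&bayenv, so it stays - exactly once
  expect_equal(sum(cr$consensus == "x"), 1)
  expect_true("y" %in% cr$consensus)
  expect_equal(unname(cr$venn_triples["arlequin&lfmm&bayenv"]), 1L)
  expect_setequal(cr$consensus, c("x", "y", paste0("a", 1:5)))
})

test_that("consensus equals the brute-force set-algebra oracle", {
  set.seed(9)
  for (i in 1:40) {
    pool <- sprintf("L%03d", 1:40)
    sl <- list(arlequin = sample(pool, rpois(1, 8)),
               lfmm = sample(pool, rpois(1, 12)),
               bayenv = sample(pool, rpois(1, 4)),
               bayscenv = sample(pool, rpois(1, 3)))
    sl$lfmm_rank <- setNames(runif(length(sl$lfmm), 0, 6), sl$lfmm)
    cr <- consensus_sets(sl, cap = 5)
    expect_identical(cr$consensus,
                     oracle_consensus(sl, sl$lfmm_rank, cap = 5))
    # order invariance of inputs
    sl2 <- sl
    sl2$arlequin <- rev(sl$arlequin)
    sl2$lfmm <- sample(sl$lfmm)
    expect_identical(consensus_sets(sl2, cap = 5)$consensus, cr$consensus)
    # idempotence: feeding the consensus back as two identical shortlists
    sl3 <- list(arlequin = cr$consensus, lfmm = cr$consensus,
                bayenv = character(0), bayscenv = character(0),
                lfmm_rank = setNames(rep(1, length(cr$consensus)),
                                     cr$consensus))
    expect_true(all(consensus_sets(sl3, cap = 100)$consensus %in%
                      cr$consensus))
  }
})

test_that("allele-frequency/climate correlations recover signs", {
  cfg <- sim_config(n_neutral_loci = 150, n_adaptive_loci = 10,
                    env_effect_b = -1.2, missing_rate = 0, seed = 18)
  sim <- simulate_genotypes(cfg)
  ds <- sim$dataset
  clim <- sim$truth$env  # climate variable = the true gradient
  adaptive <- names(sim$truth$locus_class)[
    sim$truth$locus_class == "adaptive"]
  res <- allele_freq_climate_corr(ds, adaptive, clim)
  expect_lt(mean(res$r, na.rm = TRUE), -0.3)   # negative planted b
  neutral <- sample(names(sim$truth$locus_class)[
    sim$truth$locus_class == "neutral"], 80)
  resn <- allele_freq_climate_corr(ds, neutral, clim)
  expect_lt(abs(mean(resn$r, na.rm = TRUE)), 0.15)
  # frequencies proportional to climate -> r = 1
  d <- matrix(0L, 24, 1)
  prov <- rep(paste0("p", 1:6), each = 4)
  e <- setNames(1:6 / 10, paste0("p", 1:6))
  for (g in 1:6) d[prov == paste0("p", g), 1] <- rbinom(4, 2, e[g] + 0.2)
  # construct deterministic frequencies instead: dosage = 2*rank scaled
  d[, 1] <- rep(c(0L, 0L, 1L, 1L, 1L, 2L), each = 4)[1:24]
  loci <- data.frame(id = "l1", scaffold = "s", position = 1, ref = "A",
                     alt = "T")
  ds1 <- genotype_dataset(d, sprintf("s%02d", 1:24), loci,
                          setNames(prov, sprintf("s%02d", 1:24)))
  freq <- tapply(d[, 1] / 2, prov, mean)
  r1 <- allele_freq_climate_corr(ds1, "l1", setNames(freq, names(freq)))
  expect_equal(r1$r, 1, tolerance = 1e-12)
  expect_error(allele_freq_climate_corr(ds1, "l1", e[1:3]), ">= 5")
})

test_that("eigenvectors from diagnostic loci separate groups (eta squared)", {
  # two fully diverged clusters: diagnostic loci give eta^2 ~ 1
  set.seed(20)
  n <- 40
  grp <- rep(c("east", "west"), each = n / 2)
  diag_loci <- rbind(matrix(0L, n / 2, 6), matrix(2L, n / 2, 6))
  neutral <- matrix(rbinom(n * 60, 2, 0.5), n, 60)
  d <- cbind(diag_loci, neutral)
  loci <- data.frame(id = sprintf("l%03d", 1:66), scaffold = "s",
                     position = 1:66, ref = "A", alt = "T")
  samples <- sprintf("s%02d", 1:n)
  ds <- genotype_dataset(d, samples, loci,
                         setNames(grp, samples))
  labels <- setNames(grp, samples)
  eig <- eigen_discrimination(ds, sprintf("l%03d", 1:6),
                              sprintf("l%03d", 7:66), labels, seed = 1)
  expect_gt(eig$eta2_consensus, 0.95)
  # under panmixia the random set sits near the permutation null
  perm_null <- mean(replicate(200, {
    ev <- eig$ev_random[, 1]
    g <- sample(labels)
    gm <- tapply(ev, g, mean)
    sum(table(g) * (gm - mean(ev))^2) / sum((ev - mean(ev))^2)
  }))
  expect_lt(abs(eig$eta2_random - perm_null), 0.15)
  expect_error(eigen_discrimination(ds, sprintf("l%03d", 1:60),
                                    sprintf("l%03d", 61:66), labels),
               "fewer neutral")
})
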