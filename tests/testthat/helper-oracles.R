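# Independent oracles used to cross-check the package implementations.
# Each is written from the textbook definition by a different route than the
# package code (scalar loops, direct enumeration, numerical quadrature).

# --- Hardy-Weinberg exact test by full enumeration ------------------------
# Enumerates every genotype configuration compatible with the observed
# allele counts and sums multinomial probabilities no larger than the
# observed one. Uses factorial() directly (valid for n <= 170).
oracle_hwe_exact <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  if (nA == 0 || na == 0) return(1)
  hs <- seq(nA %% 2, min(nA, na), by = 2)
  # P(h | n, nA) is proportional to 2^h / (aa! h! bb!); the common factors
  # n! nA! na! / (2n)! cancel in the normalization
  config_prob <- function(h) {
    aa <- (nA - h) / 2
    bb <- (na - h) / 2
    2^h / (factorial(aa) * factorial(h) * factorial(bb))
  }
  probs <- vapply(hs, config_prob, numeric(1))
  probs <- probs / sum(probs)
  p_obs <- probs[hs == n_Aa]
  sum(probs[probs <= p_obs * (1 + 1e-12)])
}

# --- Weir-Cockerham theta, scalar textbook implementation -----------------
# Per-locus a, b, c computed population-by-population with explicit loops.
oracle_wc_fst <- function(dosage, pops) {
  upop <- unique(pops)
  r_all <- length(upop)
  nl <- ncol(dosage)
  fst <- rep(NA_real_, nl)
  A <- B <- C <- rep(NA_real_, nl)
  for (l in seq_len(nl)) {
    n_i <- p_i <- h_i <- numeric(0)
    for (pp in upop) {
      g <- dosage[pops == pp, l]
      g <- g[!is.na(g)]
      if (length(g) == 0) next
      n_i <- c(n_i, length(g))
      p_i <- c(p_i, mean(g) / 2)
      h_i <- c(h_i, mean(g == 1))
    }
    r <- length(n_i)
    if (r < 2) next
    nbar <- mean(n_i)
    nc <- (sum(n_i) - sum(n_i^2) / sum(n_i)) / (r - 1)
    pbar <- sum(n_i * p_i) / sum(n_i)
    if (pbar <= 0 || pbar >= 1) next
    s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n_i * h_i) / sum(n_i)
    a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
                                hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
                                  ((2 * nbar - 1) / (4 * nbar)) * hbar)
    cc <- hbar / 2
    A[l] <- a; B[l] <- b; C[l] <- cc
    if (a + b + cc != 0) fst[l] <- a / (a + b + cc)
  }
  ok <- !is.na(fst)
  list(fst = fst, global = sum(A[ok]) / sum(A[ok] + B[ok] + C[ok]))
}

# --- Bayes factor by brute-force quadrature -------------------------------
# Marginal likelihood of z under z = mu*it + beta*et + eps, eps ~ N(0, I),
# mu, beta ~ N(0, sigma^2), integrated on a fine grid.
oracle_bf_quadrature <- function(z, it, et, sigma = 1, grid_n = 401,
                                 width = 8) {
  gr <- seq(-width * max(sigma, 1), width * max(sigma, 1),
            length.out = grid_n)
  dgr <- gr[2] - gr[1]
  loglik0 <- vapply(gr, function(mu)
    sum(stats::dnorm(z, mu * it, 1, log = TRUE)) +
      stats::dnorm(mu, 0, sigma, log = TRUE), numeric(1))
  m0 <- max(loglik0)
  ml0 <- exp(m0) * sum(exp(loglik0 - m0)) * dgr
  ll1 <- matrix(NA_real_, grid_n, grid_n)
  for (i in seq_len(grid_n)) {
    mu <- gr[i]
    base <- stats::dnorm(mu, 0, sigma, log = TRUE)
    for (j in seq_len(grid_n)) {
      be <- gr[j]
      ll1[i, j] <- sum(stats::dnorm(z, mu * it + be * et, 1, log = TRUE)) +
        base + stats::dnorm(be, 0, sigma, log = TRUE)
    }
  }
  m1 <- max(ll1)
  ml1 <- exp(m1) * sum(exp(ll1 - m1)) * dgr^2
  ml1 / ml0
}

# --- Tukey biweight location by objective minimization --------------------
# Minimizes the biweight rho-objective directly (independent of the IRLS
# fixed-point route used by the package).
oracle_biweight <- function(x, c = 9) {
  x <- x[!is.na(x)]
  m0 <- stats::median(x)
  s <- stats::mad(x, center = m0, constant = 1)
  if (s == 0) return(m0)
  rho <- function(u) ifelse(abs(u) < 1, (1 - (1 - u^2)^3) / 6, 1 / 6)
  obj <- function(m) sum(rho((x - m) / (c * s)))
  stats::optimize(obj, range(x), tol = 1e-12)$minimum
}

# --- Consensus rule by brute-force set algebra ----------------------------
oracle_consensus <- function(sl, rank, cap = 5) {
  methods <- c("arlequin", "lfmm", "bayenv", "bayscenv")
  all_loci <- unique(unlist(sl[methods]))
  member <- sapply(methods, function(m) all_loci %in% sl[[m]])
  if (length(all_loci) == 1) member <- matrix(member, nrow = 1)
  out <- character(0)
  al <- intersect(sl$arlequin, sl$lfmm)
  capped <- al
  if (length(al) > cap) {
    r <- rank[al]; r[is.na(r)] <- -Inf
    capped <- al[order(-r, al)][seq_len(cap)]
  }
  for (i in seq_along(all_loci)) {
    loc <- all_loci[i]
    qualifies <- FALSE
    for (m1 in 1:3) for (m2 in (m1 + 1):4) {
      if (member[i, m1] && member[i, m2]) {
        if (methods[m1] == "arlequin" && methods[m2] == "lfmm") {
          if (loc %in% capped) qualifies <- TRUE
        } else qualifies <- TRUE
      }
    }
    if (qualifies) out <- c(out, loc)
  }
  sort(unique(out))
}

# --- RDA R^2 as the sum of per-locus univariate fits ----------------------
oracle_rda_r2 <- function(Y, X) {
  Y <- as.matrix(Y)
  mu <- colMeans(Y, na.rm = TRUE)
  idx <- which(is.na(Y), arr.ind = TRUE)
  if (nrow(idx)) Y[idx] <- mu[idx[, 2]]
  Yc <- sweep(Y, 2, colMeans(Y))
  Xs <- scale(as.matrix(X))
  fit_ss <- vapply(seq_len(ncol(Yc)), function(j) {
    f <- stats::lm.fit(cbind(1, Xs), Yc[, j])
    sum((Yc[, j] - f$residuals)^2)
  }, numeric(1))
  sum(fit_ss) / sum(Yc^2)
}

# --- Beta-binomial island simulation (independent of the package rbn) -----
# Mean per-locus WC FST expected under one-level Balding-Nichols at F.
oracle_bn_mean_fst <- function(n_loci, n_demes, n_per_deme, F, seed) {
  set.seed(seed)
  fst <- numeric(n_loci)
  for (l in seq_len(n_loci)) {
    p0 <- stats::runif(1, 0.05, 0.95)
    pd <- stats::rbeta(n_demes, p0 * (1 - F) / F, (1 - p0) * (1 - F) / F)
    g <- matrix(stats::rbinom(n_demes * n_per_deme, 2,
                              rep(pd, each = n_per_deme)),
                ncol = 1)
    pops <- rep(seq_len(n_demes), each = n_per_deme)
    fst[l] <- oracle_wc_fst(g, pops)$fst[1]
  }
  fst[!is.na(fst)]
}

# --- small text VCF fixture ------------------------------------------------
write_text_vcf <- function(path, body_lines,
                           samples = c("P1_01", "P1_02", "P2_01", "P2_02")) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    body_lines), path)
  path
}

# Cached default-scenario scan fixture shared by the acceptance recovery
# tests (simulation + QC + FST scan + LFMM are computed once).
.fixture_env <- new.env(parent = emptyenv())
default_scan_fixture <- function() {
  if (!is.null(.fixture_env$fix)) return(.fixture_env$fix)
  cfg <- sim_config(seed = 7)
  sim <- simulate_genotypes(cfg)
  qc <- suppressWarnings(run_qc(sim$dataset, qc_config()))
  ds <- qc$dataset
  groups <- genotype_groups(ds, loci = qc$neutral_loci, k = 2)
  fst <- scan_fst(ds, null_model_config(n_simulated_loci = 30000, seed = 17),
                  deme_group = groups)
  pcs <- climate_pca(simulate_climate(cfg))
  lfmm <- scan_lfmm(ds, pcs$scores[, 1:2], K = 2)
  .fixture_env$fix <- list(cfg = cfg, sim = sim, qc = qc, ds = ds,
                           groups = groups, fst = fst, pcs = pcs,
                           lfmm = lfmm,
                           cls = sim$truth$locus_class[ds$loci$id])
  .fixture_env$fix
}
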