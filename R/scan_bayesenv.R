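#' Per-deme alternative-allele frequencies
#'
#' @param ds a `GenotypeDataset`.
#' @param loci optional locus ids.
#' @return list with `freq` (deme x locus), `counts` (alt-allele counts),
#'   `sizes` (called allele counts, deme x locus).
#' @export
deme_freqs <- function(ds, loci = NULL) {
  if (!is.null(loci)) ds <- subset_dataset(ds, loci = loci)
  demes <- unique(ds$provenance_of)
  d <- ds$dosage
  counts <- sizes <- matrix(0, length(demes), ncol(d),
                            dimnames = list(demes, ds$loci$id))
  for (i in seq_along(demes)) {
    di <- d[ds$provenance_of == demes[i], , drop = FALSE]
    counts[i, ] <- colSums(di, na.rm = TRUE)
    sizes[i, ] <- 2 * colSums(!is.na(di))
  }
  list(freq = ifelse(sizes > 0, counts / sizes, NA_real_),
       counts = counts, sizes = sizes)
}

#' Estimate the neutral allele-frequency covariance matrix
#'
#' Bayenv-style: per neutral locus the deme frequency vector is centered at
#' its across-deme mean and scaled by `sqrt(pbar (1 - pbar))`; Omega is the
#' average outer product of these standardized vectors. A ridge `eps * I` is
#' grown until the condition number falls below `max_condition`.
#'
#' @param freq deme x locus matrix of neutral allele frequencies.
#' @param max_condition maximum acceptable condition number (default 1e8).
#' @return list of class `OmegaMatrix`: `omega`, `L` (lower Cholesky),
#'   `ridge`, `n_loci`.
#' @export
estimate_omega <- function(freq, max_condition = 1e8) {
  ok <- colSums(is.na(freq)) == 0
  freq <- freq[, ok, drop = FALSE]
  pbar <- colMeans(freq)
  poly <- pbar > 0 & pbar < 1
  freq <- freq[, poly, drop = FALSE]
  pbar <- pbar[poly]
  if (ncol(freq) < 100)
    warning("estimate_omega: only ", ncol(freq), " usable neutral loci")
  cmat <- sweep(freq, 2, pbar) / rep(sqrt(pbar * (1 - pbar)),
                                     each = nrow(freq))
  omega <- tcrossprod(cmat) / ncol(cmat)
  ridge <- 0
  eps <- mean(diag(omega)) * 1e-8
  repeat {
    ev <- eigen(omega + diag(ridge, nrow(omega)), symmetric = TRUE,
                only.values = TRUE)$values
    if (min(ev) > 0 && max(ev) / min(ev) < max_condition) break
    ridge <- if (ridge == 0) eps else ridge * 10
    if (ridge > 1e6 * mean(diag(omega)))
      stop("estimate_omega: matrix singular even after maximal ridge")
  }
  om <- omega + diag(ridge, nrow(omega))
  structure(list(omega = om, L = t(chol(om)), ridge = ridge,
                 n_loci = ncol(cmat)),
            class = "OmegaMatrix")
}

# log N(z; 0, I + sigma2 * G G') via precomputed Cholesky; z may be a matrix
# (columns = loci).
.gauss_logml <- function(zmat, G, sigma2) {
  D <- nrow(zmat)
  S <- diag(D) + sigma2 * tcrossprod(G)
  ch <- chol(S)
  logdet <- 2 * sum(log(diag(ch)))
  w <- backsolve(ch, zmat, transpose = TRUE)
  -0.5 * colSums(w^2) - 0.5 * logdet - 0.5 * D * log(2 * pi)
}

#' Covariance-controlled environmental Bayes factors
#'
#' For each locus the centered, scaled deme-frequency vector is whitened by
#' the Cholesky factor of Omega; the Bayes factor compares the conjugate
#' Gaussian linear model with regressors (whitened intercept, whitened
#' standardized environment) against the intercept-only model, both with
#' unit residual variance and a N(0, sigma_beta^2) coefficient prior.
#' A nonparametric backup statistic (Spearman rank correlation between the
#' whitened frequencies and the whitened environment) guards against
#' single-deme outliers. A locus is shortlisted when `BF > bf_min` and
#' `|rho| > rho_min`.
#'
#' @param freq deme x locus matrix of allele frequencies at the tested loci.
#' @param env numeric deme-level environmental vector (standardized
#'   internally).
#' @param omega an [estimate_omega()] result.
#' @param sigma_beta prior coefficient sd; a vector is averaged on the
#'   marginal-likelihood scale (log-mean-exp).
#' @param bf_min,rho_min shortlist thresholds (defaults 30 and 0.4).
#' @return data.frame of class `EnvAssocResult`: locus, bf, log10_bf, rho,
#'   shortlist.
#' @export
env_bayes_factor <- function(freq, env, omega, sigma_beta = 1,
                             bf_min = 30, rho_min = 0.4) {
  stopifnot(nrow(freq) == nrow(omega$omega), length(env) == nrow(freq))
  e <- as.numeric(scale(env))
  L <- omega$L
  pbar <- colMeans(freq)
  poly <- !is.na(pbar) & pbar > 0 & pbar < 1
  cmat <- sweep(freq, 2, pbar)
  cmat[, poly] <- cmat[, poly, drop = FALSE] /
    rep(sqrt(pbar[poly] * (1 - pbar[poly])), each = nrow(freq))
  cmat[, !poly] <- 0
  z <- forwardsolve(L, cmat)
  it <- forwardsolve(L, rep(1, nrow(freq)))
  et <- forwardsolve(L, e)
  lml0 <- lml1 <- matrix(NA_real_, length(sigma_beta), ncol(freq))
  for (s in seq_along(sigma_beta)) {
    s2 <- sigma_beta[s]^2
    lml0[s, ] <- .gauss_logml(z, cbind(it), s2)
    lml1[s, ] <- .gauss_logml(z, cbind(it, et), s2)
  }
  lse <- function(m) {
    mx <- apply(m, 2, max)
    mx + log(colMeans(exp(sweep(m, 2, mx))))
  }
  log_bf <- lse(lml1) - lse(lml0)
  bf <- exp(log_bf)
  rho <- suppressWarnings(
    apply(z, 2, function(v) stats::cor(v, et, method = "spearman")))
  rho[is.na(rho)] <- 0
  bf[!poly] <- 1
  rho[!poly] <- 0
  out <- data.frame(locus = colnames(freq), bf = bf,
                    log10_bf = log_bf / log(10), rho = rho,
                    shortlist = bf > bf_min & abs(rho) > rho_min,
                    stringsAsFactors = FALSE)
  class(out) <- c("EnvAssocResult", "data.frame")
  out
}

# Beta-binomial log pmf under the F-model: allele frequency ~ Balding-
# Nichols Beta(pi (1-theta)/theta, (1-pi)(1-theta)/theta), counts binomial.
.bb_loglik <- function(a, n, pi, theta) {
  theta <- pmin(pmax(theta, 1e-9), 1 - 1e-9)
  u <- pi * (1 - theta) / theta
  v <- (1 - pi) * (1 - theta) / theta
  lchoose(n, a) + lbeta(a + u, n - a + v) - lbeta(u, v)
}

#' F-model comparison scan with environmental differentiation
#'
#' Three nested models for per-deme allele counts under a beta-binomial
#' F-model with deme-locus differentiation `theta_ij`,
#' `logit(theta_ij) = beta_i + alpha_j`:
#' M0 (neutral, `alpha_j = 0`), M1 (locus-specific, `alpha_j` free), and
#' M2 (environmental, `alpha_j = g_j * E_i` with `E_i` the absolute
#' standardized deme environment). Deme effects `beta_i` are estimated once
#' by maximum likelihood over all loci with `alpha = 0`; per locus, M1 and
#' M2 are fitted by 1-D maximum likelihood and marginal likelihoods
#' approximated by BIC. Posterior model probabilities use the priors
#' `P(M1 or M2) = pi_prior` and `P(M2 | non-neutral) = p_prior`; the
#' posterior error probability is `1 - P(M2 | data)` and q-values are
#' running means of sorted PEPs. Shortlist at `q < alpha`.
#'
#' @param counts deme x locus matrix of alternative-allele counts.
#' @param sizes deme x locus matrix of called allele counts.
#' @param env deme-level environmental vector.
#' @param pi_prior prior probability that a locus is non-neutral (default
#'   0.1).
#' @param p_prior prior probability of the environmental model given
#'   non-neutral (default 0.5).
#' @param alpha q-value shortlist threshold (default 0.05).
#' @param signed_env use the signed standardized environment instead of its
#'   absolute value (default FALSE).
#' @return data.frame of class `FModelResult`: locus, pm0, pm1, pm2, pep, q,
#'   shortlist, converged; attribute `beta` holds the deme effects.
#' @export
fmodel_env_scan <- function(counts, sizes, env, pi_prior = 0.1,
                            p_prior = 0.5, alpha = 0.05,
                            signed_env = FALSE) {
  D <- nrow(counts)
  stopifnot(nrow(sizes) == D, length(env) == D)
  e_std <- as.numeric(scale(env))
  E <- if (signed_env) e_std else abs(e_std)
  pi_j <- colSums(counts) / pmax(colSums(sizes), 1)
  pi_j <- pmin(pmax(pi_j, 1e-4), 1 - 1e-4)
  usable <- colSums(sizes) > 0 & pi_j > 1e-4 & pi_j < 1 - 1e-4
  # stage 1: deme effects beta_i with alpha = 0 (separable per deme)
  beta <- vapply(seq_len(D), function(i) {
    f <- function(b) -sum(.bb_loglik(counts[i, usable], sizes[i, usable],
                                     pi_j[usable], stats::plogis(b)))
    stats::optimize(f, c(-14, 4))$minimum
  }, numeric(1))
  theta0 <- stats::plogis(beta)
  nl <- ncol(counts)
  ll0 <- ll1 <- ll2 <- rep(NA_real_, nl)
  conv <- rep(TRUE, nl)
  for (j in seq_len(nl)) {
    if (!usable[j]) { conv[j] <- FALSE; next }
    a <- counts[, j]; n <- sizes[, j]; pj <- pi_j[j]
    ll0[j] <- sum(.bb_loglik(a, n, pj, theta0))
    r1 <- tryCatch(
      stats::optimize(function(al)
        -sum(.bb_loglik(a, n, pj, stats::plogis(beta + al))), c(-12, 12)),
      error = function(e) NULL)
    r2 <- tryCatch(
      stats::optimize(function(g)
        -sum(.bb_loglik(a, n, pj, stats::plogis(beta + g * E))), c(-12, 12)),
      error = function(e) NULL)
    if (is.null(r1) || is.null(r2)) { conv[j] <- FALSE; next }
    ll1[j] <- -r1$objective
    ll2[j] <- -r2$objective
  }
  # BIC marginal-likelihood approximation (k extra parameters, D demes)
  lml <- cbind(ll0, ll1 - 0.5 * log(D), ll2 - 0.5 * log(D))
  lprior <- log(c(1 - pi_prior, pi_prior * (1 - p_prior),
                  pi_prior * p_prior))
  lpost <- sweep(lml, 2, lprior, `+`)
  mx <- apply(lpost, 1, max)
  pm <- exp(lpost - mx)
  pm <- pm / rowSums(pm)
  if (any(!conv))
    pm[!conv, ] <- matrix(c(1, 0, 0), sum(!conv), 3, byrow = TRUE)
  pep <- 1 - pm[, 3]
  ord <- order(pep)
  q <- numeric(nl)
  q[ord] <- cumsum(pep[ord]) / seq_len(nl)
  out <- data.frame(locus = colnames(counts), pm0 = pm[, 1], pm1 = pm[, 2],
                    pm2 = pm[, 3], pep = pep, q = q,
                    shortlist = q < alpha, converged = conv,
                    stringsAsFactors = FALSE)
  attr(out, "beta") <- beta
  class(out) <- c("FModelResult", "data.frame")
  out
}
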