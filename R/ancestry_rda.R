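# Euclidean projection of each row of Q onto the probability simplex
# (Duchi et al. 2008).
.proj_simplex_rows <- function(Q) {
  if (ncol(Q) == 1L) return(matrix(1, nrow(Q), 1L))
  t(apply(Q, 1, function(v) {
    u <- sort(v, decreasing = TRUE)
    css <- cumsum(u)
    rho <- max(which(u + (1 - css) / seq_along(u) > 0))
    tau <- (css[rho] - 1) / rho
    pmax(v - tau, 0)
  }))
}

# One constrained least-squares factorization at fixed K by alternating
# projected gradient (steps of 1/Lipschitz, hence monotone loss).
.snmf_fit <- function(X, K, seed, tol = 1e-6, max_iter = 300,
                      inner_steps = 3) {
  n <- nrow(X); L <- ncol(X)
  Q <- with_seed(seed, matrix(stats::rexp(n * K), n, K))
  Q <- Q / rowSums(Q)
  G <- matrix(colMeans(X), K, L, byrow = TRUE)
  loss <- function() sum((X - Q %*% G)^2)
  trace <- loss()
  for (it in seq_len(max_iter)) {
    lipG <- max(eigen(tcrossprod(G), symmetric = TRUE,
                      only.values = TRUE)$values, 1e-12)
    for (s in seq_len(inner_steps)) {
      grad <- (Q %*% G - X) %*% t(G)
      Q <- .proj_simplex_rows(Q - grad / lipG)
    }
    lipQ <- max(eigen(crossprod(Q), symmetric = TRUE,
                      only.values = TRUE)$values, 1e-12)
    for (s in seq_len(inner_steps)) {
      grad <- t(Q) %*% (Q %*% G - X)
      G <- pmin(pmax(G - grad / lipQ, 0), 1)
    }
    cur <- loss()
    trace <- c(trace, cur)
    if ((utils::tail(trace, 2)[1] - cur) <=
        tol * max(utils::tail(trace, 2)[1], 1e-300)) break
  }
  list(Q = Q, G = G, loss = trace,
       converged = it < max_iter)
}

#' Sparse-NMF-style ancestry estimation with cross-entropy model choice
#'
#' Factorizes the scaled dosage matrix `X = dosage / 2` (mean-imputed) as
#' `Q G` with simplex-constrained ancestry rows Q (sample x K) and ancestral
#' frequencies G in [0, 1], by monotone alternating projected-gradient least
#' squares. For each K in `k_range`, a seeded fraction of entries is masked
#' (replaced by column means) before fitting and the binomial cross-entropy
#' of the masked entries under the fitted `Q G` scores the model. The chosen
#' K is where the cross-entropy curve plateaus: the smallest K such that
#' moving to K + 1 improves masked cross-entropy by less than
#' `plateau_frac`.
#'
#' @param ds a `GenotypeDataset`.
#' @param loci optional locus ids (typically the neutral subset).
#' @param k_range candidate K values (default 1:8).
#' @param mask_fraction held-out entry fraction (default 0.05).
#' @param plateau_frac relative improvement defining a plateau (default
#'   0.01).
#' @param seed RNG seed (masking and initialization).
#' @return list of class `AncestryResult`: `per_k` (list with Q, G, loss,
#'   cross_entropy per K), `cross_entropy` (named vector), `chosen_k`, `Q`
#'   (at the chosen K).
#' @export
snmf_ancestry <- function(ds, loci = NULL, k_range = 1:8,
                          mask_fraction = 0.05, plateau_frac = 0.01,
                          seed = 1) {
  if (!is.null(loci)) ds <- subset_dataset(ds, loci = loci)
  X <- ds$dosage / 2
  mu <- colMeans(X, na.rm = TRUE)
  naidx <- which(is.na(X), arr.ind = TRUE)
  if (nrow(naidx)) X[naidx] <- mu[naidx[, 2]]
  mask <- with_seed(seed,
                    which(stats::runif(length(X)) < mask_fraction))
  Xmasked <- X
  Xmasked[mask] <- rep(colMeans(X), each = nrow(X))[mask]
  eps <- 1e-6
  per_k <- list()
  ce <- numeric(0)
  for (K in k_range) {
    fit <- .snmf_fit(Xmasked, K, seed = seed + K)
    P <- pmin(pmax(fit$Q %*% fit$G, eps), 1 - eps)
    x <- X[mask]; p <- P[mask]
    fit$cross_entropy <- -mean(x * log(p) + (1 - x) * log(1 - p))
    per_k[[as.character(K)]] <- fit
    ce <- c(ce, fit$cross_entropy)
  }
  names(ce) <- k_range
  chosen <- k_range[length(k_range)]
  for (i in seq_along(k_range)[-length(k_range)]) {
    improvement <- (ce[i] - ce[i + 1]) / abs(ce[i])
    if (improvement < plateau_frac) { chosen <- k_range[i]; break }
  }
  # refit at chosen K on the unmasked matrix for the reported Q
  final <- .snmf_fit(X, chosen, seed = seed + chosen)
  rownames(final$Q) <- ds$samples
  structure(list(per_k = per_k, cross_entropy = ce, chosen_k = chosen,
                 Q = final$Q, G = final$G),
            class = "AncestryResult")
}

#' Redundancy analysis of a genotype matrix on predictor(s)
#'
#' Multivariate linear regression of the column-centered dosage matrix on a
#' z-transformed predictor matrix; `R^2` is the fraction of total genotype
#' sum of squares captured by the fitted values (equal to the sum of
#' per-locus regression fits), with Ezekiel's adjustment.
#'
#' @param Y numeric sample x locus matrix (dosages; missing entries
#'   mean-imputed).
#' @param X numeric sample x predictor matrix (z-transformed internally).
#' @return list of class `RdaResult`: `r2`, `adj_r2`, `n`, `q` (number of
#'   predictors).
#' @export
rda_fit <- function(Y, X) {
  Y <- as.matrix(Y)
  mu <- colMeans(Y, na.rm = TRUE)
  naidx <- which(is.na(Y), arr.ind = TRUE)
  if (nrow(naidx)) Y[naidx] <- mu[naidx[, 2]]
  Yc <- sweep(Y, 2, colMeans(Y))
  X <- scale(as.matrix(X))
  n <- nrow(Yc); q <- ncol(X)
  stopifnot(nrow(X) == n, n > q + 1)
  qrX <- qr(cbind(1, X))
  if (qrX$rank < q + 1) {
    bad <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)] - 1]
    stop("collinear predictor column(s): ", paste(bad, collapse = ", "))
  }
  fitted <- qr.fitted(qrX, Yc)
  r2 <- sum(fitted^2) / sum(Yc^2)
  adj <- 1 - (1 - r2) * (n - 1) / (n - q - 1)
  structure(list(r2 = r2, adj_r2 = adj, n = n, q = q),
            class = "RdaResult")
}

#' Permutation test for an RDA model
#'
#' Rows of X are permuted jointly `n_perm` times;
#' `p = (1 + #\{R2_perm >= R2_obs\}) / (n_perm + 1)`.
#'
#' @param Y sample x locus matrix.
#' @param X sample x predictor matrix.
#' @param n_perm number of permutations (default 999).
#' @param seed RNG seed.
#' @return list with `p`, `r2_obs`, `n_perm`.
#' @export
rda_permutation_test <- function(Y, X, n_perm = 999, seed = 1) {
  X <- as.matrix(X)
  X <- sweep(X, 2, colMeans(X))
  sds <- apply(X, 2, stats::sd)
  X[, sds > 0] <- sweep(X[, sds > 0, drop = FALSE], 2, sds[sds > 0], `/`)
  Y <- as.matrix(Y)
  mu <- colMeans(Y, na.rm = TRUE)
  naidx <- which(is.na(Y), arr.ind = TRUE)
  if (nrow(naidx)) Y[naidx] <- mu[naidx[, 2]]
  Yc <- sweep(Y, 2, colMeans(Y))
  tot <- sum(Yc^2)
  r2_of <- function(Xp) {
    qq <- qr(cbind(1, Xp))
    Q <- qr.Q(qq)[, seq_len(qq$rank), drop = FALSE]
    sum(crossprod(Q, Yc)^2) / tot
  }
  obs <- r2_of(X)
  perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i)
      r2_of(X[sample(nrow(X)), , drop = FALSE]), numeric(1))
  })
  list(p = (1 + sum(perm >= obs - 1e-15)) / (n_perm + 1), r2_obs = obs,
       n_perm = n_perm)
}

#' Run the standard set of RDA models
#'
#' Combined models (climate = PC1 + PC2, geography = latitude + longitude,
#' ancestry = Q at K = 2) and individual models (each predictor separately),
#' each with a permutation p-value.
#'
#' @param ds a `GenotypeDataset`.
#' @param env_scores provenance x axis matrix (>= 2 columns).
#' @param provenances data.frame with id, lat, lon.
#' @param q_column named numeric vector sample -> ancestry coefficient
#'   (first Q column at K = 2).
#' @param n_perm permutations per model.
#' @param seed RNG seed.
#' @return data.frame: model, r2, adj_r2, p, n_perm.
#' @export
rda_models <- function(ds, env_scores, provenances, q_column,
                       n_perm = 999, seed = 1) {
  Y <- ds$dosage
  prov <- ds$provenance_of
  lat <- stats::setNames(provenances$lat, provenances$id)[prov]
  lon <- stats::setNames(provenances$lon, provenances$id)[prov]
  pc1 <- env_scores[prov, 1]
  pc2 <- env_scores[prov, 2]
  qv <- q_column[ds$samples]
  preds <- list(
    `climate(PC1+PC2)` = cbind(PC1 = pc1, PC2 = pc2),
    `geography(lat+lon)` = cbind(lat = lat, lon = lon),
    ancestry = cbind(Q = qv),
    PC1 = cbind(PC1 = pc1), PC2 = cbind(PC2 = pc2),
    latitude = cbind(lat = lat), longitude = cbind(lon = lon),
    ancestry_only = cbind(Q = qv))
  out <- lapply(names(preds), function(m) {
    f <- rda_fit(Y, preds[[m]])
    pt <- rda_permutation_test(Y, preds[[m]], n_perm = n_perm,
                               seed = seed + match(m, names(preds)))
    data.frame(model = m, r2 = f$r2, adj_r2 = f$adj_r2, p = pt$p,
               n_perm = n_perm, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
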