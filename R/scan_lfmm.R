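#' Choose the number of latent factors from a scree plot
#'
#' Eigenvalues of the sample covariance of the (centered, mean-imputed)
#' neutral genotype matrix; the elbow is read from the top of the scree
#' plot: K is the length of the initial run of eigenvalue gaps
#' `lambda_k - lambda_{k+1}` that exceed a multiple (`gap_factor`, default 3)
#' of the mean gap of the spectrum's tail (its second half). Returns 0 when
#' already the first gap is within the tail's spacing (i.i.d.-noise
#' genotypes).
#'
#' @param ds a `GenotypeDataset`.
#' @param loci optional locus ids (typically the neutral subset).
#' @param k_max largest k considered (default 10).
#' @param gap_factor multiple of the mean tail gap a leading gap must exceed.
#' @return integer K.
#' @export
choose_k <- function(ds, loci = NULL, k_max = 10, gap_factor = 3) {
  if (length(ds$samples) < 10) stop("need >= 10 samples")
  pca <- genotype_pca(ds, loci = loci, n_components = 2)
  ev <- pca$values
  ev <- ev[ev > 0]
  gaps <- -diff(ev)
  tail_gaps <- gaps[seq(floor(length(gaps) / 2) + 1, length(gaps))]
  thr <- gap_factor * mean(tail_gaps)
  k <- 0L
  for (i in seq_len(min(k_max, length(gaps)))) {
    if (gaps[i] > thr) k <- i else break
  }
  k
}

#' Fit a latent factor mixed model by alternating minimization
#'
#' Model: `Y = X B' + W + E` with `W = U V'` of rank K. Y is the centered
#' (and mean-imputed) sample x locus genotype matrix, X the column-
#' standardized environmental design. The estimator alternates (i) given B,
#' a rank-K truncated SVD of `Y - X B'` for (U, V); (ii) given (U, V), ridge
#' regression of `Y - U V'` on X for B; until the relative change of the
#' penalized objective `||Y - XB' - UV'||^2 + lambda ||B||^2` falls below
#' `tol` (or `max_iter`). Deterministic: B starts at 0 so the first latent
#' estimate is the plain SVD of Y.
#'
#' @param Y numeric matrix (samples x loci), will be column-centered.
#' @param X numeric matrix (samples x d environmental axes), will be
#'   column-standardized.
#' @param K number of latent factors (0 allowed: plain ridge regression).
#' @param lambda ridge penalty on B (default 1e-5).
#' @param tol relative objective tolerance (default 1e-8).
#' @param max_iter iteration cap (default 200).
#' @return list of class `LfmmFit`: `B` (loci x d), `U` (samples x K),
#'   `V` (loci x K), `K`, `lambda`, `objective` (trace), `converged`,
#'   `Y`, `X` (the centered/standardized copies used).
#' @export
lfmm_fit <- function(Y, X, K, lambda = 1e-5, tol = 1e-8, max_iter = 200) {
  Y <- as.matrix(Y)
  if (is.null(colnames(Y)))
    colnames(Y) <- sprintf("locus%05d", seq_len(ncol(Y)))
  Y <- sweep(Y, 2, colMeans(Y))
  X <- as.matrix(X)
  X <- scale(X)
  n <- nrow(Y); d <- ncol(X)
  stopifnot(nrow(X) == n, n > d + K)
  XtX <- crossprod(X) + diag(lambda, d)
  B <- matrix(0, ncol(Y), d)
  U <- matrix(0, n, max(K, 1))[, seq_len(K), drop = FALSE]
  V <- matrix(0, ncol(Y), max(K, 1))[, seq_len(K), drop = FALSE]
  obj <- function(B, U, V) {
    R <- Y - X %*% t(B) - U %*% t(V)
    sum(R^2) + lambda * sum(B^2)
  }
  trace <- numeric(0)
  prev <- obj(B, U, V)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    if (K > 0) {
      sv <- svd(Y - X %*% t(B), nu = K, nv = K)
      U <- sv$u %*% diag(sv$d[seq_len(K)], K, K)
      V <- sv$v
    }
    B <- t(solve(XtX, crossprod(X, Y - U %*% t(V))))
    cur <- obj(B, U, V)
    trace <- c(trace, cur)
    if (prev - cur <= tol * max(prev, 1e-300)) {
      converged <- TRUE
      break
    }
    prev <- cur
  }
  if (!converged) warning("lfmm_fit did not converge in ", max_iter,
                          " iterations")
  structure(list(B = B, U = U, V = V, K = K, lambda = lambda,
                 objective = trace, converged = converged, Y = Y, X = X),
            class = "LfmmFit")
}

#' Per-locus association tests with genomic-inflation calibration
#'
#' Each (centered) genotype column is regressed by least squares on the
#' design `[X, U]` (environmental axes plus estimated latent factors); the
#' t-statistics of the X coefficients are the raw z-scores. Per axis, the
#' genomic inflation factor `lambda_GC = median(z^2) / 0.4549` recalibrates
#' the p-values via `z^2 / lambda_GC ~ chi-square(1)`. Bonferroni and
#' Benjamini-Hochberg flags are computed at level `alpha` over tested loci.
#'
#' @param fit an [lfmm_fit()] result.
#' @param alpha significance level (default 0.05).
#' @return list of class `LfmmTest`: `table` (data.frame locus-by-axis with
#'   z, p_raw, p_cal, bonferroni, fdr), `gif` (per axis),
#'   `bonferroni_neglog10` (the -log10 Bonferroni threshold), `m` (tested
#'   loci).
#' @export
lfmm_test <- function(fit, alpha = 0.05) {
  X <- fit$X; U <- fit$U; Y <- fit$Y
  n <- nrow(Y)
  D <- cbind(1, X, U)
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    # drop collinear latent columns, keep X
    keep <- qrD$pivot[seq_len(qrD$rank)]
    must <- seq_len(1 + ncol(X))
    if (!all(must %in% keep))
      stop("environmental design collinear with intercept")
    drop_u <- setdiff(seq_len(ncol(D)), keep)
    message("lfmm_test: dropping ", length(drop_u),
            " collinear latent column(s)")
    D <- D[, sort(keep), drop = FALSE]
    qrD <- qr(D)
  }
  p_cols <- ncol(D)
  coef <- qr.coef(qrD, Y)                       # p_cols x loci
  res <- Y - D %*% coef
  df <- n - p_cols
  sigma2 <- colSums(res^2) / df
  XtXinv <- solve(crossprod(D))
  axis_idx <- 1 + seq_len(ncol(X))              # X coefficient rows
  d_ax <- length(axis_idx)
  m <- ncol(Y)
  out <- vector("list", d_ax)
  gif <- numeric(d_ax)
  for (j in seq_len(d_ax)) {
    se <- sqrt(sigma2 * XtXinv[axis_idx[j], axis_idx[j]])
    z <- coef[axis_idx[j], ] / se
    gif[j] <- stats::median(z^2, na.rm = TRUE) / stats::qchisq(0.5, 1)
    p_raw <- 2 * stats::pt(-abs(z), df)
    p_cal <- stats::pchisq(z^2 / gif[j], 1, lower.tail = FALSE)
    out[[j]] <- data.frame(locus = colnames(Y), axis = j, z = z,
                           p_raw = p_raw, p_cal = p_cal,
                           stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, out)
  tab$bonferroni <- tab$p_cal < alpha / m
  tab$fdr <- stats::ave(tab$p_cal, tab$axis,
                        FUN = function(p) stats::p.adjust(p, "BH")) < alpha
  names(gif) <- paste0("axis", seq_len(d_ax))
  structure(list(table = tab, gif = gif,
                 bonferroni_neglog10 = -log10(alpha / m), m = m,
                 alpha = alpha),
            class = "LfmmTest")
}

#' Full LFMM scan of a genotype dataset
#'
#' Mean-imputes missing dosages per locus, expands the per-provenance
#' environmental scores to samples, fits the latent factor model and runs
#' the calibrated per-locus tests.
#'
#' @param ds a `GenotypeDataset`.
#' @param env_scores provenance x axis matrix (e.g. `EnvPCs$scores[, 1:2]`).
#' @param K number of latent factors; `NULL` chooses it via [choose_k()] on
#'   `neutral_loci`.
#' @param neutral_loci locus ids for [choose_k()] when `K` is `NULL`.
#' @param lambda ridge penalty.
#' @param alpha significance level.
#' @return list with `fit`, `test`, `K`.
#' @export
scan_lfmm <- function(ds, env_scores, K = NULL, neutral_loci = NULL,
                      lambda = 1e-5, alpha = 0.05) {
  if (is.null(K)) K <- max(1L, choose_k(ds, loci = neutral_loci))
  X <- env_scores[ds$provenance_of, , drop = FALSE]
  Y <- ds$dosage
  mu <- colMeans(Y, na.rm = TRUE)
  idx <- which(is.na(Y), arr.ind = TRUE)
  if (nrow(idx)) Y[idx] <- mu[idx[, 2]]
  colnames(Y) <- ds$loci$id
  fit <- lfmm_fit(Y, X, K = K, lambda = lambda)
  list(fit = fit, test = lfmm_test(fit, alpha = alpha), K = K)
}
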