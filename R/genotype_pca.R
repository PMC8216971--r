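#' Genotype principal components
#'
#' PCA of the sample x locus dosage matrix with the usual allele-frequency
#' normalization: each locus is centered at `2 p` and (optionally) scaled by
#' `sqrt(2 p (1 - p))`, missing entries are mean-imputed, and the sample
#' covariance is eigen-decomposed.
#'
#' @param ds a `GenotypeDataset`.
#' @param loci optional locus ids to restrict to.
#' @param n_components number of eigenvectors to return.
#' @param scale logical; divide by `sqrt(2p(1-p))` (default TRUE).
#' @return list with `vectors` (sample x component), `values` (all
#'   eigenvalues), `n_loci`.
#' @export
genotype_pca <- function(ds, loci = NULL, n_components = 10, scale = TRUE) {
  if (!is.null(loci)) ds <- subset_dataset(ds, loci = loci)
  x <- .scaled_dosage(ds, scale = scale)
  cv <- tcrossprod(x) / ncol(x)
  eg <- eigen(cv, symmetric = TRUE)
  k <- min(n_components, ncol(eg$vectors))
  vec <- eg$vectors[, seq_len(k), drop = FALSE]
  rownames(vec) <- ds$samples
  list(vectors = vec, values = eg$values, n_loci = ncol(x))
}

# Center dosages at 2p (optionally scale by sqrt(2p(1-p))), mean-impute
# missing entries (to 0 after centering). Drops monomorphic loci.
.scaled_dosage <- function(ds, scale = TRUE) {
  d <- ds$dosage
  p <- alt_freq(ds)
  keep <- !is.na(p) & p > 0 & p < 1
  d <- d[, keep, drop = FALSE]
  p <- p[keep]
  x <- sweep(d, 2, 2 * p)
  x[is.na(x)] <- 0
  if (scale) x <- sweep(x, 2, sqrt(2 * p * (1 - p)), `/`)
  x
}

#' Group samples by k-means on the first two genotype eigenvectors
#'
#' Used to place observed demes into the groups of a hierarchical island
#' null model: each deme is assigned the majority cluster of its samples.
#'
#' @param ds a `GenotypeDataset`.
#' @param loci locus ids to use (typically the neutral subset).
#' @param k number of clusters.
#' @param seed RNG seed for k-means restarts.
#' @return named integer vector: deme (provenance) id -> group.
#' @export
genotype_groups <- function(ds, loci = NULL, k = 2, seed = 1) {
  pca <- genotype_pca(ds, loci = loci, n_components = 2)
  km <- with_seed(seed,
                  stats::kmeans(pca$vectors, centers = k, nstart = 10))
  cl <- km$cluster
  demes <- unique(ds$provenance_of)
  out <- vapply(demes, function(d) {
    tab <- table(cl[ds$provenance_of == d])
    as.integer(names(tab)[which.max(tab)])
  }, integer(1))
  stats::setNames(out, demes)
}
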