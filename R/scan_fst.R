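# Weir-Cockerham (1984) variance components from per-population summaries.
# All arguments are pop x locus matrices: n (called samples), p (alt
# frequency), h (observed heterozygote proportion). Populations with no
# called genotype at a locus are excluded locus-wise via n = 0.
.wc_components <- function(n, p, h) {
  used <- n > 0
  r <- colSums(used)
  nsum <- colSums(n)
  nbar <- nsum / r
  nc <- (nsum - colSums(n^2) / nsum) / (r - 1)
  pbar <- colSums(n * p) / nsum
  s2 <- colSums(n * (p - rep(pbar, each = nrow(p)))^2 * used) /
    ((r - 1) * nbar)
  hbar <- colSums(n * h) / nsum
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc, pbar = pbar, r = r)
}

#' Weir-Cockerham FST
#'
#' Per-locus Weir-Cockerham (1984) theta from observed genotype (not just
#' allele-frequency) data, plus the multi-locus global estimate as the ratio
#' of summed variance components (not the mean of per-locus ratios). Loci
#' monomorphic over all called genotypes have undefined FST (`NA`) and are
#' excluded from the global sum and from outlier testing.
#'
#' @param ds a `GenotypeDataset`.
#' @param pops named character vector sample -> population (defaults to the
#'   dataset's provenance labels).
#' @return list of class `FstResult`: `fst` (per locus), `het` (expected
#'   heterozygosity `2 pbar (1 - pbar)`), `global`, `a`, `b`, `c`.
#' @export
wc_fst <- function(ds, pops = NULL) {
  if (is.null(pops)) pops <- ds$provenance_of
  pops <- pops[ds$samples]
  upop <- unique(pops)
  if (length(upop) < 2) stop("need >= 2 populations")
  if (any(table(pops) < 2)) stop("every population needs >= 2 samples")
  d <- ds$dosage
  np <- length(upop)
  nl <- ncol(d)
  n <- p <- h <- matrix(0, np, nl)
  for (i in seq_len(np)) {
    di <- d[pops == upop[i], , drop = FALSE]
    n[i, ] <- colSums(!is.na(di))
    p[i, ] <- ifelse(n[i, ] > 0, colMeans(di, na.rm = TRUE) / 2, 0)
    h[i, ] <- ifelse(n[i, ] > 0,
                     colMeans(di == 1L, na.rm = TRUE), 0)
  }
  p[is.nan(p)] <- 0; h[is.nan(h)] <- 0
  comp <- .wc_components(n, p, h)
  denom <- comp$a + comp$b + comp$c
  fst <- ifelse(abs(denom) > 0, comp$a / denom, NA_real_)
  mono <- comp$pbar <= 0 | comp$pbar >= 1
  fst[mono] <- NA_real_
  ok <- !is.na(fst)
  structure(list(fst = stats::setNames(fst, ds$loci$id),
                 het = stats::setNames(2 * comp$pbar * (1 - comp$pbar),
                                       ds$loci$id),
                 global = sum(comp$a[ok]) / sum(denom[ok]),
                 a = comp$a, b = comp$b, c = comp$c),
            class = "FstResult")
}

#' Hierarchical island null-model configuration
#'
#' Defaults echo the standard large-simulation setting: 200,000 simulated
#' loci, 10 groups of 100 demes, and 50 heterozygosity bins for conditioning
#' the outlier p-values.
#'
#' @param n_groups,demes_per_group nominal hierarchy (observed demes are
#'   embedded at their observed layout; these record the configured model).
#' @param n_simulated_loci null loci to simulate.
#' @param het_bins equal-count heterozygosity bins.
#' @param target_fst observed global FST the null is calibrated to.
#' @param tolerance calibration tolerance on |simulated - target|.
#' @param fct_fsc_ratio ratio F_CT / F_SC during calibration (the bisection
#'   scales both proportionally).
#' @param n_calibration_loci loci per calibration evaluation.
#' @param seed RNG seed.
#' @return list of class `NullModelConfig`.
#' @export
null_model_config <- function(n_groups = 10, demes_per_group = 100,
                              n_simulated_loci = 200000, het_bins = 50,
                              target_fst = NULL, tolerance = 0.002,
                              fct_fsc_ratio = 1, n_calibration_loci = 3000,
                              seed = 1) {
  stopifnot(n_groups >= 1, demes_per_group >= 1, n_simulated_loci >= 1000,
            het_bins >= 2, tolerance > 0, fct_fsc_ratio > 0)
  structure(list(n_groups = as.integer(n_groups),
                 demes_per_group = as.integer(demes_per_group),
                 n_simulated_loci = as.integer(n_simulated_loci),
                 het_bins = as.integer(het_bins),
                 target_fst = target_fst, tolerance = tolerance,
                 fct_fsc_ratio = fct_fsc_ratio,
                 n_calibration_loci = as.integer(n_calibration_loci),
                 seed = as.integer(seed)),
            class = "NullModelConfig")
}

# Simulate n_loci null loci at the observed layout and return per-locus
# summaries (n, p, h matrices) via hierarchical Balding-Nichols sampling.
.null_batch <- function(n_loci, deme_sizes, deme_group, F_CT, F_SC) {
  D <- length(deme_sizes)
  groups <- sort(unique(deme_group))
  p_anc <- stats::runif(n_loci, 0.01, 0.99)
  gf <- matrix(rbn(length(groups) * n_loci, rep(p_anc, each = length(groups)),
                   F_CT), nrow = length(groups))
  gidx <- match(deme_group, groups)
  df <- matrix(rbn(D * n_loci, as.vector(gf[gidx, , drop = FALSE]), F_SC),
               nrow = D)
  df <- pmin(pmax(df, 0), 1)
  nmat <- matrix(deme_sizes, D, n_loci)
  # genotype counts per deme under HWE at the deme frequency
  n_aa2 <- matrix(stats::rbinom(D * n_loci, as.vector(nmat),
                                as.vector(df)^2), D)
  prem <- ifelse(df < 1, 2 * df * (1 - df) / (1 - df^2), 0)
  n_het <- matrix(stats::rbinom(D * n_loci, as.vector(nmat - n_aa2),
                                as.vector(prem)), D)
  p <- (2 * n_aa2 + n_het) / (2 * nmat)
  h <- n_het / nmat
  list(n = nmat, p = p, h = h)
}

# Global (ratio-of-sums) WC FST of one simulated batch.
.null_global_fst <- function(batch) {
  comp <- .wc_components(batch$n, batch$p, batch$h)
  denom <- comp$a + comp$b + comp$c
  ok <- comp$pbar > 0 & comp$pbar < 1 & abs(denom) > 0
  sum(comp$a[ok]) / sum(denom[ok])
}

#' Simulate the hierarchical island null distribution of (het, FST)
#'
#' Generates `n_simulated_loci` null loci by hierarchical Balding-Nichols
#' sampling (ancestral frequency Uniform(0.01, 0.99), group then deme
#' frequencies) at the observed per-deme sample sizes and deme-to-group
#' mapping. The pair (F_CT, F_SC) is first calibrated by bisection on a
#' common proportionality parameter until the simulated global
#' (ratio-of-sums) FST matches `target_fst` within `tolerance`.
#'
#' @param cfg a [null_model_config()] with `target_fst` set.
#' @param deme_sizes named integer vector: deme -> number of samples.
#' @param deme_group named integer vector: deme -> group (defaults to all
#'   demes in one group when absent).
#' @return list of class `NullDistribution`: `pairs` (data.frame het, fst),
#'   `F_CT`, `F_SC`, `calibrated_fst`.
#' @export
simulate_null <- function(cfg, deme_sizes, deme_group = NULL) {
  if (is.null(cfg$target_fst)) stop("cfg$target_fst must be set")
  if (is.null(deme_group))
    deme_group <- stats::setNames(rep(1L, length(deme_sizes)),
                                  names(deme_sizes))
  deme_group <- deme_group[names(deme_sizes)]
  target <- cfg$target_fst
  ratio <- cfg$fct_fsc_ratio
  # proportionality s: F_CT = s * ratio / (1 + ratio), F_SC = s / (1 + ratio)
  split_f <- function(s) list(F_CT = s * ratio / (1 + ratio),
                              F_SC = s / (1 + ratio))
  eval_fst <- function(s) {
    f <- split_f(s)
    with_seed(cfg$seed + 1L,
              .null_global_fst(.null_batch(cfg$n_calibration_loci,
                                           deme_sizes, deme_group,
                                           f$F_CT, f$F_SC)))
  }
  if (target <= max(0, eval_fst(1e-6)) - cfg$tolerance)
    s_star <- 1e-6
  else {
    lo <- 1e-6; hi <- 0.9
    if (eval_fst(hi) < target)
      stop("calibration failed to bracket target FST ", target,
           " (max simulated ", round(eval_fst(hi), 4), ")")
    repeat {
      mid <- (lo + hi) / 2
      fm <- eval_fst(mid)
      if (abs(fm - target) <= cfg$tolerance || (hi - lo) < 1e-7) break
      if (fm < target) lo <- mid else hi <- mid
    }
    s_star <- mid
  }
  f <- split_f(s_star)
  pairs <- with_seed(cfg$seed + 2L, {
    chunks <- split(seq_len(cfg$n_simulated_loci),
                    ceiling(seq_len(cfg$n_simulated_loci) / 50000))
    res <- lapply(chunks, function(ix) {
      b <- .null_batch(length(ix), deme_sizes, deme_group, f$F_CT, f$F_SC)
      comp <- .wc_components(b$n, b$p, b$h)
      denom <- comp$a + comp$b + comp$c
      ok <- comp$pbar > 0 & comp$pbar < 1 & abs(denom) > 0
      data.frame(het = 2 * comp$pbar[ok] * (1 - comp$pbar[ok]),
                 fst = comp$a[ok] / denom[ok])
    })
    do.call(rbind, res)
  })
  final <- with_seed(cfg$seed + 1L,
                     .null_global_fst(.null_batch(cfg$n_calibration_loci,
                                                  deme_sizes, deme_group,
                                                  f$F_CT, f$F_SC)))
  structure(list(pairs = pairs, F_CT = f$F_CT, F_SC = f$F_SC,
                 calibrated_fst = final, config = cfg),
            class = "NullDistribution")
}

#' Quantile-based outlier p-values conditioned on heterozygosity
#'
#' Null (het, FST) pairs are split into `het_bins` equal-count heterozygosity
#' bins; each observed locus gets the upper-tail pseudo-count p-value
#' `(1 + #\{null FST in bin >= observed\}) / (1 + bin size)` within its bin.
#' A locus is an outlier when p < `alpha` (equivalently
#' `-log10(1 - FST quantile) > -log10(alpha)`); the Bonferroni flag uses
#' `alpha / n_tested`. Loci with heterozygosity outside the simulated range
#' are assigned the nearest bin and flagged.
#'
#' @param fst_result a [wc_fst()] result for the observed data.
#' @param null a `NullDistribution` (or data.frame with `het`, `fst`).
#' @param het_bins number of bins (default from the null's config, else 50).
#' @param alpha outlier significance level (default 0.05).
#' @return data.frame of class `OutlierCall`: locus, het, fst, p,
#'   neglog_quantile, outlier, bonferroni, out_of_range.
#' @export
outlier_pvalues <- function(fst_result, null, het_bins = NULL, alpha = 0.05) {
  pairs <- if (inherits(null, "NullDistribution")) null$pairs else null
  if (nrow(pairs) < 1000) stop("need >= 1000 null pairs")
  if (is.null(het_bins))
    het_bins <- if (inherits(null, "NullDistribution"))
      null$config$het_bins else 50L
  obs <- data.frame(locus = names(fst_result$fst),
                    het = unname(fst_result$het),
                    fst = unname(fst_result$fst))
  tested <- !is.na(obs$fst)
  m <- sum(tested)
  breaks <- stats::quantile(pairs$het, probs = seq(0, 1, length.out =
                                                     het_bins + 1))
  bin_null <- pmin(pmax(findInterval(pairs$het, breaks,
                                     rightmost.closed = TRUE), 1), het_bins)
  null_sorted <- lapply(split(pairs$fst, bin_null), sort)
  bin_obs <- findInterval(obs$het, breaks, rightmost.closed = TRUE)
  out_of_range <- bin_obs < 1 | bin_obs > het_bins
  bin_obs <- pmin(pmax(bin_obs, 1), het_bins)
  p <- rep(NA_real_, nrow(obs))
  for (b in unique(bin_obs[tested])) {
    nb <- null_sorted[[as.character(b)]]
    if (is.null(nb)) nb <- numeric(0)
    sel <- which(tested & bin_obs == b)
    n_ge <- length(nb) - findInterval(obs$fst[sel] - 1e-12, nb)
    p[sel] <- (1 + n_ge) / (1 + length(nb))
  }
  obs$p <- p
  obs$neglog_quantile <- -log10(p)
  obs$outlier <- !is.na(p) & p < alpha
  obs$bonferroni <- !is.na(p) & p < alpha / m
  obs$out_of_range <- out_of_range
  class(obs) <- c("OutlierCall", "data.frame")
  obs
}

#' Full FST outlier scan
#'
#' Convenience wrapper: Weir-Cockerham estimation, null calibration to the
#' observed global FST, and conditioned quantile p-values.
#'
#' @param ds a `GenotypeDataset`.
#' @param cfg a [null_model_config()] (its `target_fst` is overwritten with
#'   the observed global FST).
#' @param deme_group optional deme -> group mapping (default: k-means groups
#'   are the caller's responsibility; all demes in one group).
#' @return list with `fst` (`FstResult`), `null` (`NullDistribution`),
#'   `calls` (`OutlierCall`).
#' @export
scan_fst <- function(ds, cfg = null_model_config(), deme_group = NULL) {
  fr <- wc_fst(ds)
  cfg$target_fst <- fr$global
  sizes <- table(ds$provenance_of)
  deme_sizes <- stats::setNames(as.integer(sizes), names(sizes))
  null <- simulate_null(cfg, deme_sizes, deme_group)
  calls <- outlier_pvalues(fr, null)
  list(fst = fr, null = null, calls = calls)
}
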