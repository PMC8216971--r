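#' Quality-control configuration
#'
#' Defaults are the strict filter settings of a conservative EAA study:
#' MAF >= 0.05, site call rate >= 0.95, exact Hardy-Weinberg test at
#' alpha = 1e-6, LD pruning at |r| <= 0.2, pairwise kinship < 0.25,
#' heterozygosity deficit <= 0.1, sample call rate >= 0.95, and a neutral
#' subset of 1,500 unlinked SNPs.
#'
#' @param maf_min minimum minor allele frequency.
#' @param site_callrate_min minimum per-locus call rate.
#' @param hwe_alpha Hardy-Weinberg exact-test significance threshold.
#' @param ld_r_max maximum |genotype correlation| between retained loci.
#' @param ld_window sliding window size (locus count) for LD pruning.
#' @param kinship_max pairwise kinship cutoff (phi = pi-hat / 2 convention,
#'   so parent-offspring pairs sit at ~0.25); `kinship_convention` may be set
#'   to "pihat" to interpret the cutoff on pi-hat instead.
#' @param het_deficit_max maximum per-sample heterozygosity deficit
#'   F = 1 - Het_obs / Het_exp.
#' @param sample_callrate_min minimum per-sample call rate.
#' @param neutral_subset_size size of the random unlinked neutral SNP subset.
#' @param kinship_convention "phi" (default) or "pihat".
#' @param seed RNG seed for the neutral subset draw.
#' @return list of class `QcConfig`.
#' @export
qc_config <- function(maf_min = 0.05, site_callrate_min = 0.95,
                      hwe_alpha = 1e-6, ld_r_max = 0.2, ld_window = 50,
                      kinship_max = 0.25, het_deficit_max = 0.1,
                      sample_callrate_min = 0.95,
                      neutral_subset_size = 1500,
                      kinship_convention = c("phi", "pihat"), seed = 1) {
  stopifnot(maf_min > 0, maf_min < 1, site_callrate_min > 0,
            site_callrate_min <= 1, hwe_alpha > 0, hwe_alpha < 1,
            ld_r_max > 0, ld_r_max <= 1, ld_window >= 1,
            kinship_max > 0, kinship_max <= 1,
            het_deficit_max > 0, het_deficit_max < 1,
            sample_callrate_min > 0, sample_callrate_min <= 1,
            neutral_subset_size >= 1)
  structure(list(maf_min = maf_min, site_callrate_min = site_callrate_min,
                 hwe_alpha = hwe_alpha, ld_r_max = ld_r_max,
                 ld_window = as.integer(ld_window),
                 kinship_max = kinship_max,
                 het_deficit_max = het_deficit_max,
                 sample_callrate_min = sample_callrate_min,
                 neutral_subset_size = as.integer(neutral_subset_size),
                 kinship_convention = match.arg(kinship_convention),
                 seed = as.integer(seed)),
            class = "QcConfig")
}

.report_row <- function(stage, unit, n_in, n_removed) {
  data.frame(stage = stage, unit = unit, n_in = n_in,
             n_removed = n_removed, n_out = n_in - n_removed,
             stringsAsFactors = FALSE)
}

#' Site-level MAF and call-rate filters
#'
#' Removes loci with minor allele frequency below `maf_min` (computed on
#' non-missing calls; the minor allele is recomputed, not assumed ALT) or
#' call rate below `site_callrate_min`.
#'
#' @param ds a `GenotypeDataset`.
#' @param cfg a [qc_config()].
#' @return list with `dataset` (filtered) and `report` (stage rows).
#' @export
site_filters <- function(ds, cfg = qc_config()) {
  if (!nrow(ds$loci)) stop("empty dataset")
  callrate <- colMeans(!is.na(ds$dosage))
  maf <- minor_allele_freq(ds)
  maf[is.nan(maf)] <- 0
  keep <- maf >= cfg$maf_min & callrate >= cfg$site_callrate_min
  if (!any(keep)) stop("site filters removed all loci")
  list(dataset = subset_dataset(ds, loci = which(keep)),
       report = .report_row("maf+site_callrate", "loci", length(keep),
                            sum(!keep)))
}

#' Exact Hardy-Weinberg test (Levene/Haldane)
#'
#' Two-sided exact p-value obtained by summing, over all heterozygote counts
#' compatible with the observed allele counts, the conditional probabilities
#' no larger than that of the observed configuration. Monomorphic loci give
#' p = 1.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (non-negative, sum >= 1).
#' @return exact p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  stopifnot(n >= 1)
  nA <- 2L * n_AA + n_Aa
  na <- 2L * n_aa + n_Aa
  if (nA == 0L || na == 0L) return(1)
  hs <- seq(nA %% 2L, min(nA, na), by = 2L)
  # log P(h het | n, nA) up to a common constant
  logp <- lgamma(n + 1) - lgamma((nA - hs) / 2 + 1) - lgamma(hs + 1) -
    lgamma((na - hs) / 2 + 1) + hs * log(2)
  logp <- logp - max(logp)
  p <- exp(logp)
  p <- p / sum(p)
  p_obs <- p[match(n_Aa, hs)]
  sum(p[p <= p_obs * (1 + 1e-12)])
}

#' Hardy-Weinberg filter over all loci
#'
#' @param ds a `GenotypeDataset`.
#' @param cfg a [qc_config()].
#' @return list with `dataset`, `report`, and the per-locus `p` values.
#' @export
hwe_filter <- function(ds, cfg = qc_config()) {
  d <- ds$dosage
  n_AA <- colSums(d == 0L, na.rm = TRUE)
  n_Aa <- colSums(d == 1L, na.rm = TRUE)
  n_aa <- colSums(d == 2L, na.rm = TRUE)
  p <- vapply(seq_len(ncol(d)),
              function(j) hwe_exact_test(n_AA[j], n_Aa[j], n_aa[j]),
              numeric(1))
  keep <- p >= cfg$hwe_alpha
  if (!any(keep)) stop("HWE filter removed all loci")
  list(dataset = subset_dataset(ds, loci = which(keep)),
       report = .report_row("hwe", "loci", length(keep), sum(!keep)),
       p = stats::setNames(p, ds$loci$id))
}

#' Greedy sliding-window LD pruning
#'
#' Scaffold-ordered scan: a locus is dropped when its absolute composite
#' genotype correlation (Pearson r of dosages, pairwise-complete) with any
#' already-retained locus among the previous `ld_window` loci on the same
#' scaffold exceeds `ld_r_max`. Deterministic given locus order.
#'
#' @param ds a `GenotypeDataset` (after site filters).
#' @param cfg a [qc_config()].
#' @return character vector of retained locus ids.
#' @export
ld_prune <- function(ds, cfg = qc_config()) {
  ord <- order(ds$loci$scaffold, ds$loci$position)
  d <- ds$dosage
  kept_ord <- integer(0)   # ordinal positions (within ord) of retained loci
  for (k in seq_along(ord)) {
    i <- ord[k]
    cand_ord <- kept_ord[kept_ord >= k - cfg$ld_window]
    cand <- ord[cand_ord]
    cand <- cand[ds$loci$scaffold[cand] == ds$loci$scaffold[i]]
    drop <- FALSE
    if (length(cand)) {
      r <- suppressWarnings(
        stats::cor(d[, i], d[, cand, drop = FALSE],
                   use = "pairwise.complete.obs"))
      r[is.na(r)] <- 0
      drop <- any(abs(r) > cfg$ld_r_max)
    }
    if (!drop) kept_ord <- c(kept_ord, k)
  }
  ds$loci$id[sort(ord[kept_ord])]
}

# Per-locus expected IBS-class probabilities given allele frequency p,
# under IBD = 0, 1, 2. Returns 3x3 matrix [ibs0..2, ibd0..2] summed over loci.
.ibs_expectation <- function(p) {
  q <- 1 - p
  e <- matrix(0, 3, 3)
  e[1, 1] <- sum(2 * p^2 * q^2)
  e[3, 1] <- sum(q^4 + 4 * p^2 * q^2 + p^4)
  e[2, 1] <- length(p) - e[1, 1] - e[3, 1]
  e[2, 2] <- sum(2 * p * q)
  e[3, 2] <- length(p) - e[2, 2]
  e[3, 3] <- length(p)
  e / length(p)
}

#' Method-of-moments IBD sharing and kinship
#'
#' PLINK-style moments estimator: per pair, observed counts of
#' identity-by-state classes (0, 1, 2) over commonly observed loci are
#' matched to their allele-frequency expectations under IBD state 0, 1 and 2;
#' the resulting P(IBD = 0, 1, 2) is clamped to the probability simplex.
#' Kinship is reported as phi = pi-hat / 2 with pi-hat = P1/2 + P2, so a
#' self-comparison gives 0.5 and parent-offspring pairs ~0.25.
#'
#' @param ds a `GenotypeDataset`, ideally restricted to unlinked loci.
#' @param loci optional locus ids to use (default: all).
#' @param min_overlap pairs with fewer overlapping genotypes are flagged
#'   unreliable (kinship still reported).
#' @return list with `phi` (sample x sample kinship matrix), `pihat`,
#'   `ibd` (data.frame of pairs with P0, P1, P2, n_obs, reliable).
#' @export
ibd_kinship <- function(ds, loci = NULL, min_overlap = 50) {
  if (!is.null(loci)) ds <- subset_dataset(ds, loci = loci)
  d <- ds$dosage
  p <- alt_freq(ds)
  ok <- !is.na(p) & p > 0 & p < 1
  d <- d[, ok, drop = FALSE]
  p <- p[ok]
  M <- !is.na(d)
  I0 <- (d == 0L) & M; I1 <- (d == 1L) & M; I2 <- (d == 2L) & M
  storage.mode(I0) <- storage.mode(I1) <- storage.mode(I2) <- "double"
  Mn <- M; storage.mode(Mn) <- "double"
  n_obs <- Mn %*% t(Mn)
  ibs2 <- I0 %*% t(I0) + I1 %*% t(I1) + I2 %*% t(I2)
  ibs0 <- I0 %*% t(I2) + I2 %*% t(I0)
  ibs1 <- n_obs - ibs2 - ibs0
  E <- .ibs_expectation(p)
  Einv <- solve(E)
  ns <- length(ds$samples)
  obs <- rbind(as.vector(ibs0), as.vector(ibs1), as.vector(ibs2)) /
    rep(pmax(as.vector(n_obs), 1), each = 3)
  P <- Einv %*% obs
  P <- pmax(P, 0)
  P <- sweep(P, 2, pmax(colSums(P), 1e-12), `/`)
  pihat <- matrix(P[2, ] / 2 + P[3, ], ns, ns,
                  dimnames = list(ds$samples, ds$samples))
  phi <- pihat / 2
  ut <- which(upper.tri(pihat), arr.ind = TRUE)
  ibd <- data.frame(sample1 = ds$samples[ut[, 1]],
                    sample2 = ds$samples[ut[, 2]],
                    P0 = P[1, (ut[, 2] - 1) * ns + ut[, 1]],
                    P1 = P[2, (ut[, 2] - 1) * ns + ut[, 1]],
                    P2 = P[3, (ut[, 2] - 1) * ns + ut[, 1]],
                    n_obs = n_obs[ut],
                    phi = phi[ut], stringsAsFactors = FALSE)
  ibd$reliable <- ibd$n_obs >= min_overlap
  list(phi = phi, pihat = pihat, ibd = ibd)
}

#' Per-sample heterozygosity deficit
#'
#' F = 1 - Het_obs / Het_exp per sample, computed over the sample's
#' non-missing loci, with expected heterozygosity 2p(1-p) per locus (p the
#' dataset-wide alternative-allele frequency). Positive F indicates a
#' heterozygote deficit (e.g. inbreeding); negative F an excess.
#'
#' @param ds a `GenotypeDataset` (site-filtered).
#' @return named numeric vector of per-sample F values.
#' @export
het_deficit <- function(ds) {
  d <- ds$dosage
  p <- alt_freq(ds)
  he <- 2 * p * (1 - p)
  M <- !is.na(d)
  het_obs <- rowSums(d == 1L, na.rm = TRUE) / rowSums(M)
  het_exp <- (M %*% he) / rowSums(M)
  stats::setNames(1 - het_obs / as.vector(het_exp), ds$samples)
}

#' Sample-level filters: call rate, heterozygosity deficit, kinship
#'
#' Removes samples with call rate below `sample_callrate_min` or
#' heterozygosity deficit above `het_deficit_max`; then resolves remaining
#' pairs with kinship at or above `kinship_max` by removing the lower-call-
#' rate member (tie: the later sample id).
#'
#' @param ds a site-filtered `GenotypeDataset`.
#' @param cfg a [qc_config()].
#' @param kinship kinship matrix from [ibd_kinship()] (`phi` or `pihat`
#'   according to `cfg$kinship_convention`); `NULL` skips the kinship step.
#' @return list with `dataset`, `report` (stage rows), and `removed`
#'   (data.frame sample, reason).
#' @export
sample_filters <- function(ds, cfg = qc_config(), kinship = NULL) {
  callrate <- rowMeans(!is.na(ds$dosage))
  f <- het_deficit(ds)
  removed <- character(0)
  reason <- character(0)
  low_cr <- ds$samples[callrate < cfg$sample_callrate_min]
  removed <- c(removed, low_cr)
  reason <- c(reason, rep("call_rate", length(low_cr)))
  hd <- setdiff(ds$samples[f > cfg$het_deficit_max], removed)
  removed <- c(removed, hd)
  reason <- c(reason, rep("het_deficit", length(hd)))
  n_kin <- 0L
  if (!is.null(kinship)) {
    keep_now <- setdiff(ds$samples, removed)
    k <- kinship[keep_now, keep_now, drop = FALSE]
    repeat {
      diag(k) <- 0
      mx <- which(k >= cfg$kinship_max, arr.ind = TRUE)
      if (!nrow(mx)) break
      i <- mx[1, 1]; j <- mx[1, 2]
      s1 <- rownames(k)[i]; s2 <- rownames(k)[j]
      cr1 <- callrate[match(s1, ds$samples)]
      cr2 <- callrate[match(s2, ds$samples)]
      drop_s <- if (cr1 < cr2) s1 else if (cr2 < cr1) s2 else max(s1, s2)
      removed <- c(removed, drop_s)
      reason <- c(reason, "kinship")
      n_kin <- n_kin + 1L
      keep_now <- setdiff(keep_now, drop_s)
      k <- k[keep_now, keep_now, drop = FALSE]
    }
  }
  keep <- setdiff(ds$samples, removed)
  if (!length(keep)) stop("sample filters removed all samples")
  rep1 <- .report_row("sample_callrate", "samples", length(ds$samples),
                      length(low_cr))
  rep2 <- .report_row("het_deficit", "samples", rep1$n_out, length(hd))
  rep3 <- .report_row("kinship", "samples", rep2$n_out, n_kin)
  list(dataset = subset_dataset(ds, samples = keep),
       report = rbind(rep1, rep2, rep3),
       removed = data.frame(sample = removed, reason = reason,
                            stringsAsFactors = FALSE),
       het_f = f)
}

#' Random neutral SNP subset
#'
#' Uniform sample without replacement of `neutral_subset_size` locus ids
#' (all loci with a warning when fewer are available), seeded by
#' `cfg$seed` so the draw is reproducible.
#'
#' @param ds an LD-pruned `GenotypeDataset`.
#' @param cfg a [qc_config()].
#' @return character vector of locus ids.
#' @export
neutral_subset <- function(ds, cfg = qc_config()) {
  ids <- ds$loci$id
  k <- cfg$neutral_subset_size
  if (length(ids) <= k) {
    if (length(ids) < k)
      warning("only ", length(ids), " loci available for neutral subset of ",
              k)
    return(ids)
  }
  with_seed(cfg$seed, sort(sample(ids, k)))
}

#' Run the full QC cascade
#'
#' Fixed order: site filters (MAF, call rate) -> Hardy-Weinberg -> LD pruning
#' -> sample filters (call rate, heterozygosity deficit, kinship on the
#' pruned loci). MAF and HWE are computed once on the input sample set (one
#' pass, no iterative re-filtering). The telescoping `QcReport` and the
#' random neutral subset are returned alongside the filtered dataset.
#'
#' @param ds a `GenotypeDataset`.
#' @param cfg a [qc_config()].
#' @return list of class `QcResult` with `dataset`, `report`,
#'   `neutral_loci`, `kinship`, `het_f`, `removed_samples`.
#' @export
run_qc <- function(ds, cfg = qc_config()) {
  s1 <- site_filters(ds, cfg)
  s2 <- hwe_filter(s1$dataset, cfg)
  kept_ld <- ld_prune(s2$dataset, cfg)
  rep_ld <- .report_row("ld_prune", "loci", nrow(s2$dataset$loci),
                        nrow(s2$dataset$loci) - length(kept_ld))
  ds_ld <- subset_dataset(s2$dataset, loci = kept_ld)
  kin <- ibd_kinship(ds_ld)
  kmat <- if (cfg$kinship_convention == "phi") kin$phi else kin$pihat
  s4 <- sample_filters(ds_ld, cfg, kinship = kmat)
  report <- rbind(s1$report, s2$report, rep_ld, s4$report)
  out <- list(dataset = s4$dataset,
              report = report,
              neutral_loci = neutral_subset(s4$dataset, cfg),
              kinship = kin,
              het_f = s4$het_f,
              removed_samples = s4$removed,
              hwe_p = s2$p)
  class(out) <- "QcResult"
  out
}

#' @export
print.QcResult <- function(x, ...) {
  cat("QC cascade report:\n")
  print(x$report, row.names = FALSE)
  cat("Retained:", length(x$dataset$samples), "samples x",
      nrow(x$dataset$loci), "loci;", length(x$neutral_loci),
      "neutral subset loci\n")
  invisible(x)
}

#' Serialize a QC report to JSON
#'
#' @param qc a `QcResult`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(qc, path) {
  jsonlite::write_json(list(report = qc$report,
                            removed_samples = qc$removed_samples,
                            n_neutral = length(qc$neutral_loci)),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
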