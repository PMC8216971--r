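#' Per-method shortlists from scan outputs
#'
#' Applies the standard decision thresholds: FST-outlier scan
#' `-log10(1 - FST quantile) > 1.3` (p < 0.05 against the simulated null),
#' F-model scan `-log10(q) > 1.3`, Bayes-factor scan `BF > 30 and
#' |rho| > 0.4`, LFMM `-log10(p) > 1.3` (calibrated p; Bonferroni flags are
#' carried separately). All scans must cover the same locus set.
#'
#' @param fst_calls `OutlierCall` data.frame (per axis-independent), or NULL.
#' @param lfmm_table `LfmmTest$table` rows for one axis, or NULL.
#' @param bayenv `EnvAssocResult` for one axis, or NULL.
#' @param fmodel `FModelResult` for one axis, or NULL.
#' @param check_loci require identical locus sets across scans (default
#'   TRUE).
#' @return named list of character vectors: `arlequin`, `lfmm`, `bayenv`,
#'   `bayscenv` shortlisted locus ids, plus `lfmm_rank` (named -log10 p for
#'   ranking).
#' @export
build_shortlists <- function(fst_calls = NULL, lfmm_table = NULL,
                             bayenv = NULL, fmodel = NULL,
                             check_loci = TRUE) {
  sets <- list(
    arlequin = if (!is.null(fst_calls)) fst_calls$locus,
    lfmm = if (!is.null(lfmm_table)) lfmm_table$locus,
    bayenv = if (!is.null(bayenv)) bayenv$locus,
    bayscenv = if (!is.null(fmodel)) fmodel$locus)
  sets <- Filter(Negate(is.null), sets)
  if (check_loci && length(sets) > 1) {
    base <- sort(sets[[1]])
    for (s in sets[-1])
      if (!identical(sort(s), base)) stop("locus sets differ between scans")
  }
  out <- list(
    arlequin = if (is.null(fst_calls)) character(0) else
      fst_calls$locus[which(fst_calls$outlier)],
    lfmm = if (is.null(lfmm_table)) character(0) else
      lfmm_table$locus[which(-log10(lfmm_table$p_cal) > 1.3)],
    bayenv = if (is.null(bayenv)) character(0) else
      bayenv$locus[which(bayenv$shortlist)],
    bayscenv = if (is.null(fmodel)) character(0) else
      fmodel$locus[which(fmodel$shortlist)])
  out$lfmm_rank <- if (is.null(lfmm_table)) numeric(0) else
    stats::setNames(-log10(lfmm_table$p_cal), lfmm_table$locus)
  out
}

#' Consensus set under the capped two-method rule
#'
#' A locus enters the consensus when it belongs to at least two method
#' shortlists, except that the (typically very large) Arlequin-and-LFMM
#' intersection contributes only its top `cap` members ranked by the LFMM
#' `-log10 p` (ties broken by locus id). Loci capped out of that pair but
#' qualifying through another pair remain in the consensus. Venn counts for
#' all method pairs and triples are reported from the uncapped shortlists.
#'
#' @param shortlists list with `arlequin`, `lfmm`, `bayenv`, `bayscenv`
#'   (character vectors) and `lfmm_rank` (named numeric), as from
#'   [build_shortlists()].
#' @param cap cap on the Arlequin-LFMM intersection (default 5).
#' @return list of class `ConsensusReport`: `consensus` (locus ids),
#'   `venn_pairs`, `venn_triples` (named counts), `capped_pair` (the capped
#'   Arlequin-LFMM members), `shortlist_sizes`.
#' @export
consensus_sets <- function(shortlists, cap = 5) {
  methods <- c("arlequin", "lfmm", "bayenv", "bayscenv")
  sl <- lapply(shortlists[methods], unique)
  rank <- shortlists$lfmm_rank
  pairs <- utils::combn(methods, 2, simplify = FALSE)
  inter <- lapply(pairs, function(pr) intersect(sl[[pr[1]]], sl[[pr[2]]]))
  names(inter) <- vapply(pairs, paste, "", collapse = "&")
  al <- inter[["arlequin&lfmm"]]
  capped <- al
  if (length(al) > cap) {
    r <- rank[al]
    r[is.na(r)] <- -Inf
    ord <- order(-r, al)
    capped <- al[ord][seq_len(cap)]
  }
  contrib <- inter
  contrib[["arlequin&lfmm"]] <- capped
  consensus <- sort(unique(unlist(contrib)))
  triples <- utils::combn(methods, 3, simplify = FALSE)
  venn_triples <- vapply(triples, function(tr)
    length(Reduce(intersect, sl[tr])), integer(1))
  names(venn_triples) <- vapply(triples, paste, "", collapse = "&")
  structure(list(consensus = consensus,
                 venn_pairs = vapply(inter, length, integer(1)),
                 venn_triples = venn_triples,
                 capped_pair = capped,
                 shortlist_sizes = vapply(sl, length, integer(1)),
                 cap = cap),
            class = "ConsensusReport")
}

#' @export
print.ConsensusReport <- function(x, ...) {
  cat("ConsensusReport:", length(x$consensus), "consensus loci",
      "(cap", x$cap, "on arlequin&lfmm)\n")
  cat("shortlists:", paste(names(x$shortlist_sizes), x$shortlist_sizes,
                           sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Allele-frequency / climate correlation per locus
#'
#' Pearson correlation (with two-sided t test) between per-provenance
#' alternative-allele frequencies and a provenance-level climate variable.
#'
#' @param ds a `GenotypeDataset`.
#' @param loci locus ids to test.
#' @param climate_var named numeric vector: provenance -> climate value.
#' @return data.frame: locus, r, p, n (monomorphic loci get NA, flagged).
#' @export
allele_freq_climate_corr <- function(ds, loci, climate_var) {
  fr <- deme_freqs(ds, loci = loci)
  provs <- intersect(rownames(fr$freq), names(climate_var))
  if (length(provs) < 5) stop("need >= 5 provenances")
  x <- climate_var[provs]
  out <- lapply(colnames(fr$freq), function(l) {
    f <- fr$freq[provs, l]
    ok <- !is.na(f)
    if (sum(ok) < 5 || stats::sd(f[ok]) == 0)
      return(data.frame(locus = l, r = NA_real_, p = NA_real_,
                        n = sum(ok), monomorphic = TRUE))
    ct <- stats::cor.test(f[ok], x[ok])
    data.frame(locus = l, r = unname(ct$estimate), p = ct$p.value,
               n = sum(ok), monomorphic = FALSE)
  })
  do.call(rbind, out)
}

#' Eigenvector discrimination of consensus versus random neutral SNPs
#'
#' Computes the first two genotype eigenvectors once from the consensus loci
#' and once from an equal-sized random draw of neutral loci, and scores how
#' well a two-group sample labeling separates on EV1 via the between-group
#' sum of squares fraction (eta squared).
#'
#' @param ds a `GenotypeDataset`.
#' @param consensus_loci locus ids of the consensus set (>= 2).
#' @param neutral_pool locus ids to draw the random comparison set from.
#' @param labels named vector (sample -> group) with exactly two levels;
#'   defaults to splitting provenances by the sign of the structure via
#'   k-means on EV1 of the neutral pool.
#' @param seed RNG seed for the random draw.
#' @return list with `ev_consensus`, `ev_random` (sample x 2 matrices),
#'   `eta2_consensus`, `eta2_random`, `random_loci`.
#' @export
eigen_discrimination <- function(ds, consensus_loci, neutral_pool, labels,
                                 seed = 1) {
  if (length(consensus_loci) < 2) stop("need >= 2 consensus loci")
  pool <- setdiff(neutral_pool, consensus_loci)
  if (length(pool) < length(consensus_loci))
    stop("fewer neutral loci (", length(pool), ") than requested (",
         length(consensus_loci), ")")
  rnd <- with_seed(seed, sample(pool, length(consensus_loci)))
  eta2 <- function(ev1, g) {
    g <- as.factor(g)
    gm <- tapply(ev1, g, mean)
    ss_b <- sum(table(g) * (gm - mean(ev1))^2)
    ss_t <- sum((ev1 - mean(ev1))^2)
    if (ss_t == 0) 0 else ss_b / ss_t
  }
  pc_c <- genotype_pca(ds, loci = consensus_loci, n_components = 2)
  pc_r <- genotype_pca(ds, loci = rnd, n_components = 2)
  g <- labels[ds$samples]
  list(ev_consensus = pc_c$vectors, ev_random = pc_r$vectors,
       eta2_consensus = eta2(pc_c$vectors[, 1], g),
       eta2_random = eta2(pc_r$vectors[, 1], g),
       random_loci = rnd)
}
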