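#' Round half-up to a fixed number of decimals
#'
#' Matches the reporting convention for printed percentages (0.125 -> 0.13
#' at 2 decimals), unlike base R's round-half-even.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded numeric.
#' @export
round_half_up <- function(x, digits = 2) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Percentage of tested loci, printed-style
#'
#' `100 * count / total`, rounded half-up to two decimals (so 11 of 17,489
#' gives 0.06 and 29 of 17,489 gives 0.17).
#'
#' @param count numerator.
#' @param total denominator.
#' @return percentage rounded to 2 decimals.
#' @export
adaptive_fraction_pct <- function(count, total) {
  round_half_up(100 * count / total, 2)
}

#' Bonferroni threshold on the -log10 scale
#'
#' @param m number of tests.
#' @param alpha family-wise level (default 0.05).
#' @param digits rounding (default 2, the printed convention).
#' @return `-log10(alpha / m)`, rounded half-up.
#' @export
bonferroni_neglog10 <- function(m, alpha = 0.05, digits = 2) {
  round_half_up(-log10(alpha / m), digits)
}

#' Pipeline run configuration
#'
#' Bundles every stage configuration. When `sim` is provided the pipeline
#' generates its inputs; otherwise `paths` must point to the VCF/CSV inputs.
#' The null-model locus count defaults to 20,000 here (a desk-scale
#' reduction of the canonical 200,000; set `null_cfg` explicitly for the
#' full size).
#'
#' @param sim a [sim_config()] or NULL.
#' @param paths named list: vcf, provenances, climate, rings, site_climate.
#' @param qc a [qc_config()].
#' @param detrend a [detrend_config()].
#' @param null_cfg a [null_model_config()].
#' @param axes environmental PC axes to scan (default 1:2).
#' @param alpha scan significance level.
#' @param bf_min,rho_min Bayes-factor shortlist thresholds.
#' @param cap consensus cap on the Arlequin-LFMM intersection.
#' @param k_range ancestry K values scanned.
#' @param n_perm RDA permutations.
#' @param n_boot response-function bootstrap replicates.
#' @param out_dir output directory (created).
#' @param seed master seed; stage seeds are derived from it.
#' @return list of class `RunConfig`.
#' @export
run_config <- function(sim = sim_config(), paths = NULL,
                       qc = qc_config(), detrend = detrend_config(),
                       null_cfg = null_model_config(n_simulated_loci = 20000),
                       axes = 1:2, alpha = 0.05, bf_min = 30, rho_min = 0.4,
                       cap = 5, k_range = 1:6, n_perm = 199, n_boot = 1000,
                       out_dir = tempfile("provscan_run_"), seed = 1) {
  structure(list(sim = sim, paths = paths, qc = qc, detrend = detrend,
                 null_cfg = null_cfg, axes = axes, alpha = alpha,
                 bf_min = bf_min, rho_min = rho_min, cap = cap,
                 k_range = k_range, n_perm = n_perm, n_boot = n_boot,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "RunConfig")
}

.write_csv <- function(x, dir, name) {
  utils::write.csv(x, file.path(dir, name), row.names = FALSE)
}

.log_stage <- function(...) message("[provscan] ", ...)

#' Run the full EAA pipeline
#'
#' Stage order: input (read or simulate) -> QC cascade -> climate PCA ->
#' dendroclimatic traits and cline -> four genome scans (FST outlier, LFMM,
#' Bayes factors, F-model) on the selected climate PCs -> consensus ->
#' interrogation (allele-frequency/climate correlation, eigenvector
#' discrimination) -> ancestry and RDA. Every intermediate is written to
#' `cfg$out_dir` as CSV; the returned report carries counts, the consensus
#' adaptive fractions as printed percentages, and all effective seeds and
#' thresholds. Deterministic given `cfg`.
#'
#' @param cfg a [run_config()].
#' @return list of class `RunReport`.
#' @export
run_pipeline <- function(cfg = run_config()) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- "input"
  report <- list(seed = cfg$seed, out_dir = cfg$out_dir, stages = character(0))
  res <- try({
    if (!is.null(cfg$sim)) {
      .log_stage("simulating inputs (seed ", cfg$sim$seed, ")")
      sim <- simulate_genotypes(cfg$sim)
      ds <- sim$dataset
      truth <- sim$truth
      climate <- simulate_climate(cfg$sim)
      prov <- simulate_provenances(cfg$sim)
      rr <- simulate_rings(cfg$sim)
      rings <- rr$rings; site_climate <- rr$site_climate
      write_vcf(ds, file.path(cfg$out_dir, "genotypes.vcf"))
    } else {
      .log_stage("reading inputs")
      truth <- NULL
      tabs <- read_tables(cfg$paths$provenances, cfg$paths$climate,
                          cfg$paths$rings, cfg$paths$site_climate)
      prov <- tabs$provenances; climate <- tabs$climate
      rings <- tabs$rings; site_climate <- tabs$site_climate
      pm <- stats::setNames(rep(prov$id, prov$n_samples), NULL)
      ds <- read_vcf(cfg$paths$vcf)
    }
    stage <- "qc"
    .log_stage("QC cascade")
    qc <- run_qc(ds, cfg$qc)
    .write_csv(qc$report, cfg$out_dir, "qc_report.csv")
    write_qc_report(qc, file.path(cfg$out_dir, "qc_report.json"))
    dsq <- qc$dataset

    stage <- "climate_pca"
    .log_stage("climate PCA")
    pcs <- climate_pca(climate)
    .write_csv(data.frame(provenance = rownames(pcs$scores), pcs$scores),
               cfg$out_dir, "env_pcs.csv")

    stage <- "traits"
    traits <- NULL; clines <- NULL
    if (!is.null(rings)) {
      .log_stage("dendroclimatic traits")
      traits <- response_cline_traits(rings, site_climate, cfg$detrend,
                                      n_boot = cfg$n_boot,
                                      seed = cfg$seed + 101L)
      .write_csv(traits, cfg$out_dir, "response.csv")
      coefs <- stats::setNames(traits$coef, traits$provenance)
      clines <- lapply(cfg$axes, function(a) {
        cl <- cline_regression(coefs, stats::setNames(
          pcs$scores[, a], rownames(pcs$scores)))
        data.frame(axis = a, r = cl$r, p = cl$p)
      })
      clines <- do.call(rbind, clines)
      .write_csv(clines, cfg$out_dir, "trait_cline.csv")
    }

    stage <- "scan_fst"
    .log_stage("FST outlier scan (",
               cfg$null_cfg$n_simulated_loci, " null loci)")
    ncfg <- cfg$null_cfg
    ncfg$seed <- cfg$seed + 201L
    groups <- genotype_groups(dsq, loci = qc$neutral_loci, k = 2,
                              seed = cfg$seed + 202L)
    fstscan <- scan_fst(dsq, ncfg, deme_group = groups)
    .write_csv(fstscan$calls, cfg$out_dir, "fst_scan.csv")

    stage <- "scan_lfmm"
    .log_stage("LFMM scan")
    K <- max(1L, choose_k(dsq, loci = qc$neutral_loci))
    lfmm <- scan_lfmm(dsq, pcs$scores[, cfg$axes, drop = FALSE], K = K,
                      alpha = cfg$alpha)
    .write_csv(lfmm$test$table, cfg$out_dir, "lfmm_scan.csv")
    .log_stage("LFMM K = ", K, "; lambda_GC = ",
               paste(round(lfmm$test$gif, 3), collapse = ", "))

    stage <- "scan_bayenv"
    .log_stage("Bayes-factor scan")
    fr_all <- deme_freqs(dsq)
    fr_neutral <- deme_freqs(dsq, loci = qc$neutral_loci)
    omega <- estimate_omega(fr_neutral$freq)
    prov_order <- rownames(fr_all$freq)
    bayenv <- lapply(cfg$axes, function(a) {
      r <- env_bayes_factor(fr_all$freq, pcs$scores[prov_order, a], omega,
                            bf_min = cfg$bf_min, rho_min = cfg$rho_min)
      r$axis <- a
      r
    })
    .write_csv(do.call(rbind, bayenv), cfg$out_dir, "bayenv_scan.csv")

    stage <- "scan_fmodel"
    .log_stage("F-model scan")
    fmodel <- lapply(cfg$axes, function(a) {
      r <- fmodel_env_scan(fr_all$counts, fr_all$sizes,
                           pcs$scores[prov_order, a], alpha = cfg$alpha)
      r$axis <- a
      r
    })
    .write_csv(do.call(rbind, fmodel), cfg$out_dir, "fmodel_scan.csv")

    stage <- "consensus"
    .log_stage("consensus sets")
    m_tested <- sum(!is.na(fstscan$calls$fst))
    consensus <- list()
    for (i in seq_along(cfg$axes)) {
      a <- cfg$axes[i]
      sl <- build_shortlists(
        fst_calls = fstscan$calls,
        lfmm_table = lfmm$test$table[lfmm$test$table$axis == i, ],
        bayenv = bayenv[[i]], fmodel = fmodel[[i]])
      consensus[[i]] <- consensus_sets(sl, cap = cfg$cap)
    }
    cons_df <- do.call(rbind, lapply(seq_along(cfg$axes), function(i)
      if (length(consensus[[i]]$consensus))
        data.frame(axis = cfg$axes[i], locus = consensus[[i]]$consensus)
      else NULL))
    if (!is.null(cons_df)) .write_csv(cons_df, cfg$out_dir, "consensus.csv")
    venn_df <- do.call(rbind, lapply(seq_along(cfg$axes), function(i) {
      cr <- consensus[[i]]
      data.frame(axis = cfg$axes[i],
                 cell = c(names(cr$venn_pairs), names(cr$venn_triples)),
                 count = c(cr$venn_pairs, cr$venn_triples))
    }))
    .write_csv(venn_df, cfg$out_dir, "venn.csv")

    stage <- "interrogation"
    all_cons <- unique(unlist(lapply(consensus, `[[`, "consensus")))
    interrogation <- NULL
    if (length(all_cons) >= 2) {
      .log_stage("interrogating ", length(all_cons), " consensus loci")
      clim_var <- stats::setNames(climate[, 1], rownames(climate))
      afc <- allele_freq_climate_corr(dsq, all_cons, clim_var)
      .write_csv(afc, cfg$out_dir, "allele_freq_climate.csv")
      grp2 <- genotype_groups(dsq, loci = qc$neutral_loci, k = 2,
                              seed = cfg$seed + 301L)
      labels <- stats::setNames(grp2[dsq$provenance_of], dsq$samples)
      eig <- eigen_discrimination(dsq, all_cons,
                                  setdiff(qc$neutral_loci, all_cons),
                                  labels, seed = cfg$seed + 302L)
      interrogation <- list(allele_freq_corr = afc,
                            eta2_consensus = eig$eta2_consensus,
                            eta2_random = eig$eta2_random)
    }

    stage <- "ancestry_rda"
    .log_stage("ancestry and RDA")
    anc <- snmf_ancestry(dsq, loci = qc$neutral_loci, k_range = cfg$k_range,
                         seed = cfg$seed + 401L)
    .write_csv(data.frame(K = as.integer(names(anc$cross_entropy)),
                          cross_entropy = anc$cross_entropy),
               cfg$out_dir, "crossentropy.csv")
    q2 <- .snmf_fit(.impute_half_dosage(subset_dataset(
      dsq, loci = qc$neutral_loci)), 2, seed = cfg$seed + 402L)$Q
    rownames(q2) <- dsq$samples
    .write_csv(data.frame(sample = dsq$samples, q1 = q2[, 1], q2 = q2[, 2]),
               cfg$out_dir, "ancestry_Q.csv")
    rda <- rda_models(dsq, pcs$scores, prov,
                      stats::setNames(q2[, 1], dsq$samples),
                      n_perm = cfg$n_perm, seed = cfg$seed + 403L)
    .write_csv(rda, cfg$out_dir, "rda.csv")

    stage <- "report"
    shortlist_sizes <- lapply(consensus, `[[`, "shortlist_sizes")
    cons_sizes <- vapply(consensus, function(cr)
      length(cr$consensus), integer(1))
    total_consensus <- length(all_cons)
    list(
      qc = qc$report,
      n_samples = length(dsq$samples),
      n_loci_tested = m_tested,
      env_explained_pc12 = 100 * sum(pcs$explained[1:2]),
      traits = traits, clines = clines,
      lfmm_k = K, lfmm_gif = lfmm$test$gif,
      bonferroni_neglog10 = bonferroni_neglog10(m_tested, cfg$alpha),
      shortlist_sizes = shortlist_sizes,
      consensus_sizes = cons_sizes,
      consensus_pct = vapply(cons_sizes, adaptive_fraction_pct,
                             numeric(1), total = m_tested),
      total_consensus = total_consensus,
      total_consensus_pct = adaptive_fraction_pct(total_consensus, m_tested),
      interrogation = interrogation,
      ancestry_chosen_k = anc$chosen_k,
      rda = rda,
      truth = truth,
      consensus = consensus,
      thresholds = list(alpha = cfg$alpha, bf_min = cfg$bf_min,
                        rho_min = cfg$rho_min, cap = cfg$cap,
                        neglog10_alpha = round_half_up(-log10(cfg$alpha), 2))
    )
  }, silent = TRUE)
  if (inherits(res, "try-error"))
    stop("pipeline failed at stage '", stage, "': ",
         attr(res, "condition")$message)
  report <- c(report, res)
  class(report) <- "RunReport"
  jsonlite::write_json(
    list(n_samples = report$n_samples, n_loci_tested = report$n_loci_tested,
         consensus_sizes = report$consensus_sizes,
         consensus_pct = report$consensus_pct,
         thresholds = report$thresholds, seed = report$seed),
    file.path(cfg$out_dir, "run_report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report
}

# dosage/2 with mean imputation, used for ancestry refits
.impute_half_dosage <- function(ds) {
  X <- ds$dosage / 2
  mu <- colMeans(X, na.rm = TRUE)
  idx <- which(is.na(X), arr.ind = TRUE)
  if (nrow(idx)) X[idx] <- mu[idx[, 2]]
  X
}

#' @export
print.RunReport <- function(x, ...) {
  cat("provscan run report\n")
  cat("  samples:", x$n_samples, " tested loci:", x$n_loci_tested, "\n")
  cat("  climate PC1+PC2 explained:",
      sprintf("%.1f%%", x$env_explained_pc12), "\n")
  cat("  LFMM K:", x$lfmm_k, " lambda_GC:",
      paste(round(x$lfmm_gif, 3), collapse = ", "), "\n")
  cat("  consensus per axis:", paste(x$consensus_sizes, collapse = ", "),
      sprintf("(%s%%)", paste(x$consensus_pct, collapse = ", ")), "\n")
  cat("  ancestry K:", x$ancestry_chosen_k, "\n")
  invisible(x)
}
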