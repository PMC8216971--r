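# Run code under a local RNG seed, restoring caller RNG state afterwards.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulation configuration
#'
#' Describes the hierarchical island world the simulator generates: demes
#' nested in groups, Balding-Nichols differentiation between groups (`F_CT`)
#' and between demes within groups (`F_SC`), and planted climate-adaptive
#' loci whose deme allele frequencies follow a logistic cline in a deme-level
#' environmental gradient.
#'
#' Defaults mirror the shape of a 16-provenance common-garden study at desk
#' scale: 2 groups x 8 demes x 11 samples (176 trees) and 2,020 loci.
#'
#' @param n_groups number of groups (ancestral clusters).
#' @param demes_per_group demes nested in each group.
#' @param samples_per_deme diploid samples per deme.
#' @param n_neutral_loci,n_adaptive_loci locus counts.
#' @param F_CT,F_SC between-group and within-group differentiation, in [0,1).
#' @param env_effect_b logit-scale slope of adaptive-locus deme frequency on
#'   the standardized environmental gradient.
#' @param env_structure_corr correlation between the environmental gradient
#'   and the neutral structure axis (group membership), in [-1,1]; dials
#'   isolation-by-environment against isolation-by-distance confounding.
#' @param missing_rate MCAR genotype missingness rate.
#' @param n_related_pairs planted parent-offspring pairs (kinship 0.25).
#' @param n_inbred planted selfing-like inbred samples (F = 0.5).
#' @param seed integer RNG seed; all generators are pure in (config, seed).
#' @return a list of class `SimConfig`.
#' @export
sim_config <- function(n_groups = 2, demes_per_group = 8,
                       samples_per_deme = 11,
                       n_neutral_loci = 2000, n_adaptive_loci = 20,
                       F_CT = 0.03, F_SC = 0.03,
                       env_effect_b = 1, env_structure_corr = 0.3,
                       missing_rate = 0.02,
                       n_related_pairs = 0, n_inbred = 0, seed = 1) {
  stopifnot(n_groups >= 1, demes_per_group >= 1, samples_per_deme >= 1,
            n_neutral_loci >= 0, n_adaptive_loci >= 0,
            F_CT >= 0, F_CT < 1, F_SC >= 0, F_SC < 1,
            env_structure_corr >= -1, env_structure_corr <= 1,
            missing_rate >= 0, missing_rate < 1,
            n_related_pairs >= 0, n_inbred >= 0)
  cfg <- list(n_groups = n_groups, demes_per_group = demes_per_group,
              samples_per_deme = samples_per_deme,
              n_neutral_loci = n_neutral_loci,
              n_adaptive_loci = n_adaptive_loci,
              F_CT = F_CT, F_SC = F_SC, env_effect_b = env_effect_b,
              env_structure_corr = env_structure_corr,
              missing_rate = missing_rate,
              n_related_pairs = n_related_pairs, n_inbred = n_inbred,
              seed = as.integer(seed))
  class(cfg) <- "SimConfig"
  cfg
}

# Deterministic deme-level environment and structure axis shared by the
# genotype and climate simulators: env = rho * structure + sqrt(1-rho^2) * z.
.sim_env <- function(cfg) {
  n_demes <- cfg$n_groups * cfg$demes_per_group
  group_of <- rep(seq_len(cfg$n_groups), each = cfg$demes_per_group)
  with_seed(cfg$seed * 7L + 11L, {
    s <- as.numeric(scale(group_of + stats::rnorm(n_demes, sd = 0.25)))
    z <- stats::rnorm(n_demes)
    r <- stats::resid(stats::lm(z ~ s))
    z <- if (stats::sd(r) > 1e-12) as.numeric(scale(r))
         else as.numeric(scale(z))
    rho <- cfg$env_structure_corr
    e <- rho * s + sqrt(1 - rho^2) * z
    e <- as.numeric(scale(e))
    list(env = e, structure_axis = s, group_of = group_of,
         deme_ids = sprintf("G%dD%d", group_of,
                            sequence(rep(cfg$demes_per_group, cfg$n_groups))))
  })
}

# Balding-Nichols draw: Beta(p(1-F)/F, (1-p)(1-F)/F); F = 0 returns p.
rbn <- function(n, p, F) {
  if (F <= 0) return(rep_len(p, n))
  stats::rbeta(n, p * (1 - F) / F, (1 - p) * (1 - F) / F)
}

#' Simulate genotypes under a hierarchical island model
#'
#' Ancestral allele frequencies are Uniform(0.05, 0.95); group frequencies
#' are Balding-Nichols around the ancestral frequency with parameter `F_CT`,
#' deme frequencies Balding-Nichols around the group frequency with `F_SC`.
#' For adaptive loci the deme frequency is shifted on the logit scale by
#' `env_effect_b` times the deme's standardized environment. Genotypes are
#' Binomial(2, deme frequency); missingness is MCAR. Parent-offspring pairs
#' are planted by gamete sampling and inbred samples by selfing-like draws
#' with inbreeding coefficient 0.5.
#'
#' @param cfg a [sim_config()].
#' @return list with elements `dataset` (a `GenotypeDataset`) and `truth`
#'   (a `SimTruth` list: `locus_class`, `effect`, `env`, `group_of_deme`,
#'   `ancestry` sample x group matrix, `related_pairs`, `inbred`).
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  n_demes <- cfg$n_groups * cfg$demes_per_group
  n_samp <- n_demes * cfg$samples_per_deme
  if (2 * cfg$n_related_pairs + cfg$n_inbred > n_samp)
    stop("infeasible config: more planted samples than available")
  n_loci <- cfg$n_neutral_loci + cfg$n_adaptive_loci
  if (n_loci < 1) stop("infeasible config: zero loci")
  envinfo <- .sim_env(cfg)
  with_seed(cfg$seed, {
    locus_class <- rep("neutral", n_loci)
    # scatter planted loci across the genome so they never co-occur in an
    # LD-pruning window (they are mutually correlated through the cline)
    if (cfg$n_adaptive_loci > 0)
      locus_class[unique(round(seq(1, n_loci,
                                   length.out = cfg$n_adaptive_loci)))] <-
        "adaptive"
    if (sum(locus_class == "adaptive") != cfg$n_adaptive_loci)
      stop("cannot scatter ", cfg$n_adaptive_loci, " adaptive loci among ",
           n_loci)
    effect <- ifelse(locus_class == "adaptive", cfg$env_effect_b, 0)
    p_anc <- stats::runif(n_loci, 0.05, 0.95)
    # adaptive loci are planted at intermediate ancestral frequency so every
    # planted locus carries a usable cline (logit shifts are flat near 0/1)
    adp0 <- which(locus_class == "adaptive")
    if (length(adp0)) p_anc[adp0] <- stats::runif(length(adp0), 0.2, 0.8)
    # group freqs: n_groups x n_loci
    gfreq <- matrix(rbn(cfg$n_groups * n_loci, rep(p_anc, each = cfg$n_groups),
                        cfg$F_CT), nrow = cfg$n_groups)
    # deme freqs: n_demes x n_loci
    dfreq <- matrix(rbn(n_demes * n_loci,
                        as.vector(gfreq[envinfo$group_of, ]), cfg$F_SC),
                    nrow = n_demes)
    dfreq <- pmin(pmax(dfreq, 1e-6), 1 - 1e-6)
    adp <- which(locus_class == "adaptive")
    if (length(adp))
      dfreq[, adp] <- stats::plogis(
        stats::qlogis(dfreq[, adp, drop = FALSE]) +
          outer(envinfo$env, effect[adp]))
    deme_of <- rep(seq_len(n_demes), each = cfg$samples_per_deme)
    pmat <- dfreq[deme_of, , drop = FALSE]        # samples x loci
    dosage <- matrix(stats::rbinom(length(pmat), 2L, as.vector(pmat)),
                     nrow = n_samp)
    samples <- sprintf("%s_%02d", envinfo$deme_ids[deme_of],
                       sequence(rep(cfg$samples_per_deme, n_demes)))
    # planted parent-offspring pairs: offspring replaces the sample after
    # the parent in the same deme; one gamete from parent, one from deme pool
    related_pairs <- NULL
    if (cfg$n_related_pairs > 0) {
      if (cfg$samples_per_deme < 2)
        stop("infeasible config: related pairs need >= 2 samples per deme")
      par_demes <- rep_len(seq_len(n_demes), cfg$n_related_pairs)
      related_pairs <- data.frame(parent = character(0),
                                  offspring = character(0),
                                  kinship = numeric(0))
      used <- rep(0L, n_demes)
      for (k in seq_len(cfg$n_related_pairs)) {
        d <- par_demes[k]
        used[d] <- used[d] + 2L
        if (used[d] > cfg$samples_per_deme)
          stop("infeasible config: too many related pairs for deme size")
        i_par <- (d - 1L) * cfg$samples_per_deme + used[d] - 1L
        i_off <- i_par + 1L
        gam_par <- stats::rbinom(n_loci, 1L, dosage[i_par, ] / 2)
        gam_pool <- stats::rbinom(n_loci, 1L, dfreq[d, ])
        dosage[i_off, ] <- gam_par + gam_pool
        related_pairs <- rbind(related_pairs, data.frame(
          parent = samples[i_par], offspring = samples[i_off],
          kinship = 0.25))
      }
    }
    # planted inbred samples (F = 0.5): overwrite the last samples
    inbred <- NULL
    if (cfg$n_inbred > 0) {
      idx <- seq(n_samp - cfg$n_inbred + 1L, n_samp)
      for (i in idx) {
        d <- deme_of[i]
        ibd <- stats::runif(n_loci) < 0.5
        a1 <- stats::rbinom(n_loci, 1L, dfreq[d, ])
        a2 <- ifelse(ibd, a1, stats::rbinom(n_loci, 1L, dfreq[d, ]))
        dosage[i, ] <- a1 + a2
      }
      inbred <- data.frame(sample = samples[idx], F = 0.5)
    }
    if (cfg$missing_rate > 0)
      dosage[stats::runif(length(dosage)) < cfg$missing_rate] <- NA_integer_
    alleles <- c("A", "C", "G", "T")
    refalt <- t(vapply(seq_len(n_loci),
                       function(i) sample(alleles, 2), character(2)))
    loci <- data.frame(
      id = sprintf("snp%05d", seq_len(n_loci)),
      scaffold = sprintf("scaffold_%03d", ((seq_len(n_loci) - 1L) %/% 50L) + 1L),
      position = ((seq_len(n_loci) - 1L) %% 50L) * 997L + 101L,
      ref = refalt[, 1], alt = refalt[, 2], stringsAsFactors = FALSE)
    prov <- stats::setNames(envinfo$deme_ids[deme_of], samples)
    ds <- genotype_dataset(dosage, samples, loci, prov)
    ancestry <- matrix(0, n_samp, cfg$n_groups)
    ancestry[cbind(seq_len(n_samp), envinfo$group_of[deme_of])] <- 1
    rownames(ancestry) <- samples
    truth <- structure(list(
      locus_class = stats::setNames(locus_class, loci$id),
      effect = stats::setNames(effect, loci$id),
      env = stats::setNames(envinfo$env, envinfo$deme_ids),
      structure_axis = stats::setNames(envinfo$structure_axis,
                                       envinfo$deme_ids),
      group_of_deme = stats::setNames(envinfo$group_of, envinfo$deme_ids),
      deme_freq = dfreq,
      ancestry = ancestry,
      related_pairs = related_pairs,
      inbred = inbred), class = "SimTruth")
    list(dataset = ds, truth = truth)
  })
}

#' Simulate a provenance metadata table matching a simulation config
#'
#' Latitude follows the environmental gradient (colder = higher latitude),
#' longitude the structure axis, with small jitter; elevation is drawn around
#' 600 m. Purely cosmetic metadata for IO round trips.
#'
#' @param cfg a [sim_config()].
#' @return data.frame with columns id, lat, lon, elev, n_samples.
#' @export
simulate_provenances <- function(cfg) {
  envinfo <- .sim_env(cfg)
  with_seed(cfg$seed * 13L + 3L, {
    data.frame(id = envinfo$deme_ids,
               lat = round(49 - 2.2 * envinfo$env +
                             stats::rnorm(length(envinfo$env), sd = 0.2), 4),
               lon = round(-120 - 1.5 * envinfo$structure_axis +
                             stats::rnorm(length(envinfo$env), sd = 0.3), 4),
               elev = round(stats::runif(length(envinfo$env), 150, 1000)),
               n_samples = cfg$samples_per_deme,
               stringsAsFactors = FALSE)
  })
}

#' Simulate a provenance x variable climate table
#'
#' Variables are noisy linear combinations of four latent axes (temperature-,
#' precipitation-, radiation- and snow-like). Latent axis 1 equals the
#' genotype simulator's environmental gradient for the same config, so
#' climate PC1 is the axis adaptive loci respond to. Loading counts and the
#' noise level are fixed so the first two principal components dominate
#' (roughly 70-90% of variance at the default 247 variables).
#'
#' @param cfg a [sim_config()].
#' @param n_vars number of climate variables (>= 4).
#' @param noise_sd standard deviation of per-variable noise.
#' @return numeric matrix provenance x variable.
#' @export
simulate_climate <- function(cfg, n_vars = 247, noise_sd = 0.3) {
  stopifnot(n_vars >= 4)
  envinfo <- .sim_env(cfg)
  n <- length(envinfo$deme_ids)
  with_seed(cfg$seed * 17L + 5L, {
    ax <- cbind(envinfo$env,
                stats::rnorm(n), stats::rnorm(n), stats::rnorm(n))
    ax[, 2:4] <- apply(ax[, 2:4, drop = FALSE], 2,
                       function(v) as.numeric(scale(v)))
    # axis shares: temperature-like and precipitation-like dominate
    shares <- c(0.45, 0.36, 0.11, 0.08)
    counts <- pmax(1L, round(shares * n_vars))
    while (sum(counts) > n_vars) counts[which.max(counts)] <-
        counts[which.max(counts)] - 1L
    while (sum(counts) < n_vars) counts[which.max(counts)] <-
        counts[which.max(counts)] + 1L
    axis_of <- rep(1:4, counts)
    w <- stats::runif(n_vars, 0.8, 1.2) * sample(c(-1, 1), n_vars, TRUE)
    m <- ax[, axis_of, drop = FALSE] %*% diag(w) +
      matrix(stats::rnorm(n * n_vars, sd = noise_sd), n)
    # unit offsets/scales so variables look like raw climate values
    m <- sweep(m, 2, stats::runif(n_vars, 0.5, 3), `*`)
    m <- sweep(m, 2, stats::runif(n_vars, -5, 25), `+`)
    dimnames(m) <- list(envinfo$deme_ids,
                        sprintf("clim_%s_%03d",
                                c("T", "P", "R", "S")[axis_of],
                                seq_len(n_vars)))
    m
  })
}

#' Simulate ring-width series with a provenance-level climate-response cline
#'
#' Ring width is a negative-exponential age trend times
#' `exp(beta_prov * standardized July temperature + year effect + noise)`,
#' with `beta_prov = c0 + c1 * e_prov` where `e_prov` is the provenance's
#' source environment, giving a provenance-level cline in climate
#' sensitivity. The year effect (sd `year_effect_sd`, common to all trees of
#' a provenance in a year) represents non-July-temperature climate signal
#' that does not average away across trees, keeping response coefficients in
#' the 0.2-0.5 range typical of single-month response functions. Earlywood
#' carries the climate signal; latewood is a noisier fraction.
#'
#' @param cfg a [sim_config()].
#' @param years integer vector of consecutive years (>= 30).
#' @param c0,c1 intercept and slope of the sensitivity cline.
#' @param noise_sd lognormal per-tree ring-width noise standard deviation.
#' @param year_effect_sd sd of the provenance-year common effect.
#' @param trees_per_prov trees simulated per provenance.
#' @return list with `rings` (data.frame tree, provenance, year, earlywood,
#'   latewood, total) and `site_climate` (data.frame year, month, variable,
#'   value with variable "Tmean"), plus `beta_prov` (the true sensitivities).
#' @export
simulate_rings <- function(cfg, years = 1974:2011, c0 = 0.25, c1 = 0.15,
                           noise_sd = 0.25, year_effect_sd = 0.5,
                           trees_per_prov = NULL) {
  stopifnot(length(years) >= 30, all(diff(years) == 1))
  if (is.null(trees_per_prov)) trees_per_prov <- cfg$samples_per_deme
  envinfo <- .sim_env(cfg)
  n_prov <- length(envinfo$deme_ids)
  with_seed(cfg$seed * 23L + 7L, {
    ny <- length(years)
    monthly_norm <- c(-1.5, 0.2, 4.5, 9.5, 14.3, 17.6, 19.4, 18.9, 14.8,
                      9.3, 3.8, -0.3)
    site <- expand.grid(month = 1:12, year = years)
    site$variable <- "Tmean"
    site$value <- round(monthly_norm[site$month] +
                          stats::rnorm(nrow(site), sd = 1.3), 2)
    tjul <- site$value[site$month == 7]
    tjul_std <- as.numeric(scale(tjul))
    beta <- c0 + c1 * envinfo$env
    rings <- vector("list", n_prov * trees_per_prov)
    k <- 0L
    for (p in seq_len(n_prov)) {
      year_eff <- stats::rnorm(ny, sd = year_effect_sd)
      for (tr in seq_len(trees_per_prov)) {
        k <- k + 1L
        age <- seq_len(ny)
        trend <- 4.5 * exp(-age / stats::runif(1, 12, 25)) + 0.8
        sig <- exp(beta[p] * tjul_std + year_eff +
                     stats::rnorm(ny, sd = noise_sd))
        early <- pmax(trend * 0.7 * sig, 0)
        late <- pmax(trend * 0.3 *
                       exp(stats::rnorm(ny, sd = noise_sd)), 0)
        rings[[k]] <- data.frame(
          tree = sprintf("%s_t%02d", envinfo$deme_ids[p], tr),
          provenance = envinfo$deme_ids[p],
          year = years,
          earlywood = round(early, 3), latewood = round(late, 3),
          total = round(early + late, 3), stringsAsFactors = FALSE)
      }
    }
    list(rings = do.call(rbind, rings),
         site_climate = site[, c("year", "month", "variable", "value")],
         beta_prov = stats::setNames(beta, envinfo$deme_ids))
  })
}

#' Tiny deterministic fixture dataset (6 samples x 12 loci)
#'
#' Used in documentation and unit tests; two provenances of three samples.
#' @param seed RNG seed.
#' @return a `GenotypeDataset`.
#' @export
fixture_dataset <- function(seed = 42) {
  cfg <- sim_config(n_groups = 1, demes_per_group = 2, samples_per_deme = 3,
                    n_neutral_loci = 12, n_adaptive_loci = 0,
                    F_CT = 0, F_SC = 0.1, missing_rate = 0.05, seed = seed)
  simulate_genotypes(cfg)$dataset
}
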