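---
title: "provscan: models, numerical choices and what the tests establish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{provscan methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`provscan` is an environmental association analysis (EAA) pipeline for
common-garden provenance trials: strict SNP/sample QC, climate PCA,
dendroclimatic trait derivation, four genome scans with different null
models, a capped consensus rule, ancestry estimation and redundancy
analysis, plus a simulator that plants known signal for calibration and
recovery testing. This vignette records the models, the tunable parameters
and their defaults, the numerical decisions taken where the design was
genuinely open, and — importantly — what a green test suite does and does
not establish.

# The simulated world

All calibration and recovery tests run on data from `simulate_genotypes()`
and its companions. The generative model is a two-level hierarchical island
model: per locus an ancestral frequency $p \sim U(0.05, 0.95)$; group
frequencies Balding–Nichols around it,
$p_g \sim \mathrm{Beta}\!\big(p\,\tfrac{1-F_{CT}}{F_{CT}},\,(1-p)\tfrac{1-F_{CT}}{F_{CT}}\big)$;
deme frequencies Balding–Nichols around the group frequency with $F_{SC}$;
genotypes $\mathrm{Binomial}(2, p_d)$. For planted adaptive loci the deme
frequency is shifted on the logit scale by $b\,e_d$, where $e_d$ is a
standardized deme-level environmental gradient whose correlation with the
group-structure axis is the confounding knob `env_structure_corr`.

Stated-world defaults, with reasons:

* **16 demes in 2 groups, 11 samples per deme (176 trees), 2,020 loci** —
  the shape of a 16-provenance, ~178-tree exome study at roughly 100× fewer
  loci.
* **$F_{CT} = F_{SC} = 0.03$** (genome-wide $F_{ST} \approx 0.06$) — the
  order reported for range-wide Douglas-fir provenance collections. This
  value also interacts with the heterozygosity-deficit filter: each sample's
  $\hat F = 1 - H_{obs}/H_{exp}$ contains the Wahlund term
  ($\approx F_{ST}$) plus sampling noise (sd $\approx 0.035$ at 1,500 loci),
  so a world with $F_{ST} \gtrsim 0.1$ would trip the 0.1 filter for ordinary
  samples. At desk-scale locus counts the count-structure test ("exactly the
  planted inbreds are removed") therefore runs in a near-panmictic world with
  4,000 loci, where the filter's separation is clean.
* **$b = 1$, adaptive loci planted at intermediate ancestral frequency
  (0.2–0.8) and scattered across the genome.** Three structural facts force
  these choices. (i) Logit shifts are flat near fixation, so planting at
  $U(0.05, 0.95)$ makes half the "adaptive" loci carry no usable cline.
  (ii) A clinal locus has a pooled-sample Wahlund heterozygote deficit that
  grows with its among-deme variance; at $b \ge 1.5$ the strict
  Hardy–Weinberg filter ($\alpha = 10^{-6}$, $n \approx 176$) removes nearly
  every planted locus before any scan runs. At $b = 1$ the planted
  locus-specific $F_{ST}$ is ~0.2–0.35 — the same range the motivating
  study prints for its outliers — and a realistic minority (~20%) is still
  consumed by the HWE filter. (iii) Planted loci are mutually correlated
  through the shared gradient, so placing them on consecutive positions
  makes LD pruning delete all but one; they are spread out instead.
* **Missingness 2% MCAR**; related pairs by gamete sampling (expected
  kinship 0.25); inbred samples by selfing-like draws with $F = 0.5$.
* **Climate table**: 247 variables as noisy loadings on four latent axes
  (temperature-, precipitation-, radiation-, snow-like; shares
  0.45/0.36/0.11/0.08, noise sd 0.3), with axis 1 equal to the genotype
  simulator's gradient. At these settings PC1+PC2 carry 70–90% of the
  variance, emulating a climate table whose first two components dominate.
* **Ring widths**: negative-exponential age trend ×
  $\exp(\beta_p T^{July}_t + u_{pt} + \varepsilon_{it})$ with
  $\beta_p = 0.25 + 0.15\,e_p$. The provenance-year effect $u_{pt}$
  (sd 0.5) represents non-July-temperature climate signal that does **not**
  average away across trees; without it chronology–climate correlations
  come out ~0.9, far above the 0.2–0.5 range single-month response functions
  reach in practice.

What the simulator does *not* emulate: linkage blocks and recombination
(only incidental LD), selection acting through time, non-equilibrium
demography (bottlenecks, admixture zones), genotyping error that is
correlated with depth, and climate measurement error. A green recovery test
therefore establishes that the estimators recover planted equilibrium-model
signal at realistic effect sizes — not that they would behave identically on
a particular empirical dataset.

# QC cascade

Fixed order: site filters (MAF ≥ 0.05 on non-missing calls, minor allele
recomputed; call rate ≥ 0.95) → exact Hardy–Weinberg test → LD pruning →
sample filters (call rate, heterozygosity deficit, kinship). MAF and HWE are
computed once on the input sample set; there is no iterative re-filtering
after sample removal.

* **HWE**: two-sided Levene/Haldane exact test — sum of conditional
  probabilities of heterozygote counts no more likely than the observed one
  (no mid-p). Verified against a full-enumeration oracle for every
  configuration with $n \le 50$.
* **LD pruning**: greedy scaffold-ordered scan; a locus is dropped when its
  dosage Pearson correlation (composite LD) with any retained locus among the
  previous 50 loci of the same scaffold exceeds 0.2 in absolute value. The
  window size (50) and the within-scaffold restriction are package choices;
  the published analyses state only the 0.2 threshold.
* **Kinship**: method-of-moments P(IBD = 0, 1, 2) from identity-by-state
  counts and allele-frequency expectations, clamped to the simplex;
  $\varphi = \hat\pi/2$ so parent–offspring ≈ 0.25 and a self-comparison is
  0.5. The `<0.25` cutoff therefore excludes first-degree pairs; the
  alternative $\hat\pi$ reading of the cutoff is available via
  `kinship_convention = "pihat"`. Expectations use the locus-averaged class
  probabilities scaled by each pair's observed locus count (exact under MCAR
  missingness). With global allele frequencies the estimator absorbs
  structure (bias ≈ $0.75\,F_{ST}$ for within-deme pairs), which is why the
  pedigree-expectation test runs at near-panmixia.
* **Related-pair resolution**: remove the lower-call-rate member; ties
  remove the later sample id. The source analyses do not specify this.

# Phenotype and climate

* **Climate PCA** on the correlation matrix (variables z-scored — they mix
  units), SVD, first min(4, rank) components; scores standardized to sd 1
  ("standard deviations from the mean"); sign fixed so each component's
  largest-magnitude loading is positive.
* **Detrending**: the fixed-wavelength smoothing spline is implemented as
  the discrete second-difference penalized smoother
  $\hat g = (I + \lambda D_2^\top D_2)^{-1} y$ with
  $\lambda = 1/(16 \sin^4(\pi/\text{wavelength}))$, so the transfer function
  $1/(1 + 16\lambda\sin^4(\pi f))$ equals exactly 0.5 at the configured
  wavelength (15 years by default) — the 50% frequency-response convention.
  Index = raw/fitted; a non-positive fit falls back to horizontal-mean
  detrending with a warning.
* **Chronology**: per year, Tukey biweight robust location ($c = 9$ MAD,
  fixed-point iteration to $10^{-8}$), years with ≥ 3 trees only. Verified
  against an independent minimizer of the biweight ρ-objective.
* **Response functions**: Pearson correlation on the full year overlap,
  resampling years with replacement (n_boot = 1000 default; the count is a
  package choice). The reported interval is the 2.5/97.5 percentile interval;
  the **significance flag uses the studentized bootstrap (bootstrap-t) on the
  Fisher-z scale**. This is a deliberate deviation from the plain
  percentile rule: at ~33 years the percentile interval is anti-conservative
  for correlations (measured type-I ≈ 8.6%, vs ≈ 6.2% for the studentized
  interval over 3,000 null replicates), and calibration at the nominal 5% is
  a stated acceptance requirement.

# Genome scans

* **FST outlier scan.** Weir–Cockerham (1984) variance components per locus
  from genotype data; global estimate = ratio of summed components. The null
  is hierarchical Balding–Nichols at the observed deme sizes, with observed
  demes placed into groups by k-means on the first two genotype
  eigenvectors; $(F_{CT}, F_{SC})$ are scaled by a common factor found by
  bisection until the simulated global FST matches the observed one within
  0.002 (common random numbers make the bisection monotone). This replaces a
  coalescent island sampler with its equilibrium-equivalent frequency model —
  a deliberate substitution that shares code with the data simulator, making
  the self-consistency calibration test meaningful. P-values condition on
  heterozygosity: null pairs are split into 50 equal-count heterozygosity
  bins and each locus gets the pseudo-count upper-tail p
  $(1 + \#\{\text{null} \ge \text{obs}\})/(1 + \text{bin size})$ within its
  bin, which removes the mechanical FST–MAF dependence (checked as a
  property). Note the resolution limit: with $B$ null loci per bin the
  smallest achievable p is $1/(B+1)$, so Bonferroni-level calls require the
  full-size (200,000-locus) null, not the desk-scale one used in tests.
* **LFMM.** $Y = XB^\top + W + E$, $W = UV^\top$ of rank $K$; block
  minimization alternating a rank-$K$ truncated SVD of $Y - XB^\top$ with a
  ridge solve for $B$ ($\lambda = 10^{-5}$), deterministic (B starts at 0),
  objective non-increasing by construction. Per-locus tests regress each
  genotype column on $[1, X, U]$; $\lambda_{GC} = \mathrm{median}(z^2)/0.4549$
  recalibrates p per axis. **On $K$:** the scree elbow is read from the top —
  $K$ is the initial run of eigenvalue gaps exceeding 3× the mean gap of the
  spectrum's second half. The literal "largest gap above the tail mean" rule
  selects $K \approx 10$ on any structured dataset (deme-level axes are real
  but weak) and $K > 1$ on i.i.d. noise; reading the run from the top
  satisfies both sanity cases (two clusters → 1–2, noise → 0–1). Under
  deme-level Balding–Nichols noise with deme-constant predictors, residual
  overdispersion keeps $\lambda_{GC}$ near 1.5 for any $K$ below the full
  deme rank; the GIF division absorbs exactly this, and the calibrated
  p-values are uniform (checked). $\lambda_{GC} \in [0.8, 1.2]$ holds in the
  cluster-structured confounding world where the latent rank matches truth.
* **Bayes-factor scan.** $\Omega$ = mean outer product of centered, scaled
  neutral deme-frequency vectors, ridged until the condition number is
  below $10^8$. Per locus, frequencies are whitened by the Cholesky factor
  of $\Omega$ and the BF compares conjugate Gaussian models (unit residual
  variance, coefficient prior $N(0, \sigma_\beta^2)$, $\sigma_\beta = 1$
  default with an optional \{0.3, 1, 3\} grid averaged on the
  marginal-likelihood scale) with regressors (intercept, environment) vs
  intercept only — a deterministic plug-in replacement for an MCMC over
  $\Omega$ and ancestral frequencies, verified against 2-D quadrature to
  $10^{-4}$ relative error. Spearman ρ between whitened frequencies and the
  whitened environment backs the BF against single-deme outliers; the
  shortlist rule is BF > 30 and |ρ| > 0.4.
* **F-model scan.** Beta-binomial likelihood with
  $\mathrm{logit}(\theta_{ij}) = \beta_i + \alpha_j$; deme effects estimated
  once by ML with $\alpha \equiv 0$ (the likelihood separates by deme); per
  locus, 1-D ML for $\alpha_j$ (locus-specific model) and for $g_j$ in
  $\alpha_j = g_j E_i$ with $E_i = |$standardized environment$|$
  (environmental distance; the signed variant is a config switch). BIC
  approximates each model's marginal likelihood; priors
  $P(M_1 \cup M_2) = 0.1$, $P(M_2 \mid \text{non-neutral}) = 0.5$; PEP
  $= 1 - P(M_2\mid \text{data})$; q-values are running means of sorted PEPs.
  This replaces a reversible-jump MCMC; it keeps the output semantics
  (q-value shortlist at $-\log_{10} q > 1.3$) and the FDR calibration, at
  the cost of power — at the default scenario it detects few or no planted
  loci, consistent with the original tool being by far the most conservative
  of the four.

# Consensus and interrogation

A locus enters the consensus when ≥ 2 method shortlists contain it, except
that the FST-scan ∩ LFMM intersection (typically two orders of magnitude
larger than the others) contributes only its top 5 by LFMM $-\log_{10} p$
(ties broken by locus id — the source is silent). Loci capped out of that
pair but qualifying through another pair remain. Venn counts are reported
from the uncapped shortlists. The rule is verified against a brute-force
set-algebra oracle, and the published PC2 arithmetic (46 + 2 + 0, no
triples, cap 5 → 7) is an exact acceptance target. The corresponding PC1
arithmetic is **not** reproduced: the printed counts plus the cap do not
uniquely determine the published 11 (triple-membership dedupe ambiguity).

Eigenvector discrimination computes genotype PCA ($2p$-centered,
$\sqrt{2p(1-p)}$-scaled, missing entries mean-imputed) on the consensus loci
and on an equal-count random neutral draw, scoring a provided two-group
labeling by $\eta^2$ (between-group/total sum of squares) on EV1. In the
recovery test the labeling is the warm/cold split of source climate — the
contrast the consensus loci are selected for, mirroring the coastal/inland
contrast of the motivating study.

# Ancestry and RDA

Ancestry uses the least-squares (sparse-NMF) formulation: $X = QG$ with
simplex rows $Q$ and $G \in [0,1]$, alternating projected-gradient steps of
$1/L$ (Lipschitz) so the loss is monotone; masked binomial cross-entropy
(5% of entries, seeded) scores each $K$; the chosen $K$ is where the curve
plateaus — the smallest $K$ whose step to $K+1$ improves cross-entropy by
under 1%. At the weak default structure ($F_{CT} = 0.03$) the gain from
$K = 2$ is itself below 1%, so the plateau rule honestly returns $K = 1$
even though $K = 2$ assignment accuracy is ~100%; a stronger-structure world
yields $K = 2$. This replaces a Bayesian MCMC (STRUCTURE-style) sampler with
the formulation the minimum-cross-entropy selection criterion presumes.

RDA is multivariate OLS of the centered dosage matrix on z-transformed
predictors; $R^2$ = fitted/total sum of squares (equal to the sum of
per-locus fits — an exact oracle test), adjusted by Ezekiel's formula;
significance by joint row permutation of X,
$p = (1 + \#\{R^2_{perm} \ge R^2_{obs}\})/(n_{perm} + 1)$ (999 default; the
count is a package choice). The standard model set (combined: climate,
geography, ancestry; individual: PC1, PC2, latitude, longitude, ancestry)
is wrapped in `rda_models()`, with ancestry = the first Q column at K = 2,
z-transformed.

# Degenerate inputs and tie-breaks (summary)

Monomorphic loci: FST undefined (excluded from outlier testing), BF = 1 and
ρ = 0, allele-frequency correlations flagged. Constant climate variables:
dropped with a warning. Non-positive spline fits: horizontal-mean fallback.
Half-calls in VCF GT: missing. Phasing ignored throughout. Kinship-pair
removal: lower call rate, then later id. LFMM ranking ties: locus id.
Collinear RDA predictors: error naming the columns; collinear latent columns
in LFMM tests: dropped with a message.

# Known limitations

* The FST-scan's Bonferroni resolution is bounded by the null size (see
  above); desk-scale runs cannot produce multiple-testing-surviving
  FST outliers.
* The F-model substitute trades the MCMC's power for determinism; its
  q-value calibration is tested, its power is not claimed.
* Kinship estimates absorb population structure when referenced to global
  allele frequencies (as the original workflow did); interpret φ near the
  0.25 cutoff accordingly.
* The simulator's equilibrium island model cannot probe robustness to
  non-equilibrium demography; conclusions from green tests are about
  estimator correctness and calibration within the stated world.
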