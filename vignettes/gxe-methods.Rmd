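---
title: "Methods: polygenic risk, air-pollution trends, and additive interaction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: polygenic risk, air-pollution trends, and additive interaction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prsgxe)
```

This vignette is the package's account of its statistical machinery: the
models it fits, the assumptions behind them, the knobs that matter, what the
synthetic-data generator does and does not emulate, and the numerical and
design choices that were genuinely open.

## 1. The exposure metric: five-year trend slopes

Air quality in many regions is *improving*, so a long-term average
concentration conflates where someone lives with how their exposure has been
changing. The package therefore summarizes each participant's recent
exposure history by the OLS slope of annual mean concentration on calendar
year over the five years before recruitment:

$$C_{it} = \beta_{0i} + \beta_{1i} \, t + \varepsilon_{it},$$

with $\beta_{1i}$ in µg/m³ per year; positive slopes mean worsening air
quality. `fit_slope()` uses the closed form
$\hat\beta_1 = \sum(t-\bar t)(y - \bar y) / \sum(t-\bar t)^2$ with time
recoded so the earliest year is 0 — this makes the intercept the fitted
concentration at the window start and keeps the slope unit-identical to
µg/m³ per year even when a year is missing. Two distinct years are the
minimum; shorter series are excluded and logged (`slope_table()`'s
`skipped` attribute). "Baseline" in the descriptive table is the observed
concentration in the index (recruitment) year; the fitted value at the
window start is available via `baseline = "fitted_start"`. Quantiles
everywhere are the linear-interpolation (type-7) definition; SDs use the
$n-1$ denominator.

## 2. The polygenic risk score

The score is the classical weighted allele count
$PRS_i = \sum_j \beta_j G_{ij}$, with weights taken from *external* GWAS
summary statistics, never re-estimated in the analysis cohort.

**Quality control** (defaults in `qc_params()`): variant and sample call
missingness ≤ 0.02; MAF ≥ 0.05; exact conditional Hardy–Weinberg tests
computed separately in cases (exclude below p = 1e−10) and controls
(1e−6) — cases may legitimately deviate under a true association, hence the
asymmetric thresholds; heterozygosity within ±3 SD of the cohort mean;
relatedness via the standardized-genotype GRM off-diagonal (a
method-of-moments estimator of the kinship-style sharing coefficient:
≈1 for duplicates, ≈0.5 first-degree, ≈0 unrelated) with one member of each
pair above 0.2 removed (higher missingness first, ties to the larger
index); and outliers beyond 6 SD on the top two genotype principal
components. Because the GRM off-diagonal has null sampling SD
$\approx 1/\sqrt{m_\mathrm{eff}}$, a raw 0.2 cutoff mass-flags unrelated
pairs when only a few hundred (possibly LD-correlated) variants are
available; a pair is therefore flagged only when its estimate also exceeds
5 empirical null SDs. On realistically sized panels the guard is inactive;
duplicates always flag.

**Allele alignment.** Effects are put on the genotype's counted allele:
matching coding is kept, swapped coding flips the sign (equivalent by
$\beta(2-G) = 2\beta + (-\beta)G$), and strand-ambiguous A/T and C/G
variants are dropped rather than frequency-matched — the safe default when
no frequency reference is guaranteed.

**Clumping and thresholding.** `ld_clump()` implements p-value-ordered
greedy clumping (the behaviour of the standard GWAS tooling's `--clump`):
candidates at or below the threshold are visited in ascending p (ties by
position then id); each unassigned candidate becomes an index and removes
all remaining candidates within 250 kb with dosage $r^2 \ge 0.1$. The
description "LD pruning" inside a clumping-and-thresholding workflow is
read as clumping, not MAF-blind pruning — pruning would discard the most
significant variant of a correlated pair half the time, which no PRS
pipeline intends. $r^2$ is the squared Pearson correlation of dosages on
QC-passing individuals with pairwise-complete observations.

**Threshold selection.** The p-value grid spans
{5e−8, 1e−6, 1e−4, 1e−3, 0.01, 0.05, 0.1, 0.3, 0.5} (the endpoints are the
conventional genome-wide and permissive limits; the interior grid is the
usual decade ladder). For each threshold the score is standardized and
added to a logistic model with the Model-1 covariates; the threshold
maximizing ΔAUC over the covariate-only model wins, ties to the smaller
threshold (parsimony). Nagelkerke's pseudo-R² is reported alongside.
Missing dosages are imputed as twice the sample effect-allele frequency —
the standard scoring default, equivalent to mean-dosage imputation.
Scores are categorized into cohort quartiles with right-closed boundaries
(a score equal to a cut point goes to the lower category); the
categorization refuses fewer than 4 distinct values. A per-allele
normalized score (`prs_mean` = score / (2 × variant count)) is also
reported, since quartile ranges on a ~0.5 scale in published tables imply
such a normalization even where it is undocumented.

## 3. Association models

`fit_logistic()` is a binomial GLM (IRLS) with tight convergence control
(deviance tolerance 1e−10, ≤ 50 iterations) and covariance from the inverse
observed information; Wald (not profile) CIs are used throughout because
they reproduce the 2×2 cross-product arithmetic exactly — and indeed
expanding any 2×2 table into rows and fitting one binary predictor returns
the closed-form OR to numerical precision, a dual-route identity the test
suite enforces. Perfect separation (non-convergence, constant outcome, or a
perfect fit) is flagged rather than silently reported; quasi-separated
nuisance levels (|coef| > 15) produce a warning but leave the fit usable,
since a sparse covariate cell does not invalidate the exposure estimate.
Rank-deficient designs are an error, after empty factor levels are dropped.
Analyses are complete-case with the dropped count recorded. Slope terms
enter per 1 µg/m³ per year, unstandardized. Model 1 adjusts for age group,
sex, income, BMI class, education, exercise, smoking and drinking; Model 2
adds hypertension, depression and hyperlipidemia. Zero cells in 2×2 tables
are an error unless the Haldane–Anscombe 0.5 correction is explicitly
enabled (off by default; the reference tables this mirrors have no zero
cells).

## 4. Interaction

The core model (`gxe_fit()`, joint mode) is

$$\mathrm{logit}\,P(Y{=}1) = \alpha + \beta_1 E + \sum_q \beta_{2q} G_q +
\sum_q \beta_{3q} E\,G_q + \gamma' Z,$$

with $E$ the pollutant slope, $G_q$ indicators for PRS quartiles Q2–Q4
(Q1 reference) and $Z$ the adjustment covariates. Per-quartile exposure ORs
are $e^{\beta_1 + \beta_{3q}}$ with delta-method CIs. A stratified mode
fits the slope model separately within each quartile; with no covariates
the two coincide exactly (the joint interaction model is saturated across
strata), which is tested. Published per-quartile tables could come from
either; both are provided.

**Additive interaction.** The default RERI is the standard Rothman form
$e^{\beta_1+\beta_2+\beta_3} - e^{\beta_1} - e^{\beta_2} + 1
= OR_{11} - OR_{10} - OR_{01} + 1$. Some reports print a three-term
expression without $-e^{\beta_1}$ — most plausibly a typesetting loss, but
that cannot be verified from text alone — so it is kept as a first-class,
explicitly labelled variant (`variant = "as_printed"`) rather than guessed
away; all output carries the label. RERI is computed per 1-unit slope
increase by default; a binarized mode (slope > 0 = worsening ×
top-quartile PRS) exists because a binary contrast is where additive
interaction has its cleanest ground-truth definition.

**Bootstrap.** CIs are percentile intervals over resamples of individuals
(same n, with replacement, the full model refitted each time, 1,000
resamples by default); the point estimate comes from the original fit.
Resampling is unstratified — nothing in the analysis design implies
stratified resampling. Non-converged or rank-deficient refits (e.g. a
resample losing a factor level) are dropped and counted; results are
flagged unreliable above 5% failures, and all-failed is an error. BCa
intervals are not implemented; at these sample sizes the percentile
interval is the convention this literature reports.

## 5. What the generator emulates — and what it does not

`simulate_study()` produces all four inputs with known truth:

* **Genotypes**: per haplotype, a latent Gaussian AR(1) process within each
  block (correlation `within_block_rho`, default 0.8) thresholded at the
  variant's allele frequency (drawn uniformly on `maf_range`, default
  0.05–0.5); two haplotypes sum to the dosage, so Hardy–Weinberg holds by
  construction. Blocks are independent, span < 250 kb, and sit > 250 kb
  apart, so the clumping window sees blocks as the correlation units.
  Dosage correlation is the latent ρ attenuated by thresholding — tests
  check ordering and a floor, not equality. Missingness is MCAR (default
  1%).
* **Summary statistics**: reported effect = true log-OR + Normal noise with
  the standard GWAS SE approximation
  $se_j = 1/\sqrt{2 p_j (1-p_j) n_\mathrm{eff}}$; p-values are two-sided
  Wald. Default `gwas_n_effective` = 2e5, the order of magnitude of the
  large East-Asian consortium meta-analysis whose role it plays.
* **Exposures**: linear series anchored so `baseline_mean` is the
  index-year concentration (PM2.5 26.7, NO2 14.3, SO2 3.34, O3 45.4 µg/m³),
  slopes Normal with the published cohort-scale means/SDs (PM2.5
  −1.56 ± 0.88, NO2 −0.44 ± 0.59, SO2 −0.13 ± 0.13, O3 −0.01 ± 0.61),
  plus i.i.d. year noise (default SD 0.5 µg/m³, a plausible residual for
  modelled annual surfaces). Concentrations are floored at 0; with the
  defaults this touches only rare trace-gas draws.
* **Covariates and outcome**: categories drawn from the non-case marginals
  of the emulated cohort's descriptive table (reference levels: age 20–39,
  female, income < NT$20k, normal BMI, college, no exercise, never smoker,
  occasional drinker, no comorbidity); outcome Bernoulli with
  $\mathrm{logit} P = \alpha + \gamma_G z(PRS_\mathrm{true}) + \gamma_E
  \mathrm{slope} + \gamma_{GE}\, z \cdot \mathrm{slope} + \gamma'Z$.
  Defaults: $\gamma_G = 0.13$, $\gamma_E = 0.035$ (OR 1.036 per
  µg/m³/year), $\gamma_{GE} = 0.04$, moderate plausibly-signed covariate
  effects; the intercept, when not supplied, is calibrated so achieved
  prevalence sits near 5.08%.
* **Ground truth** includes an *implied true RERI* for the binary contrast
  (top-quartile true score) × (slope > 0): cell odds are the mean true
  event probabilities per cell, converted to ORs against the
  doubly-unexposed cell and combined as $OR_{11}-OR_{10}-OR_{01}+1$. This
  is the estimand the binarized fit targets, and it is defined on the
  *true* score — so simulation checks of interval coverage use true-score
  quartiles, isolating the bootstrap machinery from score-measurement
  error.

Not emulated, by design: satellite/land-use exposure modelling (the
pipeline starts from annual concentrations), genotype imputation,
population admixture beyond what PC-outlier screening needs, real LD
patterns (AR(1) blocks only), skewed slope distributions (the Gaussian
generator matches means and SDs, not the skewness visible in published
medians), and the joint calibration of *both* a marginal quartile-OR
gradient of ~1.39 and a RERI of ~0.14 — with one linear G×E term the two
cannot be matched simultaneously, and the defaults favour the
interaction-side quantities, which are the analysis's primary object.
Passing tests therefore demonstrate correctness of the machinery and
recovery under a known mechanism, not that real cohort data behave this
way.

## 6. Numerical choices and degenerate inputs

* HWE: exact conditional test, enumerated in log space; the p-value sums
  configurations with probability ≤ observed × (1 + 1e−12) to absorb
  floating-point ties. Monomorphic variants return p = 1 (only one
  configuration exists) and fail MAF instead.
* Clumping ties: ascending p, then position, then id — fully deterministic.
* Zero-variance exposure or all-equal scores: explicit errors naming the
  degeneracy.
* Threshold scan: thresholds whose model does not converge are skipped
  with a warning; an all-skipped scan is an error.
* Quartile cut points that collide (heavy ties) are tolerated by computing
  the category as 1 + #{cut points exceeded}, preserving right-closed
  semantics.
* Determinism: every generator stage draws from its own stream derived
  from the master seed, so changing, say, the outcome model leaves the
  genotypes bit-identical; `run_pipeline()` outputs are byte-identical
  across runs with the same config and seed.

## 7. Validation problem sizes

The test suite validates parameter recovery on a 50,000-participant
synthetic cohort (slope and per-quartile ORs within 3 SEs of the
generating values, with the per-quartile truth
$\gamma_E + \gamma_{GE}\,\bar z_q$ conditioned on the realized quartile
assignment); the size of the multiplicative Wald test over 1,000
outcome-redraw replicates at n = 2,000 under $\gamma_{GE}=0$ (accepted
band 3.5–6.5%); and 95% bootstrap-CI coverage of the implied true RERI
over 200 replicates at n = 5,000 with 200 resamples each (accepted band
88–99%), run with slopes centred at zero so both levels of the binary
contrast are well populated. The acceptance script reports a
20,000-participant pipeline run; the published full-cohort estimates
themselves derive from restricted data and are emulated structurally, not
reproduced.

## 8. Known limitations

* In-sample ΔAUC is optimistically biased at small n; the scan's purpose
  is threshold *selection*, not out-of-sample performance claims.
* The GRM-based relatedness estimator is a relationship coefficient, not a
  full IBD decomposition (k0/k1/k2); for the screening rule used here the
  distinction is immaterial, but pedigree reconstruction is out of scope.
* RERI for a continuous exposure depends on the unit of increase; per
  1 µg/m³/year is the reported convention and the package's default.
* The bootstrap treats the PRS threshold choice as fixed; re-running the
  scan inside each resample would propagate selection uncertainty at
  roughly 9× the cost and is not implemented.
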