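# prsgxe

Gene–environment interaction analysis of polygenic risk and air-pollution
trends for type 2 diabetes (T2D), built for epidemiologists who want the full
analysis chain — exposure metric, genetic score, association models, and
interaction statistics — as tested, reproducible R functions.

## The analysis

Cohort studies of air pollution and diabetes increasingly ask whether
genetic susceptibility modifies the effect of environmental exposure. This
package implements that analysis end to end:

1. **Exposure-trend slopes.** Rather than a long-term average, each
   participant's exposure is summarized by the ordinary-least-squares slope
   of annual pollutant concentration on time over the five years before
   recruitment: `Concentration_t = β₀ + β₁·t + ε`, with β₁ in µg/m³ per
   year. A positive slope means worsening air quality.
2. **Polygenic risk score (PRS).** `PRS_i = Σ_j β_j G_ij` with weights from
   external GWAS summary statistics, after variant/sample QC (missingness,
   MAF, exact Hardy–Weinberg tests stratified by case status,
   heterozygosity, relatedness, PC outliers) and clumping-and-thresholding:
   greedy p-value-ordered LD clumping at r² < 0.1 within 250 kb, with the
   p-value threshold chosen by the largest gain in AUC (ΔAUC) over a
   covariate-only model. Scores are categorized into cohort quartiles
   (Q1 low … Q4 high genetic risk).
3. **Association models.** Pearson chi-square tests and crude/adjusted
   logistic regressions reported as odds ratios with Wald 95% CIs
   (Model 1: demographics, socioeconomics, lifestyle; Model 2: Model 1 +
   hypertension, depression, hyperlipidemia).
4. **Interaction.** Multiplicative interaction via cross-product Wald
   tests, and additive interaction via the relative excess risk due to
   interaction,

   RERI = exp(β₁+β₂+β₃) − exp(β₁) − exp(β₂) + 1,

   where β₁, β₂, β₃ are the slope, PRS-category and product-term
   coefficients, with percentile bootstrap 95% CIs (1,000 resamples by
   default). A three-term variant omitting −exp(β₁) is selectable as
   `variant = "as_printed"` and every result is labelled with the formula
   that produced it.

Because individual-level biobank data are access-restricted, the package
ships a synthetic-data generator (`simulate_study()`) with known ground
truth — LD-block genotypes via a latent-Gaussian AR(1) haplotype model,
noisy external summary statistics, trended pollutant series, Table-1-style
covariates, and outcomes from a logistic model with a G×E product term — so
every stage is testable and parameter recovery can be verified.

## Worked example

```r
library(prsgxe)

cfg   <- sim_config(n_individuals = 5000, seed = 42)
study <- simulate_study(cfg)

# per-participant five-year trend slopes and their descriptives
slopes <- slope_table(study$exposures)
exposure_summary(slopes)[5:6, c("pollutant","metric","mean","sd","median","q1","q3")]
#>   pollutant   metric  mean    sd median    q1     q3
#> 5      pm25 baseline 26.78 7.591  26.78 21.64 31.949
#> 6      pm25    slope -1.54 0.898  -1.53 -2.16 -0.914

# QC, clumping-and-thresholding score, quartiles
cohort <- merge(study$cohort, slope_wide(slopes), by = "participant_id")
cohort <- cohort[order(cohort$participant_id), ]
qi   <- qc_individuals(study$genotypes)
qv   <- qc_variants(study$genotypes, study$cohort$t2d)
geno <- subset_genotypes(study$genotypes, qi$keep, qv$keep)
cohort <- cohort[cohort$participant_id %in% qi$keep, ]
scan <- threshold_scan(geno, study$sumstats, cohort,
                       covariates = adjustment_set("model1"))
cohort$prs_quartile <- scan$scores$quartile

# joint interaction model: slope x PRS quartile + Model-1 covariates
fit <- gxe_fit(cohort, "pm25_slope", covariates = adjustment_set("model1"))
fit
#> gene-environment interaction fit (joint mode, linear exposure)
#>   outcome t2d ~ pm25_slope x prs_quartile + 8 covariates
#> per-category exposure odds ratios:
#>  category     or ci_low ci_high      p
#>        Q1 1.0023 0.7555  1.3299 0.9870
#>        Q2 0.8737 0.6218  1.2275 0.4363
#>        Q3 0.7864 0.5563  1.1118 0.1739
#>        Q4 1.4790 1.0961  1.9956 0.0105
#> multiplicative interaction (cross-product Wald tests):
#>  category    coef     se       z      p
#>        Q2 -0.1374 0.2256 -0.6091 0.5425
#>        Q3 -0.2426 0.2280 -1.0640 0.2873
#>        Q4  0.3890 0.2105  1.8483 0.0646

reri(fit, n_boot = 200, seed = 7)
#> RERI (standard form), percentile bootstrap CI over 200 resamples (0 failed)
#>  category    reri  ci_low ci_high
#>        Q2 -0.0653 -0.3051  0.2551
#>        Q3 -0.0971 -0.3077  0.1274
#>        Q4  0.7617 -0.0001  2.8695
```

Read: in this simulated cohort of 5,000, the PM2.5 slope is associated with
T2D only in the highest genetic-risk quartile (per-1-µg/m³/year OR 1.48),
the Q4 cross-product term is borderline on the multiplicative scale
(p = 0.065), and the additive interaction for Q4 is positive with a
bootstrap CI just reaching 0 — the qualitative pattern the generator encodes
(γ_GE > 0 concentrated risk in the top quartile), estimated with the
sampling noise a cohort of this size implies.

`run_pipeline(list(simulate = list(n_individuals = 2000), seed = 1),
out_dir = "out")` runs everything in one call and writes the five
paper-shaped TSV tables (descriptives with 2×2 ORs; slope descriptives;
slope ORs per adjustment; PRS-quartile ORs; per-quartile slope ORs with
RERI), a JSON manifest (version, seed, config hash) and a log. Identical
config + seed gives byte-identical tables.

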