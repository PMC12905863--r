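# Synthetic cohort generator: LD-block genotypes, noisy external GWAS summary
# statistics, trended annual pollutant series, Table-1-style covariates, and a
# binary outcome from a logistic model with a gene-environment product term.
# Every output is a pure function of (config, seed); each stage draws from its
# own stream derived from the master seed.

# Covariate marginal distributions of the non-case population (percent), and
# the reference level of each factor (listed first).
.covariate_marginals <- list(
  age_group = c("20-39" = 22.91, "40-59" = 56.33, "60-79" = 20.74),
  sex       = c("female" = 64.44, "male" = 35.55),
  income    = c("<20k" = 54.07, "20-30k" = 18.69, "30-40k" = 26.58, ">40k" = 0.64),
  bmi_class = c("normal" = 60.69, "underweight" = 3.29, "overweight" = 29.14,
                "obesity1" = 5.79, "obesity2" = 0.88, "obesity3" = 0.17),
  education = c("college" = 48.51, "below_high_school" = 11.15,
                "high_school" = 28.69, "postgraduate" = 11.62),
  exercise  = c("no" = 60.49, "yes" = 39.50),
  smoking   = c("never" = 80.77, "former" = 9.95, "current" = 9.26),
  drinking  = c("occasional" = 2.46, "quit" = 91.63, "regular" = 5.90)
)
.comorbidity_marginals <- c(hypertension = 0.1045, hyperlipidemia = 0.0615,
                            depression = 0.0354)

# Expected multiplicative odds lift of the covariate effects under the
# generator's marginals (low-prevalence approximation), used to calibrate
# the default intercept.
.mean_odds_lift <- function(coefs) {
  lift <- 1
  for (v in names(coefs)) {
    cf <- coefs[[v]]
    if (v %in% names(.covariate_marginals)) {
      marg <- .covariate_marginals[[v]] / sum(.covariate_marginals[[v]])
      mult <- stats::setNames(rep(1, length(marg)), names(marg))
      mult[names(cf)] <- exp(cf)
      lift <- lift * sum(marg * mult)
    } else if (v %in% names(.comorbidity_marginals)) {
      p <- .comorbidity_marginals[[v]]
      lift <- lift * ((1 - p) + p * exp(cf))
    }
  }
  lift
}

# Default covariate log-odds effects in the outcome model: moderate,
# plausibly-signed values for a metabolic-disease outcome.
default_covariate_coefs <- function() {
  list(
    age_group = c("40-59" = log(2.0), "60-79" = log(3.0)),
    sex = c("male" = log(1.3)),
    bmi_class = c("overweight" = log(1.8), "obesity1" = log(2.5),
                  "obesity2" = log(3.0), "obesity3" = log(3.0)),
    hypertension = log(2.2),
    hyperlipidemia = log(2.2),
    depression = log(1.3)
  )
}

#' Configuration for the synthetic study generator
#'
#' Collects every tunable of the generator: genotype architecture (LD blocks
#' with latent-Gaussian AR(1) haplotype correlation), external summary-statistic
#' noise, annual pollutant trend parameters, and the logistic outcome model
#' with main effects and a gene-environment product term.
#'
#' @param n_individuals number of participants.
#' @param n_blocks number of independent LD blocks.
#' @param snps_per_block variants per block.
#' @param within_block_rho AR(1) latent haplotype correlation within a block,
#'   in [0, 1).
#' @param maf_range length-2 range (low, high) for effect-allele frequencies,
#'   with 0 <= low < high <= 0.5.
#' @param n_causal number of causal variants (<= total variants).
#' @param causal_beta_sd SD of causal log-odds-ratio effects.
#' @param gwas_n_effective effective sample size of the emulated external GWAS;
#'   summary-statistic noise shrinks as it grows.
#' @param years calendar years of the exposure window (length >= 2; default the
#'   five years 2008-2012).
#' @param pollutants pollutant labels.
#' @param slope_mean,slope_sd per-pollutant mean and SD of true annual trend
#'   slopes (micrograms/m3 per year); scalars are recycled. Defaults are the
#'   cohort-scale values the generator emulates (PM2.5 -1.56 +/- 0.88, NO2
#'   -0.44 +/- 0.59, SO2 -0.13 +/- 0.13, O3 -0.01 +/- 0.61).
#' @param baseline_mean,baseline_sd per-pollutant mean and SD of the
#'   concentration in the index (final) year of the window (micrograms/m3).
#' @param noise_sd SD of the i.i.d. Gaussian year-to-year measurement noise.
#' @param outcome_coefs named list: \code{intercept}, \code{prs_effect} (per SD
#'   of the true polygenic score), \code{slope_effect} (per microgram/m3/year),
#'   \code{interaction}, and \code{covariates} (nested named list of
#'   level-specific log-odds effects; \code{NULL} uses a moderate default set,
#'   an empty list turns covariate effects off). When \code{intercept} is not
#'   supplied it is calibrated so the achieved prevalence under the configured
#'   effects sits near 5.08 percent, the cohort prevalence the generator
#'   emulates.
#' @param interaction_pollutant pollutant whose true slope enters the outcome
#'   model.
#' @param missing_rate genotype missingness, missing completely at random.
#' @param seed master RNG seed; fully determines all generator output.
#' @return an object of class \code{sim_config} (a validated list).
#' @export
sim_config <- function(n_individuals = 2000, n_blocks = 20, snps_per_block = 10,
                       within_block_rho = 0.8, maf_range = c(0.05, 0.5),
                       n_causal = 40, causal_beta_sd = 0.15,
                       gwas_n_effective = 2e5,
                       years = 2008:2012,
                       pollutants = c("pm25", "no2", "so2", "o3"),
                       slope_mean = c(pm25 = -1.56, no2 = -0.44,
                                      so2 = -0.13, o3 = -0.01),
                       slope_sd = c(pm25 = 0.88, no2 = 0.59,
                                    so2 = 0.13, o3 = 0.61),
                       baseline_mean = c(pm25 = 26.7, no2 = 14.3,
                                         so2 = 3.34, o3 = 45.4),
                       baseline_sd = c(pm25 = 7.64, no2 = 6.39,
                                       so2 = 0.95, o3 = 4.33),
                       noise_sd = 0.5,
                       outcome_coefs = list(),
                       interaction_pollutant = "pm25",
                       missing_rate = 0.01,
                       seed = 1) {
  if (!is_count(n_individuals) || !is_count(n_blocks) || !is_count(snps_per_block))
    stopf("n_individuals, n_blocks and snps_per_block must be positive integers")
  if (!is.numeric(within_block_rho) || within_block_rho < 0 || within_block_rho >= 1)
    stopf("within_block_rho must lie in [0, 1)")
  if (length(maf_range) != 2 || maf_range[1] < 0 || maf_range[1] >= maf_range[2] ||
      maf_range[2] > 0.5)
    stopf("maf_range must satisfy 0 <= low < high <= 0.5")
  if (!is_count(n_causal) || n_causal > n_blocks * snps_per_block)
    stopf("n_causal must be a count <= n_blocks * snps_per_block")
  if (length(years) < 2) stopf("at least 2 exposure years are required")
  if (!is_prob(missing_rate)) stopf("missing_rate must be a probability")

  expand <- function(x, what) {
    if (length(x) == 1L) x <- stats::setNames(rep(x, length(pollutants)), pollutants)
    if (is.null(names(x))) names(x) <- pollutants
    if (!all(pollutants %in% names(x)))
      stopf("%s must name every pollutant", what)
    x[pollutants]
  }
  oc <- outcome_coefs
  coefs <- list(
    intercept = oc$intercept,  # resolved below
    prs_effect = oc$prs_effect %||% 0.13,
    slope_effect = oc$slope_effect %||% 0.035,
    interaction = oc$interaction %||% 0.04,
    covariates = if (is.null(oc$covariates) && !("covariates" %in% names(oc)))
      default_covariate_coefs() else oc$covariates
  )
  if (is.null(coefs$intercept)) {
    # calibrate the default intercept so the achieved prevalence under the
    # default effect mix sits near the 5.08% the generator emulates
    mu_s <- unname(slope_mean[if (length(slope_mean) > 1)
      match.arg(interaction_pollutant, pollutants) else 1])
    sd_s <- unname(slope_sd[if (length(slope_sd) > 1)
      match.arg(interaction_pollutant, pollutants) else 1])
    lift <- .mean_odds_lift(coefs$covariates) *
      exp(coefs$slope_effect * mu_s + 0.5 * (coefs$slope_effect * sd_s)^2) *
      exp(0.5 * coefs$prs_effect^2)
    coefs$intercept <- stats::qlogis(0.0508) - log(lift)
  }
  cfg <- list(
    n_individuals = as.integer(n_individuals),
    n_blocks = as.integer(n_blocks),
    snps_per_block = as.integer(snps_per_block),
    within_block_rho = within_block_rho,
    maf_range = maf_range,
    n_causal = as.integer(n_causal),
    causal_beta_sd = causal_beta_sd,
    gwas_n_effective = gwas_n_effective,
    years = sort(as.integer(years)),
    pollutants = pollutants,
    slope_mean = expand(slope_mean, "slope_mean"),
    slope_sd = expand(slope_sd, "slope_sd"),
    baseline_mean = expand(baseline_mean, "baseline_mean"),
    baseline_sd = expand(baseline_sd, "baseline_sd"),
    noise_sd = noise_sd,
    outcome_coefs = coefs,
    interaction_pollutant = match.arg(interaction_pollutant, pollutants),
    missing_rate = missing_rate,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic study configuration\n")
  cat(sprintf("  %d individuals, %d blocks x %d variants (rho = %.2f, missing %.1f%%)\n",
              x$n_individuals, x$n_blocks, x$snps_per_block,
              x$within_block_rho, 100 * x$missing_rate))
  cat(sprintf("  %d causal variants (beta SD %.3f), GWAS n_eff = %g\n",
              x$n_causal, x$causal_beta_sd, x$gwas_n_effective))
  cat(sprintf("  exposure years %s; pollutants: %s\n",
              paste(range(x$years), collapse = "-"),
              paste(x$pollutants, collapse = ", ")))
  cat(sprintf("  outcome: intercept %.3f, prs %.3f, slope %.3f, gxe %.3f (%s)\n",
              x$outcome_coefs$intercept, x$outcome_coefs$prs_effect,
              x$outcome_coefs$slope_effect, x$outcome_coefs$interaction,
              x$interaction_pollutant))
  invisible(x)
}

#' Simulate LD-block genotypes
#'
#' Hard-call genotypes in {0, 1, 2} with block-structured linkage
#' disequilibrium: each haplotype is a latent Gaussian AR(1) process within a
#' block, thresholded so allele j carries frequency maf_j; blocks are
#' independent. Variant positions place each block within a span under 250 kb
#' and consecutive blocks more than 250 kb apart, so distance-windowed clumping
#' sees blocks as the correlation units. Missing calls are introduced
#' completely at random at \code{missing_rate}.
#'
#' @param config a \code{\link{sim_config}}.
#' @return an object of class \code{genotype_matrix}: a list with
#'   \code{genotypes} (individuals x variants numeric matrix, NA = missing) and
#'   \code{variants} (data frame: variant_id, chrom, pos, effect_allele,
#'   other_allele, maf, block).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, 1L))
  n <- config$n_individuals
  s <- config$snps_per_block
  nb <- config$n_blocks
  m <- nb * s
  rho <- config$within_block_rho

  maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  G <- matrix(0, n, m)
  for (b in seq_len(nb)) {
    cols <- ((b - 1L) * s + 1L):(b * s)
    thr <- matrix(stats::qnorm(maf[cols]), n, s, byrow = TRUE)
    for (hap in 1:2) {
      Z <- matrix(stats::rnorm(n * s), n, s)
      if (s > 1L && rho > 0) {
        sq <- sqrt(1 - rho^2)
        for (j in 2:s) Z[, j] <- rho * Z[, j - 1L] + sq * Z[, j]
      }
      G[, cols] <- G[, cols] + (Z < thr)
    }
  }
  if (config$missing_rate > 0) {
    G[stats::runif(n * m) < config$missing_rate] <- NA_real_
  }

  step <- if (s > 1L) 240000L %/% (s - 1L) else 0L
  pos <- as.vector(vapply(seq_len(nb), function(b) {
    (b - 1L) * 1000000L + 1L + (0:(s - 1L)) * step
  }, integer(s)))
  variants <- data.frame(
    variant_id = sprintf("snp%05d", seq_len(m)),
    chrom = "1",
    pos = pos,
    effect_allele = "A",
    other_allele = "G",
    maf = maf,
    block = rep(seq_len(nb), each = s),
    stringsAsFactors = FALSE
  )
  dimnames(G) <- list(sprintf("id%06d", seq_len(n)), variants$variant_id)
  structure(list(genotypes = G, variants = variants), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d variants (%d blocks), %.2f%% missing\n",
              nrow(x$genotypes), ncol(x$genotypes), max(x$variants$block),
              100 * mean(is.na(x$genotypes))))
  invisible(x)
}

# Draw the causal architecture: which variants are causal and their log-OR.
simulate_causal_betas <- function(config, genotypes) {
  set.seed(stage_seed(config$seed, 2L))
  m <- ncol(genotypes$genotypes)
  beta <- stats::setNames(numeric(m), genotypes$variants$variant_id)
  idx <- sample.int(m, config$n_causal)
  beta[idx] <- stats::rnorm(config$n_causal, 0, config$causal_beta_sd)
  beta
}

#' Simulate external GWAS summary statistics
#'
#' Emulates a noisy external consortium GWAS of the same trait: the reported
#' effect is the true log-OR plus Gaussian noise with standard error
#' \eqn{1 / \sqrt{2 p_j (1 - p_j) n_{eff}}}{1/sqrt(2 p (1-p) n_eff)} (the usual
#' GWAS approximation), and the p-value is the two-sided Wald p of the reported
#' effect against that standard error.
#'
#' @param genotypes a \code{genotype_matrix}.
#' @param truth ground-truth list holding \code{causal_betas} named by
#'   variant id and aligned to \code{genotypes}.
#' @param config a \code{\link{sim_config}}.
#' @return data frame: chrom, pos, variant_id, effect_allele, other_allele,
#'   beta, se, pvalue.
#' @export
simulate_sumstats <- function(genotypes, truth, config) {
  stopifnot(inherits(config, "sim_config"))
  v <- genotypes$variants
  if (!identical(names(truth$causal_betas), v$variant_id))
    stopf("causal betas are not aligned to the genotype variants")
  set.seed(stage_seed(config$seed, 3L))
  se <- 1 / sqrt(2 * v$maf * (1 - v$maf) * config$gwas_n_effective)
  beta_hat <- truth$causal_betas + stats::rnorm(nrow(v)) * se
  data.frame(
    chrom = v$chrom, pos = v$pos, variant_id = v$variant_id,
    effect_allele = v$effect_allele, other_allele = v$other_allele,
    beta = as.numeric(beta_hat), se = se,
    pvalue = 2 * stats::pnorm(-abs(beta_hat) / se),
    stringsAsFactors = FALSE
  )
}

#' Simulate per-participant annual pollutant series
#'
#' Each participant's series is linear in time with Gaussian noise:
#' concentration(t) = baseline_i + slope_i * (t - t_index), where t_index is
#' the final (recruitment) year of the window, so \code{baseline_mean} is the
#' typical index-year concentration. Slopes are drawn from the configured
#' per-pollutant Normal distribution. Concentrations are floored at zero
#' (relevant only for trace gases under heavy noise).
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with \code{panel} (long data frame: participant_id, pollutant,
#'   year, concentration), \code{true_slopes} and \code{true_baselines}
#'   (wide data frames keyed by participant_id).
#' @export
simulate_exposures <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (length(config$years) < 2) stopf("at least 2 exposure years are required")
  set.seed(stage_seed(config$seed, 4L))
  n <- config$n_individuals
  yrs <- config$years
  tt <- seq_along(yrs) - length(yrs)  # 0 at the index (final) year
  ids <- sprintf("id%06d", seq_len(n))

  slopes <- baselines <- data.frame(participant_id = ids, stringsAsFactors = FALSE)
  parts <- vector("list", length(config$pollutants))
  for (k in seq_along(config$pollutants)) {
    pol <- config$pollutants[k]
    b0 <- stats::rnorm(n, config$baseline_mean[pol], config$baseline_sd[pol])
    b1 <- stats::rnorm(n, config$slope_mean[pol], config$slope_sd[pol])
    conc <- outer(b0, rep(1, length(tt))) + outer(b1, tt)
    if (config$noise_sd > 0)
      conc <- conc + matrix(stats::rnorm(n * length(tt), 0, config$noise_sd),
                            n, length(tt))
    conc <- pmax(conc, 0)
    parts[[k]] <- data.frame(
      participant_id = rep(ids, times = length(tt)),
      pollutant = pol,
      year = rep(yrs, each = n),
      concentration = as.vector(conc),
      stringsAsFactors = FALSE
    )
    slopes[[paste0(pol, "_slope")]] <- b1
    baselines[[paste0(pol, "_baseline")]] <- b0
  }
  panel <- do.call(rbind, parts)
  panel <- panel[order(panel$participant_id, panel$pollutant, panel$year), ]
  rownames(panel) <- NULL
  list(panel = panel, true_slopes = slopes, true_baselines = baselines)
}

# Sample a factor from a named percent vector; first name is the reference.
.sample_factor <- function(n, marg) {
  lev <- names(marg)
  factor(sample(lev, n, replace = TRUE, prob = marg / sum(marg)), levels = lev)
}

# Linear-predictor contribution of the covariates given nested named coefs.
.covariate_lp <- function(cov_df, coefs) {
  lp <- numeric(nrow(cov_df))
  for (v in names(coefs)) {
    cf <- coefs[[v]]
    x <- cov_df[[v]]
    if (is.null(x)) stopf("covariate '%s' has coefficients but no column", v)
    if (is.factor(x)) {
      for (lev in names(cf)) lp <- lp + cf[[lev]] * (x == lev)
    } else {
      lp <- lp + cf * as.numeric(x)
    }
  }
  lp
}

#' Simulate the cohort table (covariates and outcome)
#'
#' Covariates are drawn from fixed categorical marginals mirroring a general
#' adult cohort (reference levels: age 20-39, female, income < NT$20k, normal
#' BMI, college education, no exercise, never smoker, occasional drinker, no
#' comorbidity). Disease status is Bernoulli with
#' \eqn{logit P = \alpha + \gamma_G z(PRS) + \gamma_E slope +
#' \gamma_{GE} z(PRS) \cdot slope + covariate\ terms}, where z(PRS) is the
#' standardized true polygenic score built from the causal effects.
#'
#' @param genotypes a \code{genotype_matrix}.
#' @param truth ground-truth list with \code{causal_betas}.
#' @param exposures result of \code{\link{simulate_exposures}}.
#' @param config a \code{\link{sim_config}}.
#' @return cohort data frame (participant_id, t2d, covariates) with attributes
#'   \code{prevalence} (achieved), \code{true_prob}, and \code{prs_z}.
#' @export
simulate_cohort <- function(genotypes, truth, exposures, config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_individuals
  ids <- rownames(genotypes$genotypes)
  if (!identical(exposures$true_slopes$participant_id, ids))
    stopf("exposure and genotype participant sets are not aligned")
  set.seed(stage_seed(config$seed, 5L))

  cov_df <- data.frame(participant_id = ids, stringsAsFactors = FALSE)
  for (v in names(.covariate_marginals))
    cov_df[[v]] <- .sample_factor(n, .covariate_marginals[[v]])
  for (v in names(.comorbidity_marginals))
    cov_df[[v]] <- stats::rbinom(n, 1L, .comorbidity_marginals[[v]])

  prs_raw <- prs_score(genotypes, truth$causal_betas)$prs_raw
  prs_z <- if (stats::sd(prs_raw) > 0) as.numeric(scale(prs_raw)) else prs_raw
  slope <- exposures$true_slopes[[paste0(config$interaction_pollutant, "_slope")]]

  oc <- config$outcome_coefs
  lp <- oc$intercept + oc$prs_effect * prs_z + oc$slope_effect * slope +
    oc$interaction * prs_z * slope
  if (length(oc$covariates)) lp <- lp + .covariate_lp(cov_df, oc$covariates)
  p <- stats::plogis(lp)
  y <- stats::rbinom(n, 1L, p)

  cohort <- cbind(data.frame(participant_id = ids, t2d = y,
                             stringsAsFactors = FALSE),
                  cov_df[setdiff(names(cov_df), "participant_id")])
  attr(cohort, "prevalence") <- mean(y)
  attr(cohort, "true_prob") <- p
  attr(cohort, "prs_z") <- prs_z
  cohort
}

#' Implied true RERI of a binary high-genetic-risk by adverse-trend contrast
#'
#' Given true event probabilities under the generating model, computes the
#' relative excess risk due to interaction for the contrast (top-quartile
#' polygenic score) x (positive trend slope): cell odds are formed from the
#' mean true probability in each of the four cells, converted to odds ratios
#' against the doubly-unexposed cell, and combined as OR11 - OR10 - OR01 + 1.
#'
#' @param prs values defining genetic risk (true score); the top quartile is
#'   the high-risk group.
#' @param slope exposure trend slope; positive means worsening air quality.
#' @param true_prob true event probability per participant.
#' @return the implied RERI (NA with a warning if any cell is empty).
#' @export
implied_reri <- function(prs, slope, true_prob) {
  g <- prs > stats::quantile(prs, 0.75, names = FALSE)
  e <- slope > 0
  cells <- table(g, e)
  if (length(cells) < 4 || any(cells == 0)) {
    warnf("empty cell in the high-risk x adverse-trend contrast; implied RERI is NA")
    return(NA_real_)
  }
  odds <- function(gg, ee) {
    pm <- mean(true_prob[g == gg & e == ee])
    pm / (1 - pm)
  }
  o00 <- odds(FALSE, FALSE)
  odds(TRUE, TRUE) / o00 - odds(TRUE, FALSE) / o00 - odds(FALSE, TRUE) / o00 + 1
}

#' Simulate a complete synthetic study with ground truth
#'
#' Runs all generator stages (genotypes, causal effects, summary statistics,
#' exposures, cohort) under one master seed and assembles the ground truth
#' needed to score downstream estimates.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with \code{genotypes}, \code{sumstats}, \code{exposures}
#'   (long panel), \code{cohort}, and \code{truth} (causal_betas,
#'   outcome_coefs, true_slopes, prs_z, true_prob, prevalence,
#'   implied_true_reri).
#' @export
simulate_study <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  genotypes <- simulate_genotypes(config)
  truth <- list(causal_betas = simulate_causal_betas(config, genotypes))
  sumstats <- simulate_sumstats(genotypes, truth, config)
  exposures <- simulate_exposures(config)
  cohort <- simulate_cohort(genotypes, truth, exposures, config)

  slope <- exposures$true_slopes[[paste0(config$interaction_pollutant, "_slope")]]
  truth$outcome_coefs <- config$outcome_coefs
  truth$true_slopes <- exposures$true_slopes
  truth$true_baselines <- exposures$true_baselines
  truth$prs_z <- attr(cohort, "prs_z")
  truth$true_prob <- attr(cohort, "true_prob")
  truth$prevalence <- attr(cohort, "prevalence")
  truth$implied_true_reri <- suppressWarnings(
    implied_reri(truth$prs_z, slope, truth$true_prob))

  list(genotypes = genotypes, sumstats = sumstats,
       exposures = exposures$panel, cohort = cohort, truth = truth)
}
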