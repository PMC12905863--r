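test_that("generators are pure functions of the config seed", {
  cfg <- sim_config(n_individuals = 120, n_blocks = 4, snps_per_block = 5,
                    n_causal = 6, seed = 42)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a$genotypes$genotypes, b$genotypes$genotypes)
  expect_identical(a$sumstats, b$sumstats)
  expect_identical(a$exposures, b$exposures)
  expect_identical(a$cohort, b$cohort)
  c3 <- simulate_study(sim_config(n_individuals = 120, n_blocks = 4,
                                  snps_per_block = 5, n_causal = 6, seed = 43))
  expect_false(identical(a$genotypes$genotypes, c3$genotypes$genotypes))
})

test_that("genotype matrices have block structure and valid calls", {
  cfg <- sim_config(n_individuals = 300, n_blocks = 3, snps_per_block = 8,
                    n_causal = 6, within_block_rho = 0.8,
                    missing_rate = 0.05, seed = 2)
  g <- simulate_genotypes(cfg)
  G <- g$genotypes
  expect_equal(dim(G), c(300, 24))
  expect_true(all(G[!is.na(G)] %in% 0:2))
  expect_gt(mean(is.na(G)), 0.03)
  expect_lt(mean(is.na(G)), 0.07)
  # blocks span < 250 kb; consecutive blocks > 250 kb apart
  v <- g$variants
  for (b in unique(v$block)) {
    pp <- v$pos[v$block == b]
    expect_lt(max(pp) - min(pp), 250000)
  }
  gaps <- vapply(seq_len(max(v$block) - 1), function(b)
    min(v$pos[v$block == b + 1]) - max(v$pos[v$block == b]), numeric(1))
  expect_true(all(gaps > 250000))
  # adjacent within-block dosage correlation rises with rho
  cfg0 <- sim_config(n_individuals = 2000, n_blocks = 3, snps_per_block = 8,
                     n_causal = 6, within_block_rho = 0, missing_rate = 0,
                     seed = 2)
  cfg8 <- sim_config(n_individuals = 2000, n_blocks = 3, snps_per_block = 8,
                     n_causal = 6, within_block_rho = 0.8, missing_rate = 0,
                     seed = 2)
  adj_cor <- function(g) {
    v <- g$variants
    mean(vapply(unique(v$block), function(b) {
      j <- which(v$block == b)
      mean(diag(stats::cor(g$genotypes[, j[-length(j)]],
                           g$genotypes[, j[-1]])))
    }, numeric(1)))
  }
  # dosage correlation is the latent rho attenuated by thresholding, so the
  # check is ordering plus a conservative floor, not equality
  expect_lt(abs(adj_cor(simulate_genotypes(cfg0))), 0.1)
  expect_gt(adj_cor(simulate_genotypes(cfg8)), 0.35)
})

test_that("sample allele frequencies match the drawn frequencies without LD", {
  cfg <- sim_config(n_individuals = 4000, n_blocks = 4, snps_per_block = 10,
                    within_block_rho = 0, missing_rate = 0, seed = 9)
  g <- simulate_genotypes(cfg)
  freq <- colMeans(g$genotypes) / 2
  se <- sqrt(g$variants$maf * (1 - g$variants$maf) / (2 * 4000))
  expect_true(all(abs(freq - g$variants$maf) < 3.5 * se))
})

test_that("degenerate dimensions and invalid configs are handled", {
  g <- simulate_genotypes(sim_config(n_individuals = 1, n_blocks = 1,
                                     snps_per_block = 1, n_causal = 1,
                                     missing_rate = 0, seed = 1))
  expect_equal(dim(g$genotypes), c(1, 1))
  expect_true(g$genotypes[1, 1] %in% 0:2)
  expect_error(sim_config(n_individuals = 0), "positive integers")
  expect_error(sim_config(maf_range = c(0.3, 0.2)), "maf_range")
  expect_error(sim_config(n_causal = 1e6), "n_causal")
  expect_error(sim_config(years = 2010), "2 exposure years")
  expect_error(sim_config(within_block_rho = 1), "within_block_rho")
})

test_that("summary statistics converge to truth as the GWAS grows", {
  cfg <- sim_config(n_individuals = 60, n_blocks = 4, snps_per_block = 5,
                    n_causal = 8, gwas_n_effective = 1e8, seed = 5)
  st <- simulate_study(cfg)
  expect_true(all(abs(st$sumstats$beta - st$truth$causal_betas) < 0.005))
  # causal variants dominate the significance ranking
  causal <- names(st$truth$causal_betas)[st$truth$causal_betas != 0]
  expect_lt(median(st$sumstats$pvalue[st$sumstats$variant_id %in% causal]),
            median(st$sumstats$pvalue[!st$sumstats$variant_id %in% causal]))
})

test_that("null-variant p-values are uniform", {
  # 1,000 null variants, each an independent draw of the null sampling model
  cfg <- sim_config(n_individuals = 40, n_blocks = 200, snps_per_block = 5,
                    n_causal = 1, causal_beta_sd = 0, within_block_rho = 0,
                    seed = 31)
  st <- simulate_study(cfg)
  ks <- suppressWarnings(stats::ks.test(st$sumstats$pvalue, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("exposure series invert to their generating slopes", {
  cfg <- sim_config(n_individuals = 50, noise_sd = 0,
                    slope_mean = -1.56, slope_sd = 0, seed = 3)
  ex <- simulate_exposures(cfg)
  sl <- slope_table(ex$panel)
  expect_equal(sl$beta1[sl$pollutant == "pm25"], rep(-1.56, 50))
  # flat configuration gives constant series
  cfg0 <- sim_config(n_individuals = 5, noise_sd = 0, slope_mean = 0,
                     slope_sd = 0, seed = 3)
  p0 <- simulate_exposures(cfg0)$panel
  spread <- tapply(p0$concentration,
                   paste(p0$participant_id, p0$pollutant),
                   function(x) diff(range(x)))
  expect_true(all(spread == 0))
})

test_that("prevalence tracks the intercept and is achieved under the null", {
  null_coefs <- list(intercept = stats::qlogis(0.0508), prs_effect = 0,
                     slope_effect = 0, interaction = 0, covariates = list())
  cfg <- sim_config(n_individuals = 20000, outcome_coefs = null_coefs,
                    seed = 17)
  st <- simulate_study(cfg)
  se <- sqrt(0.0508 * (1 - 0.0508) / 20000)
  expect_lt(abs(st$truth$prevalence - 0.0508), 3 * se)
  # monotone in the intercept, all else fixed
  lower <- null_coefs; lower$intercept <- stats::qlogis(0.02)
  higher <- null_coefs; higher$intercept <- stats::qlogis(0.15)
  p_lo <- simulate_study(sim_config(n_individuals = 20000,
                                    outcome_coefs = lower, seed = 17))$truth$prevalence
  p_hi <- simulate_study(sim_config(n_individuals = 20000,
                                    outcome_coefs = higher, seed = 17))$truth$prevalence
  expect_lt(p_lo, st$truth$prevalence)
  expect_gt(p_hi, st$truth$prevalence)
})

test_that("implied true RERI matches an independent cell-odds computation", {
  cfg <- sim_config(n_individuals = 4000, slope_mean = 0,
                    outcome_coefs = list(covariates = list()), seed = 23)
  st <- simulate_study(cfg)
  z <- st$truth$prs_z
  slope <- st$truth$true_slopes$pm25_slope
  p <- st$truth$true_prob
  g <- z > stats::quantile(z, 0.75, names = FALSE)
  e <- slope > 0
  odds <- function(sel) mean(p[sel]) / (1 - mean(p[sel]))
  o00 <- odds(!g & !e)
  oracle <- odds(g & e) / o00 - odds(g & !e) / o00 - odds(!g & e) / o00 + 1
  expect_equal(st$truth$implied_true_reri, oracle)
})

test_that("study files round-trip through the on-disk formats", {
  cfg <- sim_config(n_individuals = 25, n_blocks = 2, snps_per_block = 4,
                    n_causal = 3, missing_rate = 0.05, seed = 8)
  st <- simulate_study(cfg)
  dir <- withr::local_tempdir()
  write_study(st, dir)
  expect_true(all(file.exists(file.path(
    dir, c("genotypes.vcf", "genotypes.tsv", "sumstats.tsv",
           "exposures.tsv", "cohort.tsv", "truth.json")))))
  g2 <- read_dosage_tsv(file.path(dir, "genotypes.tsv"))
  expect_equal(g2$genotypes, st$genotypes$genotypes)
  g3 <- read_vcf_genotypes(file.path(dir, "genotypes.vcf"))
  expect_equal(unname(g3$genotypes), unname(st$genotypes$genotypes))
  expect_equal(g3$variants$pos, st$genotypes$variants$pos)
})
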