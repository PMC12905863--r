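test_that("allele alignment keeps, flips and drops correctly", {
  set.seed(10)
  G <- matrix(stats::rbinom(60, 2, 0.4), 20, 3)
  geno <- make_genotypes(G, effect = c("A", "A", "A"), other = c("G", "G", "G"))
  ss <- data.frame(chrom = "1", pos = geno$variants$pos,
                   variant_id = geno$variants$variant_id,
                   effect_allele = c("A", "G", "A"),
                   other_allele = c("G", "A", "T"),
                   beta = c(0.5, 0.5, 0.5), pvalue = c(0.01, 0.01, 0.01),
                   stringsAsFactors = FALSE)
  al <- align_alleles(geno, ss)
  expect_equal(al$aligned$beta, c(0.5, -0.5))       # identity, then flip
  expect_equal(al$aligned$flipped, c(FALSE, TRUE))
  expect_equal(al$dropped$reason, "strand_ambiguous")  # the A/T variant
  # swapped coding is score-equivalent up to the constant 2*beta:
  # beta * (2 - G) = 2*beta + (-beta) * G
  s_id <- prs_score(geno, stats::setNames(0.5, "v001"))$prs_raw
  s_fl <- prs_score(geno, stats::setNames(-0.5, "v001"))$prs_raw
  expect_equal(s_fl, -s_id)
  expect_equal(0.5 * (2 - G[, 1]), 2 * 0.5 + s_fl, ignore_attr = TRUE)
})

test_that("clumping keeps the most significant variant of a correlated pair", {
  set.seed(12)
  x <- stats::rbinom(100, 2, 0.4)
  G <- cbind(x, x)  # r2 = 1
  geno <- make_genotypes(G, pos = c(5000, 15000))
  ss <- data.frame(chrom = "1", pos = c(5000, 15000),
                   variant_id = colnames(geno$genotypes),
                   pvalue = c(1e-8, 1e-9), stringsAsFactors = FALSE)
  kept <- ld_clump(ss, geno, clump_params(), threshold = 1e-5)
  expect_equal(kept, colnames(geno$genotypes)[2])  # smaller p wins
  # singleton
  expect_equal(ld_clump(ss[1, ], geno, clump_params(), 1e-5), colnames(G)[1])
  # nothing passes the threshold
  expect_equal(ld_clump(ss, geno, clump_params(), 1e-20), character())
})

test_that("clumping agrees with the brute-force reference on random instances", {
  set.seed(13)
  for (rep in 1:10) {
    st <- simulate_study(sim_config(n_individuals = 150, n_blocks = 6,
                                    snps_per_block = 5, n_causal = 10,
                                    within_block_rho = stats::runif(1, 0.3, 0.95),
                                    gwas_n_effective = 2000, seed = 100 + rep))
    thr <- sample(c(0.05, 0.2, 0.5, 1), 1)
    mine <- ld_clump(st$sumstats, st$genotypes, clump_params(), thr)
    ref <- clump_oracle(st$sumstats, st$genotypes, 0.1, 250, thr)
    expect_identical(mine, ref)
  }
})

test_that("clumped sets shrink as thresholds tighten and pass LD-free sets", {
  st <- simulate_study(sim_config(n_individuals = 400, n_blocks = 8,
                                  snps_per_block = 5, n_causal = 12,
                                  gwas_n_effective = 5000, seed = 44))
  sizes_p <- vapply(c(0.5, 0.1, 1e-3, 1e-8), function(thr)
    length(ld_clump(st$sumstats, st$genotypes, clump_params(), thr)), numeric(1))
  expect_true(all(diff(sizes_p) <= 0))
  sizes_r2 <- vapply(c(0.8, 0.3, 0.05), function(r2)
    length(ld_clump(st$sumstats, st$genotypes,
                    clump_params(r2_threshold = r2), 0.5)), numeric(1))
  expect_true(all(diff(sizes_r2) <= 0))
  # LD-free data: clumping returns exactly the variants passing the threshold
  free <- simulate_study(sim_config(n_individuals = 400, n_blocks = 40,
                                    snps_per_block = 1, n_causal = 5,
                                    within_block_rho = 0, seed = 45))
  kept <- ld_clump(free$sumstats, free$genotypes, clump_params(), 0.3)
  expect_setequal(kept,
                  free$sumstats$variant_id[free$sumstats$pvalue <= 0.3])
})

test_that("scoring matches the naive double-loop oracle", {
  one <- make_genotypes(matrix(c(0, 1, 2), 3, 1))
  expect_equal(prs_score(one, stats::setNames(log(2), "v001"))$prs_raw,
               c(0, log(2), 2 * log(2)))
  set.seed(14)
  G <- matrix(stats::rbinom(1000, 2, 0.3), 50, 20)
  G[sample(1000, 30)] <- NA
  geno <- make_genotypes(G)
  G <- geno$genotypes  # named copy
  beta <- stats::setNames(stats::rnorm(20), colnames(G))
  sc <- prs_score(geno, beta)
  # brute force with explicit mean-dosage imputation
  imp <- colMeans(G, na.rm = TRUE)
  oracle <- numeric(50)
  for (i in 1:50) for (j in 1:20) {
    gij <- if (is.na(G[i, j])) imp[j] else G[i, j]
    oracle[i] <- oracle[i] + beta[j] * gij
  }
  expect_equal(sc$prs_raw, oracle, tolerance = 1e-12)
  expect_equal(sc$prs_mean, oracle / 40, tolerance = 1e-12)
  # null weights, linearity and reorder invariance
  expect_equal(prs_score(geno, beta * 0)$prs_raw, rep(0, 50))
  expect_equal(prs_score(geno, 2 * beta)$prs_raw, 2 * sc$prs_raw)
  expect_equal(prs_score(geno, beta[sample(20)])$prs_raw, sc$prs_raw)
})

test_that("quartile categorization is right-closed and tie-stable", {
  q <- quartile_categories(1:100)
  expect_equal(as.vector(table(q)), c(25, 25, 25, 25))
  expect_error(quartile_categories(rep(1, 10)), "degenerate")
  # ties at the median: every value assigned exactly once, sizes off only
  # by the tie count
  x <- c(1, 2, 3, 5, 5, 5, 5, 5, 7, 8, 9, 10)
  qt <- quartile_categories(x)
  expect_equal(length(qt), 12L)
  expect_false(anyNA(qt))
  cuts <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  manual <- cut(x, c(-Inf, cuts, Inf), labels = c("Q1", "Q2", "Q3", "Q4"))
  expect_equal(qt, manual)
})

test_that("the threshold scan finds no signal in null summary statistics", {
  cfg <- sim_config(n_individuals = 5000, n_blocks = 10, snps_per_block = 5,
                    n_causal = 1, causal_beta_sd = 0, gwas_n_effective = 500,
                    outcome_coefs = list(prs_effect = 0, slope_effect = 0,
                                         interaction = 0),
                    seed = 55)
  st <- simulate_study(cfg)
  scan <- suppressWarnings(
    threshold_scan(st$genotypes, st$sumstats, st$cohort,
                   covariates = adjustment_set("model1")))
  expect_lt(abs(scan$delta_auc), 0.01)
})

test_that("informative summary statistics give a predictive score", {
  cfg <- sim_config(n_individuals = 4000, n_blocks = 10, snps_per_block = 5,
                    n_causal = 20, causal_beta_sd = 0.25,
                    gwas_n_effective = 1e6,
                    outcome_coefs = list(prs_effect = 0.5,
                                         covariates = list()),
                    seed = 56)
  st <- simulate_study(cfg)
  scan <- suppressWarnings(
    threshold_scan(st$genotypes, st$sumstats, st$cohort))
  expect_gt(scan$delta_auc, 0)
  # elevated risk in every upper quartile, maximal in the top quartile
  st$cohort$prs_quartile <- scan$scores$quartile
  or4 <- model_suite(st$cohort, "prs_quartile", adjustment = "crude")
  expect_true(all(or4$or > 1))
  expect_equal(or4$level[which.max(or4$or)], "Q4")
  expect_gt(or4$ci_low[or4$level == "Q4"], 1)
})
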