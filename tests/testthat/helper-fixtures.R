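# Shared fixture builders: everything is generated in code at test time.

# Build a genotype_matrix by hand from a dosage matrix and variant metadata.
make_genotypes <- function(G, pos = NULL, chrom = "1",
                           effect = "A", other = "G") {
  m <- ncol(G)
  if (is.null(colnames(G))) colnames(G) <- sprintf("v%03d", seq_len(m))
  if (is.null(rownames(G))) rownames(G) <- sprintf("i%03d", seq_len(nrow(G)))
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  variants <- data.frame(
    variant_id = colnames(G), chrom = rep(chrom, length.out = m),
    pos = as.integer(pos),
    effect_allele = rep(effect, length.out = m),
    other_allele = rep(other, length.out = m),
    maf = pmin(colMeans(G, na.rm = TRUE) / 2, 1 - colMeans(G, na.rm = TRUE) / 2),
    stringsAsFactors = FALSE)
  structure(list(genotypes = G, variants = variants),
            class = "genotype_matrix")
}

# Expand a 2x2 table (a exposed cases, b unexposed cases, c exposed
# non-cases, d unexposed non-cases) into individual rows.
expand_2x2 <- function(a, b, c, d) {
  data.frame(
    y = rep(c(1, 1, 0, 0), times = c(a, b, c, d)),
    x = rep(c(1, 0, 1, 0), times = c(a, b, c, d)))
}

# Independent greedy clumping reference: explicit p-ordered scan with
# all-pairs distance and r-squared checks.
clump_oracle <- function(ss, geno, r2t, win_kb, thr) {
  cand <- ss[ss$pvalue <= thr & ss$variant_id %in% colnames(geno$genotypes), ]
  if (nrow(cand) == 0) return(character())
  cand <- cand[order(cand$pvalue, cand$pos, cand$variant_id), ]
  kept <- character(); removed <- character()
  for (i in seq_len(nrow(cand))) {
    id <- cand$variant_id[i]
    if (id %in% removed) next
    kept <- c(kept, id)
    for (j in seq_len(nrow(cand))) {
      jd <- cand$variant_id[j]
      if (jd %in% kept || jd %in% removed) next
      if (cand$chrom[j] == cand$chrom[i] &&
          abs(cand$pos[j] - cand$pos[i]) <= win_kb * 1000) {
        r2 <- suppressWarnings(
          stats::cor(geno$genotypes[, id], geno$genotypes[, jd],
                     use = "pairwise.complete.obs"))^2
        if (!is.na(r2) && r2 >= r2t) removed <- c(removed, jd)
      }
    }
  }
  kept
}

# Independent Hardy-Weinberg exact test via the ratio recurrence over
# heterozygote counts (distinct formulation from the package's log-factorial
# enumeration).
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nr <- min(2 * n_AA + n_Aa, 2 * n - (2 * n_AA + n_Aa))
  if (nr == 0) return(1)
  hets <- seq(nr %% 2, nr, by = 2)
  k <- length(hets)
  p <- numeric(k); p[1] <- 1
  if (k > 1) for (t in 1:(k - 1)) {
    h <- hets[t]
    hom_r <- (nr - h) / 2
    hom_c <- n - h - hom_r
    p[t + 1] <- p[t] * 4 * hom_r * hom_c / ((h + 2) * (h + 1))
  }
  p <- p / sum(p)
  obs <- p[match(n_Aa, hets)]
  sum(p[p <= obs * (1 + 1e-12)])
}

# Table-1 printed 2x2 counts that verify exactly against their printed ORs:
# list(c(exposed cases, unexposed cases, exposed non-cases, unexposed
# non-cases), printed OR).
table1_counts <- list(
  hypertension   = list(counts = c(2186, 3129, 10375, 88864), or = 5.98),
  hyperlipidemia = list(counts = c(1744, 3571, 6104, 93135), or = 7.45),
  male_sex       = list(counts = c(2542, 2773, 35285, 63954), or = 1.66),
  age_60_79      = list(counts = c(2469, 240, 20590, 22741), or = 11.36),
  exercise       = list(counts = c(2578, 2737, 39207, 60032), or = 1.44),
  former_smoking = list(counts = c(897, 3785, 9880, 80163), or = 1.92),
  depression     = list(counts = c(295, 5020, 3516, 95723), or = 1.60)
)
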