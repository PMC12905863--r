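# Genotype quality control: per-variant filters (missingness, MAF,
# Hardy-Weinberg exact test stratified by case status) and per-individual
# filters (missingness, heterozygosity outliers, method-of-moments
# relatedness, principal-component outliers).

#' Quality-control thresholds
#'
#' @param max_missing_rate maximum call-missingness, applied to both variants
#'   and individuals.
#' @param min_maf minimum minor allele frequency.
#' @param hwe_p_cases,hwe_p_controls Hardy-Weinberg exact-test p-value below
#'   which a variant is excluded, evaluated separately in cases and controls.
#' @param het_sd heterozygosity-rate outlier bound, in SDs around the mean.
#' @param max_pihat relatedness bound; one member of each pair above it is
#'   removed.
#' @param pc_outlier_sd outlier bound on the top two genotype principal
#'   components, in SDs.
#' @return list of class \code{qc_params}.
#' @export
qc_params <- function(max_missing_rate = 0.02, min_maf = 0.05,
                      hwe_p_cases = 1e-10, hwe_p_controls = 1e-6,
                      het_sd = 3, max_pihat = 0.2, pc_outlier_sd = 6) {
  stopifnot(is_prob(max_missing_rate), is_prob(min_maf), min_maf <= 0.5,
            is_prob(hwe_p_cases), is_prob(hwe_p_controls),
            het_sd > 0, is_prob(max_pihat), pc_outlier_sd > 0)
  structure(list(max_missing_rate = max_missing_rate, min_maf = min_maf,
                 hwe_p_cases = hwe_p_cases, hwe_p_controls = hwe_p_controls,
                 het_sd = het_sd, max_pihat = max_pihat,
                 pc_outlier_sd = pc_outlier_sd),
            class = "qc_params")
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact conditional test: given the observed allele counts, the p-value is
#' the total probability of heterozygote counts whose conditional probability
#' does not exceed that of the observed count. The null distribution over the
#' heterozygote count h is proportional to \eqn{2^h n! / (n_{AA}! h! n_{aa}!)}.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (non-negative, total > 0).
#' @return exact two-sided p-value.
#' @export
#' @examples
#' hwe_exact_p(25, 50, 25)
hwe_exact_p <- function(n_AA, n_Aa, n_aa) {
  counts <- c(n_AA, n_Aa, n_aa)
  if (any(counts < 0) || any(counts != floor(counts)))
    stopf("genotype counts must be non-negative integers")
  n <- sum(counts)
  if (n == 0) stopf("insufficient data: all genotype counts are zero")
  nA <- 2 * n_AA + n_Aa
  n_rare <- min(nA, 2 * n - nA)
  if (n_rare == 0) return(1)  # monomorphic: only one configuration exists
  hets <- seq(n_rare %% 2, n_rare, by = 2)
  logp <- hets * log(2) + lfactorial(n) -
    lfactorial((n_rare - hets) / 2) - lfactorial(hets) -
    lfactorial(n - hets - (n_rare - hets) / 2)
  logp <- logp - max(logp)
  prob <- exp(logp) / sum(exp(logp))
  obs <- prob[match(n_Aa, hets)]
  sum(prob[prob <= obs * (1 + 1e-12)])
}

# Genotype counts (0/1/2) per variant within a subset of rows.
.geno_counts <- function(G) {
  cbind(n0 = colSums(G == 0, na.rm = TRUE),
        n1 = colSums(G == 1, na.rm = TRUE),
        n2 = colSums(G == 2, na.rm = TRUE))
}

#' Variant-level quality control
#'
#' Excludes variants with call missingness above \code{max_missing_rate},
#' minor allele frequency below \code{min_maf}, or Hardy-Weinberg exact-test
#' p-values below the case and control thresholds (tested separately in each
#' stratum).
#'
#' @param genotypes a \code{genotype_matrix}.
#' @param outcome binary vector (1 = case) aligned to the genotype rows, used
#'   to stratify the Hardy-Weinberg test.
#' @param params a \code{\link{qc_params}}.
#' @return list: \code{keep} (passing variant ids) and \code{report} (per
#'   variant: missingness, maf, HWE p-values, comma-separated failure
#'   reasons, pass flag).
#' @export
qc_variants <- function(genotypes, outcome, params = qc_params()) {
  G <- genotypes$genotypes
  if (length(outcome) != nrow(G))
    stopf("outcome must be aligned to the genotype rows")
  miss <- colMeans(is.na(G))
  freq <- colMeans(G, na.rm = TRUE) / 2
  maf <- pmin(freq, 1 - freq)
  maf[is.nan(maf)] <- 0

  case <- which(outcome == 1); ctrl <- which(outcome != 1)
  cc <- .geno_counts(G[case, , drop = FALSE])
  kk <- .geno_counts(G[ctrl, , drop = FALSE])
  hwe_case <- vapply(seq_len(ncol(G)), function(j) {
    if (sum(cc[j, ]) == 0) return(1)
    hwe_exact_p(cc[j, 1], cc[j, 2], cc[j, 3])
  }, numeric(1))
  hwe_ctrl <- vapply(seq_len(ncol(G)), function(j) {
    if (sum(kk[j, ]) == 0) return(1)
    hwe_exact_p(kk[j, 1], kk[j, 2], kk[j, 3])
  }, numeric(1))

  reasons <- mapply(function(mi, mf, hc, hk) {
    r <- character()
    if (mi > params$max_missing_rate) r <- c(r, "missingness")
    if (mf < params$min_maf) r <- c(r, "maf")
    if (hc < params$hwe_p_cases) r <- c(r, "hwe_cases")
    if (hk < params$hwe_p_controls) r <- c(r, "hwe_controls")
    paste(r, collapse = ",")
  }, miss, maf, hwe_case, hwe_ctrl)

  report <- data.frame(variant_id = colnames(G), missing = miss, maf = maf,
                       hwe_p_cases = hwe_case, hwe_p_controls = hwe_ctrl,
                       reasons = reasons, pass = reasons == "",
                       stringsAsFactors = FALSE, row.names = NULL)
  keep <- report$variant_id[report$pass]
  if (length(keep) == 0) warnf("no variants survive quality control")
  list(keep = keep, report = report)
}

# Standardize a dosage matrix per variant (mean-impute missing calls).
.standardize_genotypes <- function(G) {
  p <- colMeans(G, na.rm = TRUE) / 2
  keep <- p > 0 & p < 1
  G <- G[, keep, drop = FALSE]; p <- p[keep]
  X <- sweep(G, 2, 2 * p)
  X[is.na(X)] <- 0
  sweep(X, 2, sqrt(2 * p * (1 - p)), "/")
}

# Pairs with method-of-moments relatedness (GRM off-diagonal) above a
# threshold, computed blockwise to bound memory at large n. Because the
# estimator's null sampling SD scales as 1/sqrt(effective markers), a pair is
# only flagged when its estimate also exceeds 5 empirical null SDs - on small
# or LD-dense variant panels the raw threshold alone would mass-flag
# unrelated pairs. Returns the flagged pairs and the empirical off-diagonal
# SD.
related_pairs <- function(G, max_pihat, block_size = 2000L) {
  X <- .standardize_genotypes(G)
  m <- ncol(X); n <- nrow(X)
  out <- list()
  s1 <- s2 <- 0; cnt <- 0
  starts <- seq(1L, n, by = block_size)
  for (s in starts) {
    rows <- s:min(s + block_size - 1L, n)
    A <- tcrossprod(X[rows, , drop = FALSE], X) / m
    for (k in seq_along(rows)) {
      i <- rows[k]
      if (i < n) {
        v <- A[k, (i + 1L):n]
        s1 <- s1 + sum(v); s2 <- s2 + sum(v * v); cnt <- cnt + length(v)
        j <- which(v > max_pihat) + i
        if (length(j))
          out[[length(out) + 1L]] <- data.frame(i = i, j = j,
                                                pihat = A[k, j])
      }
    }
  }
  sd_null <- if (cnt > 1) sqrt(max(s2 / cnt - (s1 / cnt)^2, 0)) else 0
  pairs <- if (length(out)) do.call(rbind, out)
  else data.frame(i = integer(), j = integer(), pihat = numeric())
  pairs <- pairs[pairs$pihat > max(max_pihat, 5 * sd_null), , drop = FALSE]
  list(pairs = pairs, sd_null = sd_null)
}

#' Individual-level quality control
#'
#' Excludes individuals with call missingness above \code{max_missing_rate};
#' heterozygosity rate (heterozygous calls over non-missing calls) outside
#' mean +/- \code{het_sd} SDs; one member of each pair with method-of-moments
#' relatedness above \code{max_pihat} (and above 5 empirical null SDs of the
#' estimator, so small variant panels do not mass-flag unrelated pairs; the
#' member with higher missingness is dropped, ties broken toward the larger
#' row index); and outliers beyond
#' \code{pc_outlier_sd} SDs on either of the top two principal components of
#' the standardized genotype matrix.
#'
#' @param genotypes a \code{genotype_matrix}.
#' @param params a \code{\link{qc_params}}.
#' @param relatedness set \code{FALSE} to skip the O(n^2) relatedness scan.
#' @return list: \code{keep} (passing individual ids) and \code{report}.
#' @export
qc_individuals <- function(genotypes, params = qc_params(), relatedness = TRUE) {
  G <- genotypes$genotypes
  n <- nrow(G)
  ids <- rownames(G)
  miss <- rowMeans(is.na(G))
  nonmiss <- rowSums(!is.na(G))
  het <- rowSums(G == 1, na.rm = TRUE) / pmax(nonmiss, 1)
  het_mu <- mean(het); het_sd <- stats::sd(het)

  flags <- rep("", n)
  add_flag <- function(flags, idx, what)
    ifelse(seq_along(flags) %in% idx,
           ifelse(flags == "", what, paste(flags, what, sep = ",")), flags)

  flags <- add_flag(flags, which(miss > params$max_missing_rate), "missingness")
  if (is.finite(het_sd) && het_sd > 0) {
    out_het <- which(abs(het - het_mu) > params$het_sd * het_sd)
    flags <- add_flag(flags, out_het, "heterozygosity")
  }

  if (relatedness && n >= 2) {
    pairs <- related_pairs(G, params$max_pihat)$pairs
    drop_rel <- integer()
    if (nrow(pairs)) {
      alive <- rep(TRUE, n)
      for (r in seq_len(nrow(pairs))) {
        i <- pairs$i[r]; j <- pairs$j[r]
        if (alive[i] && alive[j]) {
          victim <- if (miss[i] > miss[j]) i else if (miss[j] > miss[i]) j
                    else max(i, j)
          alive[victim] <- FALSE
          drop_rel <- c(drop_rel, victim)
        }
      }
    }
    flags <- add_flag(flags, drop_rel, "relatedness")
  } else if (relatedness && n < 2) {
    warnf("fewer than 2 individuals; relatedness screen skipped")
  }

  X <- .standardize_genotypes(G)
  if (ncol(X) >= 2 && n >= 3) {
    pcs <- stats::prcomp(X, center = FALSE, rank. = 2L)$x
    out_pc <- which(abs(pcs[, 1] - mean(pcs[, 1])) >
                      params$pc_outlier_sd * stats::sd(pcs[, 1]) |
                    abs(pcs[, 2] - mean(pcs[, 2])) >
                      params$pc_outlier_sd * stats::sd(pcs[, 2]))
    flags <- add_flag(flags, out_pc, "pc_outlier")
  }

  report <- data.frame(participant_id = ids, missing = miss,
                       het_rate = het, reasons = flags, pass = flags == "",
                       stringsAsFactors = FALSE, row.names = NULL)
  list(keep = ids[report$pass], report = report)
}

#' Subset a genotype matrix by individuals and/or variants
#'
#' @param genotypes a \code{genotype_matrix}.
#' @param individuals individual ids to keep (default all).
#' @param variants variant ids to keep (default all).
#' @return the filtered \code{genotype_matrix}.
#' @export
subset_genotypes <- function(genotypes, individuals = NULL, variants = NULL) {
  G <- genotypes$genotypes
  v <- genotypes$variants
  if (!is.null(individuals)) G <- G[rownames(G) %in% individuals, , drop = FALSE]
  if (!is.null(variants)) {
    keep <- colnames(G) %in% variants
    G <- G[, keep, drop = FALSE]
    v <- v[v$variant_id %in% variants, , drop = FALSE]
  }
  structure(list(genotypes = G, variants = v), class = "genotype_matrix")
}
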