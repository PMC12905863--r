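# Clumping-and-thresholding polygenic risk score: allele alignment against
# external summary statistics, greedy p-value-ordered LD clumping, weighted
# dosage scoring, threshold selection by delta-AUC, quartile categorization.

#' Clumping-and-thresholding parameters
#'
#' @param r2_threshold squared dosage correlation above which a variant is
#'   assigned to a nearby, more significant index variant.
#' @param window_kb clumping window half-width in kilobases.
#' @param p_thresholds ascending candidate p-value thresholds for the score
#'   scan (defaults span 5e-8 to 0.5).
#' @return list of class \code{clump_params}.
#' @export
clump_params <- function(r2_threshold = 0.1, window_kb = 250,
                         p_thresholds = c(5e-8, 1e-6, 1e-4, 1e-3, 0.01,
                                          0.05, 0.1, 0.3, 0.5)) {
  stopifnot(r2_threshold > 0, r2_threshold < 1, window_kb > 0,
            all(p_thresholds > 0), all(p_thresholds <= 1),
            !is.unsorted(p_thresholds, strictly = TRUE))
  structure(list(r2_threshold = r2_threshold, window_kb = window_kb,
                 p_thresholds = p_thresholds),
            class = "clump_params")
}

#' Align summary-statistic effects to the genotype allele coding
#'
#' Matches variants by id (or by chrom:pos when ids do not overlap) and puts
#' every effect on the genotype's counted allele: where the summary-statistic
#' effect allele equals the counted allele the effect is kept; where the
#' alleles are swapped the effect sign is flipped; strand-ambiguous (A/T, C/G)
#' and allele-incompatible variants are dropped with a reason.
#'
#' @param genotypes a \code{genotype_matrix} (counted allele =
#'   \code{effect_allele} column of its variant table).
#' @param sumstats summary-statistic data frame (variant_id, effect_allele,
#'   other_allele, beta, pvalue, ...).
#' @return list: \code{aligned} (variant_id, beta, pvalue, flipped) and
#'   \code{dropped} (variant_id, reason).
#' @export
align_alleles <- function(genotypes, sumstats) {
  v <- genotypes$variants
  key_match <- match(sumstats$variant_id, v$variant_id)
  if (all(is.na(key_match))) {
    key_match <- match(paste(sumstats$chrom, sumstats$pos),
                       paste(v$chrom, v$pos))
  }
  if (all(is.na(key_match)))
    stopf("no summary-statistic variants match the genotype variants")

  norm <- function(x) toupper(trimws(x))
  out <- vector("list", nrow(sumstats))
  dropped <- list()
  for (i in seq_len(nrow(sumstats))) {
    j <- key_match[i]
    id <- sumstats$variant_id[i]
    if (is.na(j)) {
      dropped[[length(dropped) + 1L]] <- c(id, "unmatched"); next
    }
    sa <- norm(sumstats$effect_allele[i]); so <- norm(sumstats$other_allele[i])
    pair <- sort(c(sa, so))
    if (identical(pair, c("A", "T")) || identical(pair, c("C", "G"))) {
      dropped[[length(dropped) + 1L]] <- c(id, "strand_ambiguous"); next
    }
    ga <- norm(v$effect_allele[j]); go <- norm(v$other_allele[j])
    if (sa == ga && so == go) {
      out[[i]] <- data.frame(variant_id = v$variant_id[j],
                             beta = sumstats$beta[i],
                             pvalue = sumstats$pvalue[i], flipped = FALSE,
                             stringsAsFactors = FALSE)
    } else if (sa == go && so == ga) {
      out[[i]] <- data.frame(variant_id = v$variant_id[j],
                             beta = -sumstats$beta[i],
                             pvalue = sumstats$pvalue[i], flipped = TRUE,
                             stringsAsFactors = FALSE)
    } else {
      dropped[[length(dropped) + 1L]] <- c(id, "allele_mismatch")
    }
  }
  aligned <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  dropped <- if (length(dropped)) {
    dd <- do.call(rbind, dropped)
    data.frame(variant_id = dd[, 1], reason = dd[, 2], stringsAsFactors = FALSE)
  } else data.frame(variant_id = character(), reason = character())
  list(aligned = aligned %||%
         data.frame(variant_id = character(), beta = numeric(),
                    pvalue = numeric(), flipped = logical()),
       dropped = dropped)
}

#' Greedy p-value-ordered LD clumping
#'
#' The clumping step of C+T scoring, matching the behaviour of the standard
#' GWAS tooling: variants with p at or below the threshold are visited in
#' ascending p order (ties broken by position, then id); each unassigned
#' variant becomes an index and removes every remaining candidate within
#' \code{window_kb} whose squared dosage correlation with it reaches
#' \code{r2_threshold}. All retained index pairs within the window therefore
#' have r-squared below the threshold.
#'
#' @param sumstats summary statistics (variant_id, chrom, pos, pvalue).
#' @param genotypes a \code{genotype_matrix} providing dosages for r-squared
#'   (pairwise-complete Pearson correlation).
#' @param params a \code{\link{clump_params}}.
#' @param threshold p-value threshold for candidacy.
#' @return character vector of index variant ids (possibly empty).
#' @export
ld_clump <- function(sumstats, genotypes, params = clump_params(), threshold) {
  cand <- sumstats[sumstats$pvalue <= threshold &
                     sumstats$variant_id %in% colnames(genotypes$genotypes), ]
  if (nrow(cand) == 0) return(character())
  cand <- cand[order(cand$pvalue, cand$pos, cand$variant_id), ]
  G <- genotypes$genotypes[, cand$variant_id, drop = FALSE]
  k <- nrow(cand)
  active <- rep(TRUE, k)
  index <- character()
  win <- params$window_kb * 1000
  for (i in seq_len(k)) {
    if (!active[i]) next
    index <- c(index, cand$variant_id[i])
    active[i] <- FALSE
    nb <- which(active & cand$chrom == cand$chrom[i] &
                  abs(cand$pos - cand$pos[i]) <= win)
    if (length(nb)) {
      r2 <- suppressWarnings(
        stats::cor(G[, i], G[, nb, drop = FALSE],
                   use = "pairwise.complete.obs"))^2
      hit <- nb[!is.na(r2) & r2 >= params$r2_threshold]
      active[hit] <- FALSE
    }
  }
  index
}

#' Weighted polygenic score
#'
#' \eqn{PRS_i = \sum_j \beta_j G_{ij}} over the supplied variants, with
#' missing dosages imputed as twice the sample effect-allele frequency (the
#' standard scoring default). Also reports the per-allele normalized score
#' \code{prs_mean} = score / (2 x variant count).
#'
#' @param genotypes a \code{genotype_matrix}.
#' @param betas named numeric vector of aligned effects (names = variant ids),
#'   or the \code{aligned} data frame from \code{\link{align_alleles}}.
#' @return data frame: participant_id, prs_raw, prs_mean; attribute
#'   \code{n_variants}.
#' @export
prs_score <- function(genotypes, betas) {
  if (is.data.frame(betas)) betas <- stats::setNames(betas$beta, betas$variant_id)
  use <- intersect(names(betas), colnames(genotypes$genotypes))
  ids <- rownames(genotypes$genotypes)
  if (length(use) == 0) {
    warnf("no variants retained for scoring; all scores are zero")
    out <- data.frame(participant_id = ids, prs_raw = 0, prs_mean = 0,
                      stringsAsFactors = FALSE)
    attr(out, "n_variants") <- 0L
    return(out)
  }
  G <- genotypes$genotypes[, use, drop = FALSE]
  if (anyNA(G)) {
    freq <- colMeans(G, na.rm = TRUE)
    idx <- which(is.na(G), arr.ind = TRUE)
    G[idx] <- freq[idx[, 2]]
  }
  score <- as.vector(G %*% betas[use])
  out <- data.frame(participant_id = ids, prs_raw = score,
                    prs_mean = score / (2 * length(use)),
                    stringsAsFactors = FALSE)
  attr(out, "n_variants") <- length(use)
  out
}

#' Quartile categorization of polygenic scores
#'
#' Cut points at the 25th/50th/75th percentiles of the analyzed cohort
#' (type-7 quantiles); intervals are right-closed, so a score equal to a cut
#' point falls in the lower category. Q1 = low genetic risk, Q4 = high.
#'
#' @param scores numeric vector with at least 4 distinct values.
#' @return factor with levels Q1-Q4.
#' @export
quartile_categories <- function(scores) {
  if (length(unique(scores)) < 4)
    stopf("degenerate categorization: fewer than 4 distinct score values")
  cuts <- stats::quantile(scores, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  # right-closed assignment that also tolerates tied (duplicate) cut points
  idx <- 1L + (scores > cuts[1]) + (scores > cuts[2]) + (scores > cuts[3])
  factor(paste0("Q", idx), levels = paste0("Q", 1:4))
}

#' Scan p-value thresholds and select the score maximizing delta-AUC
#'
#' For each candidate threshold: clump, score, standardize the score, fit a
#' logistic model outcome ~ covariates + score, and record the gain in AUC
#' over the covariate-only null model plus the Nagelkerke pseudo-R-squared.
#' The chosen threshold maximizes delta-AUC (ties resolved toward the smaller
#' threshold); the returned scores and quartiles come from that threshold.
#'
#' @param genotypes a \code{genotype_matrix} (post-QC).
#' @param sumstats external summary statistics.
#' @param cohort data frame with the outcome and covariates, rows aligned to
#'   the genotype rows.
#' @param params a \code{\link{clump_params}}.
#' @param covariates covariate column names for the null model (may be empty).
#' @param outcome outcome column name (binary).
#' @return object of class \code{prs_scan}: \code{scan} (threshold,
#'   n_variants, delta_auc, pseudo_r2), \code{chosen_threshold},
#'   \code{delta_auc}, \code{scores} (participant_id, prs_raw, prs_mean,
#'   quartile), \code{variants} (ids used at the chosen threshold).
#' @export
threshold_scan <- function(genotypes, sumstats, cohort,
                           params = clump_params(), covariates = character(),
                           outcome = "t2d") {
  stopifnot(identical(cohort$participant_id, rownames(genotypes$genotypes)))
  al <- align_alleles(genotypes, sumstats)
  betas <- stats::setNames(al$aligned$beta, al$aligned$variant_id)
  pvals <- stats::setNames(al$aligned$pvalue, al$aligned$variant_id)
  ss <- sumstats[sumstats$variant_id %in% names(betas), ]
  ss$pvalue <- pvals[ss$variant_id]

  y <- cohort[[outcome]]
  rhs0 <- if (length(covariates)) paste(covariates, collapse = " + ") else "1"
  null_fit <- stats::glm(stats::reformulate(rhs0, response = outcome),
                         data = cohort, family = stats::binomial())
  auc0 <- auc_binary(y, stats::fitted(null_fit))

  rows <- list(); per_thr <- list()
  for (thr in params$p_thresholds) {
    idx <- ld_clump(ss, genotypes, params, thr)
    if (length(idx) == 0) {
      rows[[length(rows) + 1L]] <- data.frame(threshold = thr, n_variants = 0L,
                                              delta_auc = NA_real_,
                                              pseudo_r2 = NA_real_)
      per_thr[length(rows)] <- list(NULL)
      next
    }
    sc <- prs_score(genotypes, betas[idx])
    dat <- cohort
    dat$.prs_z <- if (stats::sd(sc$prs_raw) > 0) as.numeric(scale(sc$prs_raw))
                  else sc$prs_raw
    fit <- tryCatch(
      stats::glm(stats::reformulate(c(if (length(covariates)) covariates, ".prs_z"),
                                    response = outcome),
                 data = dat, family = stats::binomial(),
                 control = stats::glm.control(epsilon = 1e-10, maxit = 50)),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) {
      warnf("model at threshold %g did not converge; threshold skipped", thr)
      rows[[length(rows) + 1L]] <- data.frame(threshold = thr,
                                              n_variants = length(idx),
                                              delta_auc = NA_real_,
                                              pseudo_r2 = NA_real_)
      per_thr[length(rows)] <- list(NULL)
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      threshold = thr, n_variants = length(idx),
      delta_auc = auc_binary(y, stats::fitted(fit)) - auc0,
      pseudo_r2 = nagelkerke_r2(fit))
    per_thr[[length(rows)]] <- list(scores = sc, variants = idx)
  }
  scan <- do.call(rbind, rows)
  if (all(is.na(scan$delta_auc)))
    stopf("no threshold produced a usable score")
  best <- which.max(scan$delta_auc)  # ascending grid: first max = smallest thr
  chosen <- per_thr[[best]]
  scores <- chosen$scores
  scores$quartile <- quartile_categories(scores$prs_raw)
  structure(list(scan = scan, chosen_threshold = scan$threshold[best],
                 delta_auc = scan$delta_auc[best],
                 pseudo_r2 = scan$pseudo_r2[best],
                 scores = scores, variants = chosen$variants),
            class = "prs_scan")
}

#' @export
print.prs_scan <- function(x, ...) {
  cat("C+T threshold scan\n")
  print(x$scan, row.names = FALSE)
  cat(sprintf("chosen threshold: %g (%d variants, delta-AUC %.4f, Nagelkerke R2 %.4f)\n",
              x$chosen_threshold, length(x$variants), x$delta_auc, x$pseudo_r2))
  invisible(x)
}
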