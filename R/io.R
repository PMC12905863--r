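# Readers and writers for the on-disk interchange formats: VCF (GT hard
# calls), dosage TSV, summary-statistic TSV, long exposure TSV, cohort TSV,
# and the ground-truth JSON.

#' Write hard-call genotypes as VCF
#'
#' Minimal VCF 4.2 with a GT FORMAT field; REF is the other allele and ALT
#' the counted (effect) allele, so dosage = ALT allele count. Missing calls
#' are written as "./.".
#'
#' @param genotypes a \code{genotype_matrix}.
#' @param path output path (plain text).
#' @export
write_vcf <- function(genotypes, path) {
  G <- genotypes$genotypes
  v <- genotypes$variants
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=prsgxe",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(G)), collapse = "\t")), con)
  for (j in seq_len(ncol(G))) {
    gj <- G[, j]
    calls <- ifelse(is.na(gj), "./.", gt_code[as.character(gj)])
    writeLines(paste(c(v$chrom[j], v$pos[j], v$variant_id[j],
                       v$other_allele[j], v$effect_allele[j], ".", "PASS",
                       ".", "GT", calls), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read hard-call genotypes from a VCF
#'
#' Parses GT fields with vcfR and counts ALT alleles, so the returned dosage
#' matrix uses ALT as the counted (effect) allele.
#'
#' @param path VCF path.
#' @return a \code{genotype_matrix}.
#' @export
read_vcf_genotypes <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stopf("reading VCF requires the vcfR package")
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  fix <- vcfR::getFIX(vcf)
  dose <- apply(gt, c(1, 2), function(x) {
    if (is.na(x) || x %in% c("./.", ".|.")) return(NA_real_)
    sum(as.integer(strsplit(x, "[/|]")[[1]]) > 0)
  })
  G <- t(dose)
  variants <- data.frame(variant_id = unname(fix[, "ID"]),
                         chrom = unname(fix[, "CHROM"]),
                         pos = as.integer(fix[, "POS"]),
                         effect_allele = unname(fix[, "ALT"]),
                         other_allele = unname(fix[, "REF"]),
                         stringsAsFactors = FALSE)
  colnames(G) <- variants$variant_id
  structure(list(genotypes = G, variants = variants), class = "genotype_matrix")
}

#' Write genotypes as a dosage TSV (rows = individuals)
#'
#' Two files are written: \code{path} with participant_id plus one dosage
#' column per variant, and \code{paste0(path, ".variants")} with the variant
#' metadata.
#'
#' @param genotypes a \code{genotype_matrix}.
#' @param path output path.
#' @export
write_dosage_tsv <- function(genotypes, path) {
  df <- data.frame(participant_id = rownames(genotypes$genotypes),
                   genotypes$genotypes, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_file(df, path)
  write_tsv_file(genotypes$variants, paste0(path, ".variants"))
  invisible(path)
}

#' Read genotypes from a dosage TSV written by \code{write_dosage_tsv}
#'
#' @param path dosage TSV path (expects \code{paste0(path, ".variants")}
#'   alongside).
#' @return a \code{genotype_matrix}.
#' @export
read_dosage_tsv <- function(path) {
  df <- read_tsv_file(path)
  variants <- read_tsv_file(paste0(path, ".variants"))
  G <- as.matrix(df[, -1, drop = FALSE])
  rownames(G) <- df$participant_id
  structure(list(genotypes = G, variants = variants), class = "genotype_matrix")
}

#' Write a full synthetic study to a directory
#'
#' Emits genotypes (VCF and dosage TSV), summary statistics, the long
#' exposure panel, the cohort table, and the ground truth as JSON.
#'
#' @param study result of \code{\link{simulate_study}}.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_vcf(study$genotypes, file.path(dir, "genotypes.vcf"))
  write_dosage_tsv(study$genotypes, file.path(dir, "genotypes.tsv"))
  write_tsv_file(study$sumstats, file.path(dir, "sumstats.tsv"))
  write_tsv_file(study$exposures, file.path(dir, "exposures.tsv"))
  write_tsv_file(study$cohort, file.path(dir, "cohort.tsv"))
  truth <- study$truth
  truth$causal_betas <- as.list(truth$causal_betas)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}
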