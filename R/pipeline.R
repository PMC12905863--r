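# End-to-end orchestration: simulate or ingest -> QC -> trend slopes -> PRS
# threshold scan -> association models -> interaction suite, with
# paper-shaped TSV tables, a machine-readable manifest, and a plain-text log.

#' Descriptive case/non-case table with level-wise odds ratios
#'
#' For every categorical cohort variable: counts and column percentages by
#' case status, a 2x2 odds ratio per non-reference level against the
#' variable's reference level (first factor level), and the chi-square
#' p-value over the full variable. Binary 0/1 columns are treated as no/yes
#' factors. An overall prevalence row is included as variable
#' \code{"_overall"}.
#'
#' @param cohort cohort data frame.
#' @param outcome binary outcome column name.
#' @return data frame: variable, level, reference, cases_n, cases_pct,
#'   controls_n, controls_pct, or, ci_low, ci_high, p_chisq; attribute
#'   \code{prevalence} (percent).
#' @export
table1_report <- function(cohort, outcome = "t2d") {
  if (nrow(cohort) == 0) stopf("empty cohort")
  y <- cohort[[outcome]]
  n_case <- sum(y == 1); n_ctrl <- sum(y != 1)
  vars <- setdiff(names(cohort), c("participant_id", outcome))
  vars <- vars[vapply(cohort[vars], function(x)
    is.factor(x) || is.character(x) || all(x %in% c(0, 1, NA)), logical(1))]

  rows <- list()
  rows[[1]] <- data.frame(variable = "_overall", level = "cases",
                          reference = FALSE, cases_n = n_case,
                          cases_pct = 100 * n_case / (n_case + n_ctrl),
                          controls_n = n_ctrl,
                          controls_pct = 100 * n_ctrl / (n_case + n_ctrl),
                          or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                          p_chisq = NA_real_, stringsAsFactors = FALSE)
  for (v in vars) {
    x <- cohort[[v]]
    if (!is.factor(x)) {
      x <- if (all(x %in% c(0, 1, NA)))
        factor(ifelse(x == 1, "yes", "no"), levels = c("no", "yes"))
      else factor(x)
    }
    tab <- table(x, factor(y == 1, levels = c(FALSE, TRUE)))
    p <- if (nrow(tab) >= 2 && all(rowSums(tab) > 0) && all(colSums(tab) > 0))
      chisq_test_table(tab)$p_value else NA_real_
    ref <- levels(x)[1]
    for (lev in levels(x)) {
      a <- tab[lev, "TRUE"]; cc <- tab[lev, "FALSE"]
      if (lev == ref || nlevels(x) < 2) {
        orv <- list(or = NA_real_, ci_low = NA_real_, ci_high = NA_real_)
      } else {
        b <- tab[ref, "TRUE"]; d <- tab[ref, "FALSE"]
        orv <- tryCatch(two_by_two_or(a, b, cc, d),
                        error = function(e)
                          list(or = NA_real_, ci_low = NA_real_,
                               ci_high = NA_real_))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, level = lev, reference = lev == ref,
        cases_n = a, cases_pct = 100 * a / max(n_case, 1),
        controls_n = cc, controls_pct = 100 * cc / max(n_ctrl, 1),
        or = orv$or, ci_low = orv$ci_low, ci_high = orv$ci_high,
        p_chisq = p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "prevalence") <- 100 * n_case / (n_case + n_ctrl)
  out
}

# Default pipeline configuration skeleton; user values override by name.
default_run_config <- function() {
  list(
    simulate = list(),          # sim_config() arguments; NULL to use inputs
    inputs = NULL,              # list(genotypes=, sumstats=, exposures=, cohort=)
    qc = list(relatedness = TRUE),
    clump = list(),
    adjustment = c("crude", "model1", "model2"),
    interaction = list(pollutant = "pm25", n_boot = 200,
                       reri_variant = "standard", mode = "joint",
                       adjustment = "model1"),
    seed = 1
  )
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or ingest) -> individual and variant QC -> exposure
#' trend slopes -> PRS threshold scan -> association models -> additive and
#' multiplicative interaction, and writes paper-shaped TSV tables
#' (\code{table1.tsv} descriptives and 2x2 ORs, \code{table2.tsv} slope
#' descriptives, \code{table3.tsv} slope ORs per adjustment,
#' \code{table4.tsv} PRS-quartile ORs, \code{table5.tsv} per-quartile slope
#' ORs with RERI), a JSON run manifest (package version, seed, config hash),
#' and a plain-text log. All randomness is governed by \code{config$seed}.
#'
#' @param config configuration list (see \code{default_run_config} in the
#'   sources) or path to a YAML file with the same structure. Supply either a
#'   \code{simulate} block (arguments to \code{\link{sim_config}}) or an
#'   \code{inputs} block of file paths (genotypes VCF/dosage TSV, sumstats,
#'   exposures, cohort).
#' @param out_dir output directory.
#' @return list with the analysis objects (invisible): cohort, slopes, scan,
#'   tables, interaction fit, RERI, manifest.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stopf("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  cfg <- merge_config(default_run_config(), config)
  if (missing(out_dir)) out_dir <- cfg$out_dir
  if (is.null(out_dir)) stopf("an output directory is required")
  if (is.null(cfg$simulate) && is.null(cfg$inputs))
    stopf("config needs either a 'simulate' block or an 'inputs' block")
  if (!is.null(cfg$inputs)) {
    for (f in unlist(cfg$inputs))
      if (!file.exists(f)) stopf("input file not found: %s", f)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  log_con <- file(log_path, "w")
  on.exit(close(log_con), add = TRUE)
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    writeLines(msg, log_con)
    message(msg)
  }
  manifest <- list(package = "prsgxe",
                   version = as.character(utils::packageVersion("prsgxe")),
                   seed = cfg$seed, config_hash = config_hash(cfg),
                   status = "running", failed_stage = NULL)
  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  stage <- function(name, expr) {
    say("stage: %s", name)
    tryCatch(expr, error = function(e) {
      manifest$status <<- "failed"; manifest$failed_stage <<- name
      write_manifest()
      stopf("pipeline failed at stage '%s': %s", name, conditionMessage(e))
    })
  }

  truth <- NULL
  dat <- stage("data", {
    if (!is.null(cfg$simulate) && is.null(cfg$inputs)) {
      sc <- do.call(sim_config, c(cfg$simulate, list(seed = cfg$seed)))
      st <- simulate_study(sc)
      truth <- st$truth
      say("  simulated %d individuals x %d variants (prevalence %.2f%%)",
          nrow(st$genotypes$genotypes), ncol(st$genotypes$genotypes),
          100 * st$truth$prevalence)
      st
    } else {
      g <- if (grepl("\\.vcf$", cfg$inputs$genotypes))
        read_vcf_genotypes(cfg$inputs$genotypes)
      else read_dosage_tsv(cfg$inputs$genotypes)
      co <- read_tsv_file(cfg$inputs$cohort)
      # restore canonical reference levels on ingest
      for (v in intersect(names(.covariate_marginals), names(co)))
        co[[v]] <- factor(co[[v]], levels = names(.covariate_marginals[[v]]))
      list(genotypes = g,
           sumstats = read_tsv_file(cfg$inputs$sumstats),
           exposures = read_tsv_file(cfg$inputs$exposures),
           cohort = co)
    }
  })
  cohort <- dat$cohort

  qcp <- do.call(qc_params, cfg$qc[setdiff(names(cfg$qc), "relatedness")])
  qc_ind <- stage("qc_individuals", qc_individuals(
    dat$genotypes, qcp, relatedness = isTRUE(cfg$qc$relatedness)))
  qc_var <- stage("qc_variants", {
    keep_rows <- match(qc_ind$keep, cohort$participant_id)
    qc_variants(subset_genotypes(dat$genotypes, individuals = qc_ind$keep),
                cohort$t2d[keep_rows], qcp)
  })
  genotypes <- subset_genotypes(dat$genotypes, individuals = qc_ind$keep,
                                variants = qc_var$keep)
  cohort <- cohort[cohort$participant_id %in% qc_ind$keep, , drop = FALSE]
  say("  QC kept %d/%d individuals, %d/%d variants",
      length(qc_ind$keep), nrow(qc_ind$report),
      length(qc_var$keep), nrow(qc_var$report))
  write_tsv_file(qc_ind$report, file.path(out_dir, "qc_individuals.tsv"))
  write_tsv_file(qc_var$report, file.path(out_dir, "qc_variants.tsv"))

  slopes <- stage("slopes", {
    panel <- dat$exposures
    slope_table(panel[panel$participant_id %in% cohort$participant_id, ])
  })
  table2 <- exposure_summary(slopes)
  cohort <- merge(cohort, slope_wide(slopes), by = "participant_id",
                  sort = TRUE)
  cohort <- cohort[order(cohort$participant_id), , drop = FALSE]
  rownames(cohort) <- NULL

  scan <- stage("prs_scan", {
    cp <- do.call(clump_params, cfg$clump)
    threshold_scan(genotypes, dat$sumstats, cohort, cp,
                   covariates = adjustment_set("model1"))
  })
  say("  chosen p threshold %g, delta-AUC %.4f",
      scan$chosen_threshold, scan$delta_auc)
  cohort$prs_raw <- scan$scores$prs_raw
  cohort$prs_quartile <- scan$scores$quartile
  write_tsv_file(scan$scan, file.path(out_dir, "prs_scan.tsv"))
  write_tsv_file(scan$scores, file.path(out_dir, "prs_scores.tsv"))

  slope_cols <- paste0(unique(slopes$pollutant), "_slope")
  table3 <- stage("association", {
    model_suite(cohort, slope_cols, adjustment = cfg$adjustment)
  })
  table4 <- stage("prs_association", {
    model_suite(cohort, "prs_quartile", adjustment = cfg$adjustment)
  })
  table1 <- table1_report(cohort[, !(names(cohort) %in%
                                       c(slope_cols,
                                         paste0(unique(slopes$pollutant),
                                                "_baseline"),
                                         "prs_raw"))])

  inter <- stage("interaction", {
    icfg <- cfg$interaction
    exp_col <- paste0(icfg$pollutant, "_slope")
    fit <- gxe_fit(cohort, exposure = exp_col,
                   modifier = "prs_quartile",
                   covariates = adjustment_set(icfg$adjustment),
                   mode = icfg$mode)
    rr <- if (icfg$mode == "joint")
      reri(fit, n_boot = icfg$n_boot, seed = stage_seed(cfg$seed, 9L),
           variant = icfg$reri_variant)
    else NULL
    list(fit = fit, reri = rr)
  })
  table5 <- inter$fit$category_or
  table5$pollutant <- cfg$interaction$pollutant
  if (!is.null(inter$reri)) {
    i <- match(table5$category, inter$reri$category)
    table5$reri <- inter$reri$estimate[i]
    table5$reri_ci_low <- inter$reri$ci_low[i]
    table5$reri_ci_high <- inter$reri$ci_high[i]
    table5$reri_variant <- inter$reri$variant[1]
  }
  if (!is.null(inter$fit$interaction_tests))
    write_tsv_file(inter$fit$interaction_tests,
                   file.path(out_dir, "interaction_wald.tsv"))

  for (nm in c("table1", "table2", "table3", "table4", "table5"))
    write_tsv_file(get(nm), file.path(out_dir, paste0(nm, ".tsv")))
  manifest$status <- "ok"
  manifest$prevalence_pct <- attr(table1, "prevalence")
  manifest$chosen_threshold <- scan$chosen_threshold
  manifest$delta_auc <- scan$delta_auc
  write_manifest()
  say("pipeline complete: %s", out_dir)

  invisible(list(cohort = cohort, slopes = slopes, scan = scan,
                 tables = list(table1 = table1, table2 = table2,
                               table3 = table3, table4 = table4,
                               table5 = table5),
                 interaction = inter$fit, reri = inter$reri, truth = truth,
                 manifest = manifest))
}
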