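# Contingency-table statistics and crude/adjusted logistic odds-ratio models.

MODEL1_COVARIATES <- c("age_group", "sex", "income", "bmi_class", "education",
                       "exercise", "smoking", "drinking")
MODEL2_COVARIATES <- c(MODEL1_COVARIATES,
                       "hypertension", "depression", "hyperlipidemia")

#' Adjustment covariate sets
#'
#' The named covariate sets used throughout: \code{crude} (none),
#' \code{model1} (demographics, socioeconomics and lifestyle), \code{model2}
#' (model1 plus hypertension, depression and hyperlipidemia).
#'
#' @param adjustment one of "crude", "model1", "model2".
#' @return character vector of covariate column names.
#' @export
adjustment_set <- function(adjustment = c("crude", "model1", "model2")) {
  switch(match.arg(adjustment),
         crude = character(),
         model1 = MODEL1_COVARIATES,
         model2 = MODEL2_COVARIATES)
}

#' Odds ratio of a 2x2 table with Wald confidence interval
#'
#' OR = (a d) / (b c); CI = exp(log OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d)).
#'
#' @param a exposed cases.
#' @param b unexposed cases.
#' @param c exposed non-cases.
#' @param d unexposed non-cases.
#' @param continuity add 0.5 to every cell when any cell is zero
#'   (Haldane-Anscombe); off by default.
#' @param conf_level confidence level.
#' @return list: or, ci_low, ci_high, log_or, se.
#' @export
#' @examples
#' two_by_two_or(2186, 3129, 10375, 88864)  # OR 5.98
two_by_two_or <- function(a, b, c, d, continuity = FALSE, conf_level = 0.95) {
  cells <- c(a, b, c, d)
  if (any(cells < 0)) stopf("cell counts must be non-negative")
  if (any(cells == 0)) {
    if (!continuity)
      stopf("zero cell makes the odds ratio undefined; set continuity = TRUE")
    cells <- cells + 0.5
  }
  a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
  log_or <- log(a) + log(d) - log(b) - log(c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(or = exp(log_or), ci_low = exp(log_or - z * se),
       ci_high = exp(log_or + z * se), log_or = log_or, se = se)
}

#' Pearson chi-square test of independence for an R x C count table
#'
#' Pearson statistic without continuity correction; degrees of freedom
#' (R - 1)(C - 1); upper-tail chi-square p-value.
#'
#' @param tab matrix of counts, at least 2 x 2.
#' @return list: statistic, df, p_value.
#' @export
chisq_test_table <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2 || ncol(tab) < 2) stopf("table must be at least 2 x 2")
  if (any(tab < 0)) stopf("counts must be non-negative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stopf("degenerate table: a row or column margin is zero")
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = unname(res$p.value))
}

#' Maximum-likelihood logistic regression fit
#'
#' Binomial GLM fit by iteratively reweighted least squares (tight tolerance,
#' at most 50 iterations), with the covariance taken as the inverse observed
#' information. The design is checked for rank deficiency up front; perfect
#' or quasi-perfect separation (non-convergence, runaway coefficients, or a
#' constant outcome) is flagged rather than raised.
#'
#' @param formula model formula; the response must be binary (0/1, logical,
#'   or a two-level factor).
#' @param data data frame; rows with missing values in any model variable are
#'   dropped (complete-case) and counted.
#' @return object of class \code{logistic_fit}: coefficients, vcov, n_obs,
#'   n_dropped, converged, usable, iterations, and the underlying glm.
#' @export
fit_logistic <- function(formula, data) {
  vars <- all.vars(formula)
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols))
    stopf("columns not found in data: %s", paste(missing_cols, collapse = ", "))
  cc <- stats::complete.cases(data[vars])
  n_dropped <- sum(!cc)
  dat <- droplevels(data[cc, vars, drop = FALSE])

  y <- dat[[vars[1]]]
  if (is.factor(y)) y <- as.integer(y) - 1L
  if (is.logical(y)) y <- as.integer(y)
  if (!all(y %in% c(0, 1))) stopf("outcome must be binary")
  dat[[vars[1]]] <- y

  X <- stats::model.matrix(formula, dat)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stopf("rank-deficient design: collinear terms (%s)",
          paste(colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]], collapse = ", "))

  fit <- stats::glm(formula, data = dat, family = stats::binomial(),
                    control = stats::glm.control(epsilon = 1e-10, maxit = 50))
  # perfect separation: non-convergence, a constant outcome, or a perfect fit
  separated <- !fit$converged || length(unique(y)) < 2 ||
    (fit$deviance < 1e-6 && fit$null.deviance > 1e-6)
  if (separated)
    warnf("possible separation or non-convergence; fit flagged unusable")
  extreme <- names(stats::coef(fit))[abs(stats::coef(fit)) > 15]
  if (!separated && length(extreme))
    warnf("quasi-separated term(s) with extreme coefficients: %s",
          paste(extreme, collapse = ", "))
  structure(list(coefficients = stats::coef(fit), vcov = stats::vcov(fit),
                 n_obs = nrow(dat), n_dropped = n_dropped,
                 converged = fit$converged && !separated,
                 usable = !separated, iterations = fit$iter,
                 formula = formula, glm = fit),
            class = "logistic_fit")
}

#' @export
coef.logistic_fit <- function(object, ...) object$coefficients

#' @export
vcov.logistic_fit <- function(object, ...) object$vcov

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("logistic fit: %s\n", deparse(x$formula)))
  cat(sprintf("  n = %d (%d dropped), %d IRLS iterations, %s\n",
              x$n_obs, x$n_dropped, x$iterations,
              if (x$usable) "converged" else "FLAGGED (separation/non-convergence)"))
  print(round(or_table(x), 4), row.names = FALSE)
  invisible(x)
}

#' @export
summary.logistic_fit <- function(object, ...) {
  or_table(object)
}

#' @export
predict.logistic_fit <- function(object, newdata = NULL,
                                 type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) stats::predict(object$glm, type = type)
  else stats::predict(object$glm, newdata = newdata, type = type)
}

#' Odds-ratio table of a fitted logistic model
#'
#' @param fit a \code{logistic_fit}.
#' @param conf_level confidence level for Wald intervals.
#' @return data frame: term, or, ci_low, ci_high, p (intercept excluded).
#' @export
or_table <- function(fit, conf_level = 0.95) {
  est <- fit$coefficients
  se <- sqrt(diag(fit$vcov))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  out <- data.frame(term = names(est), or = exp(est),
                    ci_low = exp(est - z * se), ci_high = exp(est + z * se),
                    p = 2 * stats::pnorm(-abs(est / se)),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[out$term != "(Intercept)", ]
}

#' Crude and adjusted odds-ratio models for exposure terms
#'
#' Fits, per requested adjustment set, either one model per exposure term or
#' one joint multi-exposure model, and collects Wald odds ratios for the
#' exposure terms.
#'
#' @param cohort analysis data frame (outcome, covariates, exposure columns).
#' @param exposure_terms column names of the exposures (e.g. pollutant slopes
#'   or the PRS quartile factor).
#' @param adjustment subset of c("crude", "model1", "model2").
#' @param multi_exposure if TRUE all exposure terms enter one model
#'   (multi-pollutant mode); otherwise one model per term.
#' @param outcome outcome column name.
#' @return data frame: term, level, or, ci_low, ci_high, p, model.
#' @export
model_suite <- function(cohort, exposure_terms,
                        adjustment = c("crude", "model1", "model2"),
                        multi_exposure = FALSE, outcome = "t2d") {
  adjustment <- match.arg(adjustment, several.ok = TRUE)
  rows <- list()
  groups <- if (multi_exposure) list(exposure_terms) else as.list(exposure_terms)
  for (adj in adjustment) {
    covs <- adjustment_set(adj)
    miss <- setdiff(covs, names(cohort))
    if (length(miss))
      stopf("missing covariate column(s): %s", paste(miss, collapse = ", "))
    for (terms in groups) {
      fml <- stats::reformulate(c(terms, covs), response = outcome)
      fit <- fit_logistic(fml, cohort)
      tab <- or_table(fit)
      for (term in terms) {
        hit <- tab[startsWith(tab$term, term), , drop = FALSE]
        if (nrow(hit) == 0) next
        rows[[length(rows) + 1L]] <- data.frame(
          term = term,
          level = sub(paste0("^", term), "", hit$term),
          or = hit$or, ci_low = hit$ci_low, ci_high = hit$ci_high,
          p = hit$p, model = adj, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
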