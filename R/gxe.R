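# Gene-environment interaction: joint or stratified logistic models of an
# exposure trend by genetic-risk category, additive interaction via the
# relative excess risk due to interaction (RERI) with percentile bootstrap
# confidence intervals, and multiplicative cross-product Wald tests.

#' Relative excess risk due to interaction from model coefficients
#'
#' Standard (Rothman) form:
#' \eqn{RERI = e^{\beta_1+\beta_2+\beta_3} - e^{\beta_1} - e^{\beta_2} + 1},
#' equivalently OR11 - OR10 - OR01 + 1. The \code{"as_printed"} variant drops
#' the \eqn{-e^{\beta_1}} term
#' (\eqn{e^{\beta_1+\beta_2+\beta_3} - e^{\beta_2} + 1}); it is offered because
#' some reports print that three-term expression, and results carry a label
#' saying which variant produced them.
#'
#' @param beta1 exposure main-effect coefficient (log-OR).
#' @param beta2 modifier-category coefficient (log-OR).
#' @param beta3 interaction coefficient (log-OR).
#' @param variant "standard" (default) or "as_printed".
#' @return the RERI value.
#' @export
#' @examples
#' reri_from_coefs(log(2), log(3), 0)  # 6 - 2 - 3 + 1 = 2
reri_from_coefs <- function(beta1, beta2, beta3,
                            variant = c("standard", "as_printed")) {
  variant <- match.arg(variant)
  if (!all(is.finite(c(beta1, beta2, beta3))))
    stopf("coefficients must be finite")
  if (variant == "standard")
    exp(beta1 + beta2 + beta3) - exp(beta1) - exp(beta2) + 1
  else
    exp(beta1 + beta2 + beta3) - exp(beta2) + 1
}

#' Wald test of one model term
#'
#' z = coefficient / sqrt(diagonal covariance entry); two-sided normal p.
#'
#' @param fit a \code{logistic_fit}, \code{gxe_fit}, or glm.
#' @param term coefficient name.
#' @return list: estimate, se, z, p_value.
#' @export
wald_test <- function(fit, term) {
  if (inherits(fit, "gxe_fit")) fit <- fit$fit
  est <- stats::coef(fit); V <- stats::vcov(fit)
  if (!term %in% names(est)) stopf("term '%s' not in the fit", term)
  v <- V[term, term]
  if (!is.finite(v) || v <= 0) stopf("degenerate test: zero variance for '%s'", term)
  z <- unname(est[term]) / sqrt(v)
  list(estimate = unname(est[term]), se = sqrt(v), z = z,
       p_value = 2 * stats::pnorm(-abs(z)))
}

#' Fit the gene-environment interaction model
#'
#' The core model: logistic regression of the outcome on an exposure trend
#' slope, genetic-risk categories, their product terms, and adjustment
#' covariates. In \code{"joint"} mode one model with cross-product terms is
#' fitted and the per-category exposure odds ratio is
#' \eqn{e^{\beta_1 + \beta_3(q)}} (delta-method CI); in \code{"stratified"}
#' mode the exposure model is fitted separately within each category.
#' With \code{exposure_form = "binary"} the exposure is dichotomized at
#' \code{binary_cutoff} (positive slope = worsening air quality) and the
#' modifier at its highest category versus the rest - the contrast under
#' which the generator's implied true RERI is defined.
#'
#' @param data analysis data frame.
#' @param exposure exposure column name (continuous trend slope).
#' @param modifier modifier column name (factor; first level is the
#'   reference, e.g. PRS quartile Q1).
#' @param covariates adjustment covariate names (e.g.
#'   \code{adjustment_set("model1")}).
#' @param outcome binary outcome column name.
#' @param mode "joint" (cross-product model, default) or "stratified".
#' @param exposure_form "linear" (per 1 unit of slope, default) or "binary".
#' @param binary_cutoff cutoff for the binary exposure form.
#' @return object of class \code{gxe_fit}.
#' @export
gxe_fit <- function(data, exposure, modifier = "prs_quartile",
                    covariates = character(), outcome = "t2d",
                    mode = c("joint", "stratified"),
                    exposure_form = c("linear", "binary"),
                    binary_cutoff = 0) {
  mode <- match.arg(mode)
  exposure_form <- match.arg(exposure_form)
  for (col in c(exposure, modifier, outcome, covariates))
    if (!col %in% names(data)) stopf("column '%s' not found", col)

  dat <- data
  if (stats::var(as.numeric(dat[[exposure]]), na.rm = TRUE) == 0)
    stopf("rank-deficient design: exposure '%s' has zero variance", exposure)
  if (exposure_form == "binary") {
    dat$.E <- as.integer(dat[[exposure]] > binary_cutoff)
    mod <- dat[[modifier]]
    lev <- if (is.factor(mod)) levels(mod) else sort(unique(mod))
    dat$.G <- as.integer(mod == lev[length(lev)])
    e_name <- ".E"; m_name <- ".G"
    categories <- "high"
  } else {
    dat$.E <- as.numeric(dat[[exposure]])
    dat[[modifier]] <- as.factor(dat[[modifier]])
    e_name <- ".E"; m_name <- modifier
    categories <- levels(dat[[modifier]])[-1]
  }

  if (mode == "joint") {
    fml <- stats::reformulate(c(paste(e_name, m_name, sep = " * "), covariates),
                              response = outcome)
    fit <- fit_logistic(fml, dat)
    est <- fit$coefficients; V <- fit$vcov
    b1_name <- e_name
    m_names <- if (exposure_form == "binary") ".G" else
      paste0(m_name, categories)
    i_names <- paste0(e_name, ":", m_names)
    # per-category exposure log-OR: beta1 (+ beta3 for non-reference levels)
    per_cat <- lapply(c("<reference>", categories), function(q) {
      if (q == "<reference>") {
        b <- est[b1_name]; v <- V[b1_name, b1_name]
        lab <- if (exposure_form == "binary") "low" else
          levels(dat[[modifier]])[1]
      } else {
        i_nm <- i_names[match(q, categories)]
        b <- est[b1_name] + est[i_nm]
        v <- V[b1_name, b1_name] + V[i_nm, i_nm] + 2 * V[b1_name, i_nm]
        lab <- q
      }
      z <- stats::qnorm(0.975)
      data.frame(category = lab, or = exp(unname(b)),
                 ci_low = exp(unname(b) - z * sqrt(v)),
                 ci_high = exp(unname(b) + z * sqrt(v)),
                 p = 2 * stats::pnorm(-abs(unname(b) / sqrt(v))),
                 stringsAsFactors = FALSE)
    })
    inter <- do.call(rbind, lapply(seq_along(categories), function(k) {
      wt <- wald_test(fit, i_names[k])
      data.frame(category = categories[k], coef = wt$estimate, se = wt$se,
                 z = wt$z, p = wt$p_value, stringsAsFactors = FALSE)
    }))
    obj <- list(mode = mode, exposure = exposure, modifier = modifier,
                covariates = covariates, outcome = outcome,
                exposure_form = exposure_form, binary_cutoff = binary_cutoff,
                fit = fit, data = dat, formula = fml,
                term_names = list(beta1 = b1_name, beta2 = m_names,
                                  beta3 = i_names, categories = categories),
                category_or = do.call(rbind, per_cat),
                interaction_tests = inter)
  } else {
    mod <- as.factor(dat[[m_name]])
    fits <- list(); per_cat <- list()
    for (lev in levels(mod)) {
      sub <- dat[mod == lev, , drop = FALSE]
      if (nrow(sub) == 0 || length(unique(sub[[outcome]])) < 2) {
        warnf("stratum '%s' is empty or outcome-degenerate; skipped", lev)
        next
      }
      f <- fit_logistic(stats::reformulate(c(e_name, covariates),
                                           response = outcome), sub)
      fits[[lev]] <- f
      tab <- or_table(f)
      hit <- tab[tab$term == e_name, ]
      per_cat[[lev]] <- data.frame(category = lev, or = hit$or,
                                   ci_low = hit$ci_low, ci_high = hit$ci_high,
                                   p = hit$p, stringsAsFactors = FALSE)
    }
    obj <- list(mode = mode, exposure = exposure, modifier = modifier,
                covariates = covariates, outcome = outcome,
                exposure_form = exposure_form, binary_cutoff = binary_cutoff,
                fit = fits, data = dat,
                category_or = do.call(rbind, per_cat),
                interaction_tests = NULL)
  }
  class(obj) <- "gxe_fit"
  obj
}

#' @export
print.gxe_fit <- function(x, ...) {
  cat(sprintf("gene-environment interaction fit (%s mode, %s exposure)\n",
              x$mode, x$exposure_form))
  cat(sprintf("  outcome %s ~ %s x %s%s\n", x$outcome, x$exposure, x$modifier,
              if (length(x$covariates))
                paste0(" + ", length(x$covariates), " covariates") else ""))
  cat("per-category exposure odds ratios:\n")
  print(cbind(x$category_or[1],
              round(x$category_or[-1], 4)), row.names = FALSE)
  if (!is.null(x$interaction_tests)) {
    cat("multiplicative interaction (cross-product Wald tests):\n")
    print(cbind(x$interaction_tests[1],
                round(x$interaction_tests[-1], 4)), row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.gxe_fit <- function(object, ...) {
  list(category_or = object$category_or,
       interaction_tests = object$interaction_tests,
       model = if (object$mode == "joint") summary(object$fit) else
         lapply(object$fit, summary))
}

#' @export
coef.gxe_fit <- function(object, ...) {
  if (object$mode == "joint") stats::coef(object$fit)
  else lapply(object$fit, stats::coef)
}

#' @export
vcov.gxe_fit <- function(object, ...) {
  if (object$mode == "joint") stats::vcov(object$fit)
  else lapply(object$fit, stats::vcov)
}

#' @export
predict.gxe_fit <- function(object, newdata = NULL, ...) {
  if (object$mode != "joint")
    stopf("predict is only available for joint-mode fits")
  if (!is.null(newdata)) {
    newdata$.E <- if (object$exposure_form == "binary")
      as.integer(newdata[[object$exposure]] > object$binary_cutoff)
    else as.numeric(newdata[[object$exposure]])
  }
  predict(object$fit, newdata = newdata, ...)
}

#' @export
confint.gxe_fit <- function(object, parm, level = 0.95, ...) {
  fit <- if (object$mode == "joint") list(object$fit) else object$fit
  do.call(rbind, lapply(fit, function(f) {
    est <- stats::coef(f); se <- sqrt(diag(stats::vcov(f)))
    z <- stats::qnorm(1 - (1 - level) / 2)
    cbind(lower = est - z * se, upper = est + z * se)
  }))
}

# RERI point estimates per non-reference category from a joint fit's
# coefficient vector (names resolved through the fit's term map).
.reri_points <- function(est, tn, variant) {
  vapply(seq_along(tn$categories), function(k) {
    b1 <- est[tn$beta1]; b2 <- est[tn$beta2[k]]; b3 <- est[tn$beta3[k]]
    if (anyNA(c(b1, b2, b3))) return(NA_real_)
    reri_from_coefs(unname(b1), unname(b2), unname(b3), variant)
  }, numeric(1))
}

#' Generic for additive-interaction estimates
#' @param object a fitted model object.
#' @param ... passed to methods.
#' @export
reri <- function(object, ...) UseMethod("reri")

#' RERI with percentile bootstrap confidence intervals
#'
#' Point estimates come from the original joint fit; confidence intervals are
#' the 2.5th/97.5th percentiles of the RERI recomputed over bootstrap
#' resamples of individuals (same n, with replacement, full model refitted
#' each time). Non-converged or rank-deficient refits are dropped and
#' counted; results are flagged unreliable when more than
#' \code{max_fail_rate} of refits failed.
#'
#' @param object a joint-mode \code{\link{gxe_fit}}.
#' @param n_boot number of bootstrap resamples (1000 by default).
#' @param seed RNG seed controlling the full resampling stream.
#' @param variant RERI formula variant, see \code{\link{reri_from_coefs}}.
#' @param conf_level confidence level.
#' @param max_fail_rate failed-refit proportion above which results are
#'   flagged.
#' @param ... unused.
#' @return data frame of class \code{reri_result}: category, estimate,
#'   ci_low, ci_high, n_boot, n_failed, variant, unreliable.
#' @export
reri.gxe_fit <- function(object, n_boot = 1000, seed = NULL,
                         variant = c("standard", "as_printed"),
                         conf_level = 0.95, max_fail_rate = 0.05, ...) {
  variant <- match.arg(variant)
  if (object$mode != "joint")
    stopf("RERI needs the joint cross-product model (mode = 'joint')")
  if (!object$fit$usable)
    stopf("base model did not converge; RERI unavailable")
  tn <- object$term_names
  point <- .reri_points(object$fit$coefficients, tn, variant)

  X <- stats::model.matrix(object$fit$glm)
  y <- object$fit$glm$y
  n <- nrow(X)
  cn <- colnames(X)
  if (!is.null(seed)) set.seed(seed)
  draws <- matrix(NA_real_, n_boot, length(tn$categories))
  n_failed <- 0L
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    fb <- tryCatch(
      suppressWarnings(stats::glm.fit(X[idx, , drop = FALSE], y[idx],
                                      family = stats::binomial(),
                                      control = stats::glm.control(maxit = 50))),
      error = function(e) NULL)
    ok <- !is.null(fb) && fb$converged && !anyNA(stats::coef(fb)) &&
      all(abs(stats::coef(fb)[c(tn$beta1, tn$beta2, tn$beta3)]) < 15)
    if (!ok) { n_failed <- n_failed + 1L; next }
    draws[b, ] <- .reri_points(stats::setNames(stats::coef(fb), cn), tn, variant)
  }
  if (n_failed == n_boot) stopf("all bootstrap refits failed")
  alpha <- (1 - conf_level) / 2
  ci <- t(apply(draws, 2, function(col)
    stats::quantile(col, c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)))
  out <- data.frame(category = tn$categories, estimate = point,
                    ci_low = ci[, 1], ci_high = ci[, 2],
                    n_boot = n_boot, n_failed = n_failed, variant = variant,
                    unreliable = n_failed / n_boot > max_fail_rate,
                    stringsAsFactors = FALSE)
  if (any(out$unreliable))
    warnf("%d of %d bootstrap refits failed; RERI flagged unreliable",
          n_failed, n_boot)
  class(out) <- c("reri_result", "data.frame")
  out
}

#' @export
print.reri_result <- function(x, ...) {
  cat(sprintf("RERI (%s form), percentile bootstrap CI over %d resamples (%d failed)\n",
              x$variant[1], x$n_boot[1], x$n_failed[1]))
  df <- data.frame(category = x$category, reri = round(x$estimate, 4),
                   ci_low = round(x$ci_low, 4), ci_high = round(x$ci_high, 4))
  print(df, row.names = FALSE)
  invisible(x)
}
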