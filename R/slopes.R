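# Per-participant exposure-trend metrics: ordinary least-squares slope of
# annual pollutant concentration on time, plus descriptive summaries.

#' Fit the annual trend slope of one concentration series
#'
#' Ordinary least squares of concentration on time, with time recoded so the
#' earliest year is 0 (each later year keeps its calendar offset, so the slope
#' is in concentration units per year and the intercept is the fitted
#' concentration at the window start). A positive slope means worsening air
#' quality.
#'
#' @param year calendar years (>= 2 distinct values).
#' @param concentration concentrations (micrograms/m3), same length.
#' @param baseline how to report the baseline concentration:
#'   \code{"index_year"} (observed value in the latest year, the default) or
#'   \code{"fitted_start"} (fitted value at the window start, i.e. the
#'   intercept).
#' @return list of class \code{slope_fit}: \code{beta0} (intercept),
#'   \code{beta1} (slope), \code{n_years}, \code{baseline}.
#' @export
#' @examples
#' fit_slope(2008:2012, c(26.7, 25.0, 24.1, 22.9, 21.5))
fit_slope <- function(year, concentration,
                      baseline = c("index_year", "fitted_start")) {
  baseline <- match.arg(baseline)
  ok <- is.finite(year) & is.finite(concentration)
  year <- year[ok]; concentration <- concentration[ok]
  if (length(year) < 2) stopf("insufficient data: need at least 2 yearly values")
  if (length(unique(year)) < 2)
    stopf("degenerate design: all observations share one year")
  t <- year - min(year)
  tbar <- mean(t); ybar <- mean(concentration)
  beta1 <- sum((t - tbar) * (concentration - ybar)) / sum((t - tbar)^2)
  beta0 <- ybar - beta1 * tbar
  base <- if (baseline == "index_year")
    concentration[which.max(year)] else beta0
  structure(list(beta0 = beta0, beta1 = beta1,
                 n_years = length(unique(year)), baseline = base),
            class = "slope_fit")
}

#' @export
print.slope_fit <- function(x, ...) {
  cat(sprintf("trend slope %.4f per year (intercept %.4f, %d years, baseline %.4f)\n",
              x$beta1, x$beta0, x$n_years, x$baseline))
  invisible(x)
}

#' Trend slopes for every participant and pollutant in an exposure panel
#'
#' Vectorized closed-form OLS per (participant, pollutant) group. Groups with
#' fewer than two distinct years are skipped and reported in the
#' \code{"skipped"} attribute with a reason.
#'
#' @param panel long data frame with columns participant_id, pollutant, year,
#'   concentration.
#' @param baseline as in \code{\link{fit_slope}}.
#' @return data frame: participant_id, pollutant, beta0, beta1, n_years,
#'   baseline; attribute \code{skipped} lists excluded groups.
#' @export
slope_table <- function(panel, baseline = c("index_year", "fitted_start")) {
  baseline <- match.arg(baseline)
  need <- c("participant_id", "pollutant", "year", "concentration")
  if (!all(need %in% names(panel)))
    stopf("panel must have columns %s", paste(need, collapse = ", "))
  if (nrow(panel) == 0) {
    warnf("empty exposure panel; returning an empty slope table")
    out <- data.frame(participant_id = character(), pollutant = character(),
                      beta0 = numeric(), beta1 = numeric(),
                      n_years = integer(), baseline = numeric())
    attr(out, "skipped") <- data.frame(participant_id = character(),
                                       pollutant = character(),
                                       reason = character())
    return(out)
  }
  panel <- panel[is.finite(panel$year) & is.finite(panel$concentration), ]
  g <- paste(panel$participant_id, panel$pollutant, sep = "\r")
  gi <- factor(g, levels = unique(g))
  gc <- as.integer(gi)  # rowsum sorts groups; integer codes keep level order
  tmin <- stats::ave(panel$year, gc, FUN = min)
  t <- panel$year - tmin
  y <- panel$concentration
  ones <- rep(1, nrow(panel))
  n_g <- as.vector(rowsum(ones, gc))
  St <- as.vector(rowsum(t, gc)); Sy <- as.vector(rowsum(y, gc))
  Stt <- as.vector(rowsum(t * t, gc)); Sty <- as.vector(rowsum(t * y, gc))
  sxx <- Stt - St^2 / n_g
  beta1 <- (Sty - St * Sy / n_g) / sxx
  beta0 <- Sy / n_g - beta1 * St / n_g
  ny <- as.vector(rowsum(as.numeric(!duplicated(paste(g, panel$year))), gc))

  # baseline: observed concentration at the latest year of each group
  ord <- order(gc, panel$year)
  last <- ord[!duplicated(gi[ord], fromLast = TRUE)]
  base <- if (baseline == "index_year") y[last] else beta0

  keys <- do.call(rbind, strsplit(levels(gi), "\r", fixed = TRUE))
  out <- data.frame(participant_id = keys[, 1], pollutant = keys[, 2],
                    beta0 = beta0, beta1 = beta1, n_years = as.integer(ny),
                    baseline = base, stringsAsFactors = FALSE)
  bad <- out$n_years < 2 | !is.finite(out$beta1)
  skipped <- data.frame(participant_id = out$participant_id[bad],
                        pollutant = out$pollutant[bad],
                        reason = ifelse(out$n_years[bad] < 2,
                                        "fewer than 2 distinct years",
                                        "degenerate time design"),
                        stringsAsFactors = FALSE)
  out <- out[!bad, ]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Reshape a slope table to one row per participant
#'
#' @param slopes output of \code{\link{slope_table}}.
#' @return data frame: participant_id plus \code{<pollutant>_slope} and
#'   \code{<pollutant>_baseline} columns.
#' @export
slope_wide <- function(slopes) {
  ids <- unique(slopes$participant_id)
  out <- data.frame(participant_id = ids, stringsAsFactors = FALSE)
  for (pol in unique(slopes$pollutant)) {
    sub <- slopes[slopes$pollutant == pol, ]
    i <- match(ids, sub$participant_id)
    out[[paste0(pol, "_slope")]] <- sub$beta1[i]
    out[[paste0(pol, "_baseline")]] <- sub$baseline[i]
  }
  out
}

#' Descriptive summary of a numeric vector
#'
#' Mean, SD (n - 1 denominator), median, min, max, quartiles (linear
#' interpolation between order statistics, \code{stats::quantile} type 7) and
#' IQR.
#'
#' @param x non-empty numeric vector (NAs dropped).
#' @return named numeric vector: mean, sd, median, min, max, q1, q3, iqr.
#' @export
describe_values <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0) stopf("insufficient data: no finite values to summarize")
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  c(mean = mean(x), sd = if (length(x) > 1) stats::sd(x) else 0,
    median = q[2], min = min(x), max = max(x),
    q1 = q[1], q3 = q[3], iqr = q[3] - q[1])
}

#' Baseline and slope descriptives per pollutant
#'
#' The descriptive table of the exposure metrics: one row per pollutant and
#' metric (baseline concentration, trend slope) with the
#' \code{\link{describe_values}} statistics as columns.
#'
#' @param slopes output of \code{\link{slope_table}}.
#' @return data frame: pollutant, metric, mean, sd, median, min, max, q1, q3,
#'   iqr.
#' @export
exposure_summary <- function(slopes) {
  rows <- list()
  for (pol in unique(slopes$pollutant)) {
    sub <- slopes[slopes$pollutant == pol, ]
    for (metric in c("baseline", "slope")) {
      vals <- if (metric == "baseline") sub$baseline else sub$beta1
      rows[[length(rows) + 1L]] <- data.frame(
        pollutant = pol, metric = metric,
        t(describe_values(vals)), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
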