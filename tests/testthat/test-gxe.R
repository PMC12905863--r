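test_that("RERI arithmetic is exact in both formula variants", {
  expect_equal(reri_from_coefs(0, 0, 0, "standard"), 0)
  expect_equal(reri_from_coefs(0, 0, 0, "as_printed"), 1)
  expect_equal(reri_from_coefs(log(2), log(3), 0, "standard"), 2)
  expect_equal(reri_from_coefs(log(2), log(3), 0, "as_printed"), 4)
  expect_error(reri_from_coefs(Inf, 0, 0), "finite")
  # strictly increasing in the interaction coefficient
  b3 <- seq(-0.5, 0.5, length.out = 11)
  for (v in c("standard", "as_printed")) {
    vals <- vapply(b3, function(b) reri_from_coefs(0.2, 0.4, b, v), numeric(1))
    expect_true(all(diff(vals) > 0))
  }
})

test_that("Wald tests match the normal-CDF oracle", {
  fake <- structure(list(coefficients = c(a = 1.959964, b = 0),
                         vcov = diag(2) |>
                           `dimnames<-`(list(c("a", "b"), c("a", "b")))),
                    class = "logistic_fit")
  expect_equal(wald_test(fake, "a")$p_value, 0.05, tolerance = 1e-6)
  expect_equal(wald_test(fake, "b")$z, 0)
  expect_equal(wald_test(fake, "b")$p_value, 1)
  set.seed(18)
  dat <- data.frame(y = stats::rbinom(300, 1, 0.4), x = stats::rnorm(300))
  fit <- fit_logistic(y ~ x, dat)
  wt <- wald_test(fit, "x")
  z <- unname(coef(fit)["x"] / sqrt(vcov(fit)["x", "x"]))
  expect_equal(wt$p_value, 2 * stats::pnorm(-abs(z)), tolerance = 1e-10)
  expect_error(wald_test(fit, "nope"), "not in the fit")
})

test_that("the standard RERI equals the cell-odds identity on a saturated fit", {
  set.seed(19)
  n <- 4000
  g <- stats::rbinom(n, 1, 0.3)
  e <- stats::rbinom(n, 1, 0.4)
  p <- stats::plogis(-2 + 0.5 * e + 0.7 * g + 0.3 * e * g)
  dat <- data.frame(t2d = stats::rbinom(n, 1, p), slope = e - 0.5,
                    grp = factor(ifelse(g == 1, "hi", "lo"),
                                 levels = c("lo", "hi")))
  fit <- gxe_fit(dat, exposure = "slope", modifier = "grp",
                 exposure_form = "binary", binary_cutoff = 0)
  cf <- coef(fit)
  r <- reri_from_coefs(cf[".E"], cf[".G"], cf[".E:.G"])
  # empirical cell odds: the saturated MLE reproduces them exactly
  odds <- function(ee, gg) {
    m <- mean(dat$t2d[e == ee & g == gg])
    m / (1 - m)
  }
  o00 <- odds(0, 0)
  expect_equal(unname(r),
               odds(1, 1) / o00 - odds(1, 0) / o00 - odds(0, 1) / o00 + 1,
               tolerance = 1e-6)
})

test_that("joint and stratified per-category ORs coincide without covariates", {
  set.seed(20)
  n <- 3000
  q <- factor(sample(paste0("Q", 1:4), n, replace = TRUE),
              levels = paste0("Q", 1:4))
  slope <- stats::rnorm(n)
  p <- stats::plogis(-2.5 + 0.05 * slope + 0.1 * (as.integer(q) - 1) +
                       0.06 * slope * (as.integer(q) - 1))
  dat <- data.frame(t2d = stats::rbinom(n, 1, p), pm25_slope = slope,
                    prs_quartile = q)
  joint <- gxe_fit(dat, "pm25_slope", mode = "joint")
  strat <- gxe_fit(dat, "pm25_slope", mode = "stratified")
  expect_equal(joint$category_or$or, strat$category_or$or, tolerance = 1e-6)
  expect_equal(joint$category_or$ci_low, strat$category_or$ci_low,
               tolerance = 1e-4)
  # degenerate exposure is rejected
  dat0 <- dat; dat0$pm25_slope <- 1
  expect_error(gxe_fit(dat0, "pm25_slope"), "zero variance")
})

test_that("the RERI bootstrap is seed-deterministic with ordered intervals", {
  set.seed(21)
  n <- 2500
  q <- factor(sample(paste0("Q", 1:4), n, replace = TRUE),
              levels = paste0("Q", 1:4))
  slope <- stats::rnorm(n)
  p <- stats::plogis(-2.2 + 0.08 * slope + 0.15 * (q == "Q4") +
                       0.1 * slope * (q == "Q4"))
  dat <- data.frame(t2d = stats::rbinom(n, 1, p), pm25_slope = slope,
                    prs_quartile = q)
  fit <- gxe_fit(dat, "pm25_slope")
  r1 <- reri(fit, n_boot = 80, seed = 7)
  r2 <- reri(fit, n_boot = 80, seed = 7)
  expect_identical(r1, r2)
  expect_equal(r1$category, c("Q2", "Q3", "Q4"))
  expect_true(all(r1$ci_low <= r1$ci_high))
  expect_true(all(r1$ci_low <= r1$estimate & r1$estimate <= r1$ci_high))
  expect_true(all(r1$n_failed / r1$n_boot <= 0.05))
  r3 <- reri(fit, n_boot = 80, seed = 8)
  expect_false(identical(r1$ci_low, r3$ci_low))
  # the printed-formula variant shifts estimates by exp(beta1) - ... + terms
  r_printed <- reri(fit, n_boot = 40, seed = 7, variant = "as_printed")
  cf <- coef(fit)
  expect_equal(r_printed$estimate[3],
               reri_from_coefs(cf[".E"], cf["prs_quartileQ4"],
                               cf[".E:prs_quartileQ4"], "as_printed"),
               ignore_attr = TRUE)
})

test_that("bootstrap interval width shrinks with sample size", {
  make <- function(n, seed) {
    set.seed(seed)
    q <- factor(sample(paste0("Q", 1:4), n, replace = TRUE),
                levels = paste0("Q", 1:4))
    slope <- stats::rnorm(n)
    p <- stats::plogis(-2.2 + 0.05 * slope + 0.1 * (q == "Q4"))
    data.frame(t2d = stats::rbinom(n, 1, p), pm25_slope = slope,
               prs_quartile = q)
  }
  w <- vapply(c(1500, 12000), function(n) {
    fit <- gxe_fit(make(n, 22), "pm25_slope")
    r <- reri(fit, n_boot = 60, seed = 5)
    mean(r$ci_high - r$ci_low)
  }, numeric(1))
  expect_lt(w[2], w[1])
})

test_that("stratified mode skips outcome-degenerate strata with a warning", {
  set.seed(23)
  n <- 400
  q <- factor(rep(c("Q1", "Q2"), each = n / 2), levels = c("Q1", "Q2"))
  dat <- data.frame(t2d = c(stats::rbinom(n / 2, 1, 0.3), rep(0, n / 2)),
                    pm25_slope = stats::rnorm(n), prs_quartile = q)
  expect_warning(fit <- gxe_fit(dat, "pm25_slope", mode = "stratified"),
                 "degenerate|skipped")
  expect_equal(fit$category_or$category, "Q1")
})
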