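# The log transform linearises exp growth exactly: a noise-free series
# y = exp(a + b t) - 1 must give back slope b with ~zero residuals.
test_that("Gaussian ln(x+1) fit recovers an exact exponential trend", {
  t <- 0:29
  s <- population_series("s", "t", 1990 + t, exp(1 + 0.1 * t) - 1)
  fits <- fit_candidates(s, families = "gaussian_ln", degrees = 1L)
  f <- fits[[1L]]
  expect_equal(f$b1, 0.1, tolerance = 1e-10)
  expect_lt(max(abs(residuals(f$model))), 1e-10)
})

test_that("a constant series yields no trend in any family", {
  s <- population_series("s", "t", 1990:2014, rep(5, 25))
  fits <- suppressWarnings(fit_candidates(s))
  for (f in fits) {
    if (!isTRUE(f$converged)) next
    expect_lt(abs(f$b1), 1e-8)
    expect_true(is.na(f$slope_p) || f$slope_p > 0.05)
  }
  expect_equal(suppressWarnings(classify_trend(s))$trend_type, "neutral")
})

test_that("Poisson degree-1 slope is recovered within 2 SE almost always", {
  set.seed(101)
  n_rep <- 200L
  hit <- 0L
  for (r in seq_len(n_rep)) {
    t <- 0:29
    y <- rpois(30, exp(1 + 0.05 * t))
    s <- population_series("s", "t", 1990 + t, y)
    f <- fit_candidates(s, families = "poisson", degrees = 1L)[[1L]]
    se <- coef(summary(f$model))[2L, 2L]
    if (abs(f$b1 - 0.05) <= 2 * se) hit <- hit + 1L
  }
  expect_gte(hit / n_rep, 0.93)
})

test_that("normality flag is calibrated on truly Gaussian residuals", {
  set.seed(102)
  n_rep <- 300L
  ok <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    t <- 0:29
    s <- population_series("s", "t", 1990 + t,
                           exp(2 + 0.05 * t + rnorm(30, 0, 0.3)) - 1)
    f <- check_assumptions(
      fit_candidates(s, families = "gaussian_ln", degrees = 1L)[[1L]])
    ok[r] <- isTRUE(f$normality_ok) || is.na(f$normality_ok)
  }
  # nominal pass rate 95%; allow ~3 binomial SE
  expect_gt(mean(ok), 0.91)
  expect_lt(mean(ok), 0.99)
})

test_that("overdispersed counts trip the Poisson dispersion flag", {
  set.seed(103)
  n_rep <- 100L
  flagged <- 0L
  for (r in seq_len(n_rep)) {
    t <- 0:29
    y <- rnbinom(30, size = 0.2, mu = exp(2 + 0.03 * t))  # dispersion ~ 5x
    s <- population_series("s", "t", 1990 + t, y)
    f <- suppressWarnings(check_assumptions(
      fit_candidates(s, families = "poisson", degrees = 1L)[[1L]]))
    if (identical(f$overdispersion_ok, FALSE)) flagged <- flagged + 1L
  }
  expect_gte(flagged / n_rep, 0.90)
})

make_fit <- function(family, degree, aic, slope_p = 0.01, valid = TRUE,
                     b1 = 1, b2 = -0.1) {
  structure(list(family = family, degree = degree, aic = aic,
                 slope_p = slope_p, valid = valid, converged = TRUE,
                 b1 = b1, b2 = if (degree == 2L) b2 else NA_real_),
            class = "candidate_fit")
}

test_that("model selection prefers low AIC, then parsimony on ties", {
  lin <- make_fit("gaussian_ln", 1L, 100)
  qua <- make_fit("gaussian_ln", 2L, 104)
  expect_identical(select_model(list(qua, lin))$degree, 1L)
  expect_identical(select_model(list(lin, make_fit("poisson", 1L, 90)))$family,
                   "poisson")
  # exact tie: lower degree, then family order gaussian < poisson < negbin
  expect_identical(select_model(list(make_fit("negbin", 1L, 100),
                                     make_fit("gaussian_ln", 1L, 100)))$family,
                   "gaussian_ln")
  expect_identical(select_model(list(make_fit("gaussian_ln", 2L, 100),
                                     make_fit("poisson", 1L, 100)))$degree, 1L)
  # two numerically -Inf AICs (perfect fits) tie-break the same way
  expect_identical(select_model(list(make_fit("gaussian_ln", 2L, -Inf),
                                     make_fit("gaussian_ln", 1L, -Inf)))$degree,
                   1L)
  # no significant or no valid fit -> NULL -> neutral
  expect_null(select_model(list(make_fit("gaussian_ln", 1L, 100,
                                         slope_p = 0.4))))
  expect_null(select_model(list(make_fit("gaussian_ln", 1L, 100,
                                         valid = FALSE))))
})

test_that("MOS test locates the vertex analytically and gates on range", {
  t <- 0:30
  s <- population_series("s", "t", 1980 + t,
                         exp(3 + 0.12 * t - 0.004 * t^2) - 1)  # vertex at 15
  f <- fit_candidates(s, families = "gaussian_ln", degrees = 2L)[[1L]]
  mos <- mos_test(f, s)
  expect_true(mos$is_unimodal)
  expect_equal(mos$mode_year, 1995, tolerance = 1e-9)

  # vertex outside the observed range
  s2 <- population_series("s", "t", 1980 + t,
                          exp(1 + 0.32 * t - 0.004 * t^2) - 1)  # vertex at 40
  f2 <- fit_candidates(s2, families = "gaussian_ln", degrees = 2L)[[1L]]
  expect_false(mos_test(f2, s2)$is_unimodal)

  # same-sign coefficients are never unimodal
  s3 <- population_series("s", "t", 1980 + t, exp(1 + 0.01 * t + 0.002 * t^2) - 1)
  f3 <- fit_candidates(s3, families = "gaussian_ln", degrees = 2L)[[1L]]
  expect_false(mos_test(f3, s3)$is_unimodal)
})

test_that("MOS test agrees with the vegan implementation on noisy data", {
  skip_if_not_installed("vegan")
  set.seed(104)
  agree <- 0L
  n_rep <- 30L
  for (r in seq_len(n_rep)) {
    t <- 0:30
    z <- 3 + 0.12 * t - 0.004 * t^2 + rnorm(31, 0, 0.25)
    s <- population_series("s", "t", 1980 + t, pmax(exp(z) - 1, 0))
    f <- fit_candidates(s, families = "gaussian_ln", degrees = 2L)[[1L]]
    ours <- mos_test(f, s)
    vg <- vegan::MOStest(t, log1p(s$values))
    # vegan: hump bracketed and both endpoint F-tests significant
    theirs <- vg$isHump && vg$isBracketed &&
      all(vg$coefficients[["Pr(>F)"]][1:2] < 0.05)
    if (identical(ours$is_unimodal, theirs)) agree <- agree + 1L
  }
  expect_gte(agree / n_rep, 0.9)
})

test_that("classification is invariant to year recentring and scaling", {
  set.seed(105)
  t <- 0:30
  z <- 5 + 0.08 * t + rnorm(31, 0, 0.2)
  y <- exp(z)  # large magnitude: ln(x+1) ~ ln(x)
  base <- suppressWarnings(classify_trend(
    population_series("s", "t", 1950 + t, y), families = "gaussian_ln"))
  shifted <- suppressWarnings(classify_trend(
    population_series("s", "t", 2000 + t, y), families = "gaussian_ln"))
  scaled <- suppressWarnings(classify_trend(
    population_series("s", "t", 1950 + t, 1000 * y),
    families = "gaussian_ln"))
  expect_identical(base$trend_type, "positive_linear")
  expect_identical(shifted$trend_type, base$trend_type)
  expect_identical(scaled$trend_type, base$trend_type)
})

test_that("quadratic series too short for degree 2 are skipped with reason", {
  s <- population_series("s", "t", c(1990L, 1991L, 1992L), c(1, 2, 3))
  fits <- suppressWarnings(fit_candidates(s, families = "gaussian_ln"))
  deg2 <- Filter(function(f) f$degree == 2L, fits)[[1L]]
  expect_false(deg2$converged)
  expect_match(deg2$skip_reason, "distinct years")
})
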