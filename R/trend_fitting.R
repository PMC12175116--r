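#' @title Candidate trend models for one population
#' @description
#' Fits up to six regressions of abundance on year: three error families
#' (Gaussian on `ln(x+1)`-transformed abundance; Poisson and negative
#' binomial on abundance rounded to the nearest integer) crossed with two
#' polynomial degrees (linear, quadratic). Years are centred on the first
#' observed year before fitting; trend classification depends only on signs
#' and significance, which the centring leaves untouched.
#'
#' Each candidate records its coefficients, the Wald p-value of its trend
#' term (the linear term for degree 1, the quadratic term for degree 2), its
#' AIC, and — after [check_assumptions()] — its residual-diagnostic flags.
#'
#' @param series a [population_series()] that passed [inclusion_filter()].
#' @param families subset of `c("gaussian_ln", "poisson", "negbin")`.
#' @param degrees subset of `c(1, 2)`.
#' @param jacobian if `TRUE` (default) the Gaussian AIC is mapped to the
#'   original abundance scale by adding the log-Jacobian of the `ln(x+1)`
#'   transform (`2 * sum(log(x + 1))`), so AIC is comparable across response
#'   scales; `FALSE` compares raw AICs.
#' @return a list of `candidate_fit` objects (skipped candidates carry a
#'   `skip_reason`).
#' @export
fit_candidates <- function(series,
                           families = c("gaussian_ln", "poisson", "negbin"),
                           degrees = c(1L, 2L), jacobian = TRUE) {
  t <- series$years - series$years[1L]
  y <- series$values
  z <- log1p(y)
  yc <- round(y)
  ndist <- length(unique(t))
  fits <- list()
  for (fam in families) for (deg in degrees) {
    need <- if (deg == 1L) 3L else 4L
    if (ndist < need) {
      fits[[length(fits) + 1L]] <- structure(
        list(family = fam, degree = deg, converged = FALSE,
             skip_reason = sprintf("<%d distinct years", need)),
        class = "candidate_fit")
      next
    }
    fits[[length(fits) + 1L]] <- fit_one_candidate(fam, deg, t, y, z, yc,
                                                  jacobian)
  }
  fits
}

# Scale below which a coefficient is numerically zero: on noise-free series
# the residual variance underflows and Wald statistics of ~1e-17 terms are
# arbitrary O(1) numbers, so such terms must not register as trends.
coef_zero_scale <- function(cf, response) {
  1e-10 * max(abs(cf), sd(response), 1e-8, na.rm = TRUE)
}

extract_candidate <- function(model, fam, deg, t, response, aic_shift) {
  sm <- suppressWarnings(summary(model))
  cf <- coef(sm)
  # coefficient table rows: (Intercept), t, [I(t^2)]
  get <- function(row, col) if (row <= nrow(cf)) cf[row, col] else NA_real_
  b0 <- get(1L, 1L); b1 <- get(2L, 1L); b2 <- if (deg == 2L) get(3L, 1L) else NA_real_
  se1 <- get(2L, 2L); se2 <- if (deg == 2L) get(3L, 2L) else NA_real_
  p1 <- get(2L, 4L); p2 <- if (deg == 2L) get(3L, 4L) else NA_real_
  zero <- coef_zero_scale(c(b0, b1, b2), response)
  if (!is.na(b1) && abs(b1) < zero) p1 <- NA_real_
  if (!is.na(b2) && abs(b2) < zero) p2 <- NA_real_
  slope_p <- if (deg == 1L) p1 else p2
  if (!is.na(slope_p) && is.nan(slope_p)) slope_p <- NA_real_
  structure(list(family = fam, degree = deg,
                 b0 = b0, b1 = b1, b2 = b2, se_b1 = se1, se_b2 = se2,
                 slope_p = slope_p, p_b1 = p1, p_b2 = p2,
                 aic = AIC(model) + aic_shift, aic_raw = AIC(model),
                 converged = TRUE, model = model, t = t,
                 normality_ok = NA, homoscedasticity_ok = NA,
                 overdispersion_ok = NA, valid = NA),
            class = "candidate_fit")
}

fit_one_candidate <- function(fam, deg, t, y, z, yc, jacobian) {
  fml <- if (deg == 1L) resp ~ t else resp ~ t + I(t^2)
  fail <- function(msg) structure(
    list(family = fam, degree = deg, converged = FALSE, skip_reason = msg),
    class = "candidate_fit")
  if (fam == "gaussian_ln") {
    d <- data.frame(resp = z, t = t)
    m <- tryCatch(lm(fml, data = d), error = function(e) NULL)
    if (is.null(m)) return(fail("lm failed"))
    shift <- if (jacobian) 2 * sum(log1p(y)) else 0
    return(extract_candidate(m, fam, deg, t, z, shift))
  }
  d <- data.frame(resp = yc, t = t)
  if (fam == "poisson") {
    m <- tryCatch(suppressWarnings(glm(fml, data = d, family = poisson())),
                  error = function(e) NULL)
    if (is.null(m) || !m$converged) return(fail("poisson glm failed"))
    return(extract_candidate(m, fam, deg, t, log1p(yc), 0))
  }
  # negative binomial: ML theta, falling back to method-of-moments
  m <- tryCatch(suppressWarnings(MASS::glm.nb(fml, data = d)),
                error = function(e) NULL)
  if (is.null(m)) {
    pm <- tryCatch(suppressWarnings(glm(fml, data = d, family = poisson())),
                   error = function(e) NULL)
    if (is.null(pm)) return(fail("negbin and poisson fallback failed"))
    mu <- fitted(pm)
    excess <- sum((yc - mu)^2 - mu)
    theta <- if (excess > 0) sum(mu^2) / excess else 1e6
    theta <- min(max(theta, 1e-3), 1e6)
    m <- tryCatch(suppressWarnings(
      glm(fml, data = d, family = MASS::negative.binomial(theta))),
      error = function(e) NULL)
    if (is.null(m)) return(fail("negbin fallback failed"))
    out <- extract_candidate(m, fam, deg, t, log1p(yc), 2)  # +2: theta counted
    out$theta <- theta
    out$theta_method <- "moments"
    return(out)
  }
  out <- extract_candidate(m, fam, deg, t, log1p(yc), 0)
  out$theta <- m$theta
  out$theta_method <- "ml"
  out
}

#' Residual-assumption checks for a candidate fit
#'
#' Gaussian and Poisson fits are tested for normality of residuals
#' (Shapiro-Wilk) and homoscedasticity (Breusch-Pagan; for Poisson an
#' auxiliary regression of squared Pearson residuals on the predictors);
#' Poisson fits are additionally tested for overdispersion (Pearson
#' dispersion statistic against chi-squared). Negative binomial fits carry no
#' applicable flags beyond convergence. Degenerate residuals (all equal, as
#' on noise-free series) make a test inapplicable and count as a pass. A fit
#' is `valid` when every applicable flag passes.
#'
#' @param fit a `candidate_fit` from [fit_candidates()].
#' @param alpha significance level for all diagnostic tests (default 0.05).
#' @return the fit with `normality_ok`, `homoscedasticity_ok`,
#'   `overdispersion_ok` and `valid` filled in.
#' @export
check_assumptions <- function(fit, alpha = 0.05) {
  if (!isTRUE(fit$converged)) {
    fit$valid <- FALSE
    return(fit)
  }
  m <- fit$model
  # numerically exact fit: residuals are floating-point noise, diagnostics
  # are inapplicable (and would react to rounding structure, not the data)
  res0 <- residuals(m)
  if (sd(res0) < 1e-8 * max(sd(fitted(m)) + sd(res0), 1e-8)) {
    fit$valid <- TRUE
    return(fit)
  }
  if (fit$family == "gaussian_ln") {
    res <- res0
    fit$normality_ok <- test_normality(res, alpha)
    fit$homoscedasticity_ok <- tryCatch({
      bp <- lmtest::bptest(m)
      if (is.na(bp$p.value)) NA else bp$p.value >= alpha
    }, error = function(e) NA)
  } else if (fit$family == "poisson") {
    res <- residuals(m, type = "deviance")
    fit$normality_ok <- test_normality(res, alpha)
    fit$homoscedasticity_ok <- bp_aux(m, alpha)
    pr <- residuals(m, type = "pearson")
    X2 <- sum(pr^2)
    dfr <- m$df.residual
    disp_p <- pchisq(X2, dfr, lower.tail = FALSE)
    fit$overdispersion_ok <- !(X2 / dfr > 1 && disp_p < alpha)
  }
  flags <- c(fit$normality_ok, fit$homoscedasticity_ok, fit$overdispersion_ok)
  fit$valid <- all(flags[!is.na(flags)])
  fit
}

test_normality <- function(res, alpha) {
  if (length(res) < 3L || sd(res) < 1e-10 * (1 + max(abs(res)))) return(NA)
  p <- tryCatch(shapiro.test(res)$p.value, error = function(e) NA_real_)
  if (is.na(p)) NA else p >= alpha
}

# Breusch-Pagan-style auxiliary regression for glm fits: squared Pearson
# residuals on the linear predictor's model matrix; LM statistic n * R^2.
bp_aux <- function(m, alpha) {
  pr <- residuals(m, type = "pearson")
  if (sd(pr) < 1e-10) return(NA)
  X <- stats::model.matrix(m)
  if (ncol(X) < 2L) return(NA)
  aux <- lm(I(pr^2) ~ X[, -1, drop = FALSE])
  r2 <- summary(aux)$r.squared
  if (is.na(r2)) return(NA)
  lmstat <- length(pr) * r2
  pchisq(lmstat, ncol(X) - 1L, lower.tail = FALSE) >= alpha
}

FAMILY_ORDER <- c(gaussian_ln = 1L, poisson = 2L, negbin = 3L)

#' Select the most parsimonious valid significant trend model
#'
#' Among converged candidates that pass their assumption checks and whose
#' trend term is significant (Wald p below `alpha`), returns the fit with the
#' lowest AIC (on the comparable scale, see [fit_candidates()]). Ties within
#' `1e-9` (including two numerically infinite AICs from noise-free fits) are
#' broken towards the lower degree, then by family order Gaussian < Poisson
#' < negative binomial. Returns `NULL` when no candidate qualifies; the
#' population is then a neutral trend.
#'
#' @param fits list of `candidate_fit`s with assumption flags filled.
#' @param alpha trend significance level (default 0.05).
#' @return a single `candidate_fit` or `NULL`.
#' @export
select_model <- function(fits, alpha = 0.05) {
  ok <- Filter(function(f) isTRUE(f$converged) && isTRUE(f$valid) &&
                 !is.na(f$slope_p) && f$slope_p < alpha, fits)
  if (!length(ok)) return(NULL)
  aics <- vapply(ok, function(f) f$aic, numeric(1))
  if (all(!is.finite(aics))) {
    tied <- ok
  } else {
    best <- min(aics[is.finite(aics)])
    tied <- ok[aics <= best + 1e-9 | (!is.finite(aics) & aics < 0)]
  }
  key <- vapply(tied, function(f) f$degree * 10L + FAMILY_ORDER[[f$family]],
                integer(1))
  tied[[which.min(key)]]
}

#' Mitchell-Olds and Shaw test for an interior extremum
#'
#' For a degree-2 candidate, locates the fitted extremum at
#' `-b1 / (2 b2)` (centred year scale, mapped back to calendar years) and
#' tests whether it lies strictly inside the observation period: the model is
#' refitted with the year axis shifted to each end of the period so that the
#' linear coefficient equals the fitted derivative there; the extremum is
#' confirmed interior when both endpoint derivatives are significant with
#' opposite signs.
#'
#' @param fit a converged degree-2 `candidate_fit`.
#' @param series the [population_series()] the fit came from.
#' @param alpha significance level (default 0.05).
#' @return list with `is_unimodal`, `mode_year` (calendar year, `NA` when the
#'   curvature is numerically zero) and `p` (the larger endpoint p-value).
#' @export
mos_test <- function(fit, series, alpha = 0.05) {
  if (fit$degree != 2L || !isTRUE(fit$converged))
    stop("mos_test needs a converged degree-2 fit")
  b1 <- fit$b1; b2 <- fit$b2
  if (is.na(b2) || abs(b2) < coef_zero_scale(c(fit$b0, b1), log1p(series$values)))
    return(list(is_unimodal = FALSE, mode_year = NA_real_, p = NA_real_))
  t <- series$years - series$years[1L]
  tmax <- max(t)
  vertex <- -b1 / (2 * b2)
  mode_year <- series$years[1L] + vertex
  if (vertex <= 0 || vertex >= tmax || sign(b1) == sign(b2) || b1 == 0)
    return(list(is_unimodal = FALSE, mode_year = mode_year, p = NA_real_))
  ends <- lapply(c(0, tmax), function(a) endpoint_derivative(fit, series, a))
  if (any(vapply(ends, function(e) is.na(e$p) || is.na(e$est), logical(1))))
    return(list(is_unimodal = FALSE, mode_year = mode_year, p = NA_real_))
  opposite <- sign(ends[[1L]]$est) != sign(ends[[2L]]$est) &&
    ends[[1L]]$est != 0 && ends[[2L]]$est != 0
  p <- max(ends[[1L]]$p, ends[[2L]]$p)
  list(is_unimodal = opposite && p < alpha, mode_year = mode_year, p = p)
}

# Refit the degree-2 candidate with years shifted by `a` so the linear
# coefficient is the derivative at t = a; returns its estimate and Wald p.
endpoint_derivative <- function(fit, series, a) {
  t <- series$years - series$years[1L] - a
  y <- series$values
  d <- switch(fit$family,
              gaussian_ln = data.frame(resp = log1p(y), t = t),
              data.frame(resp = round(y), t = t))
  m <- tryCatch(suppressWarnings(switch(
    fit$family,
    gaussian_ln = lm(resp ~ t + I(t^2), data = d),
    poisson = glm(resp ~ t + I(t^2), data = d, family = poisson()),
    negbin = glm(resp ~ t + I(t^2), data = d,
                 family = MASS::negative.binomial(
                   if (!is.null(fit$theta)) fit$theta else 1)))),
    error = function(e) NULL)
  if (is.null(m)) return(list(est = NA_real_, p = NA_real_))
  cf <- coef(suppressWarnings(summary(m)))
  if (nrow(cf) < 3L) return(list(est = NA_real_, p = NA_real_))
  est <- cf[2L, 1L]; p <- cf[2L, 4L]
  if (abs(est) < coef_zero_scale(cf[, 1L], d$resp)) p <- NA_real_
  list(est = est, p = p)
}

NINE_TREND_TYPES <- c("neutral", "positive_linear", "negative_linear",
                      "positive_accelerating", "positive_decelerating",
                      "negative_accelerating", "negative_decelerating",
                      "unimodal_pos_to_neg", "unimodal_neg_to_pos")

#' Classify a population series into one of nine trend types
#'
#' Runs [fit_candidates()], [check_assumptions()] and [select_model()], then
#' applies the decision tree: no valid significant model is a neutral trend;
#' a linear best model gives a positive or negative linear trend by the sign
#' of its slope; a quadratic best model with opposite-sign coefficients and a
#' [mos_test()]-confirmed interior extremum gives a unimodal trend (positive
#' to negative when the curvature is negative, the reverse otherwise); any
#' other quadratic best model is an accelerating or decelerating positive or
#' negative trend — direction from the sign of the fitted change over the
#' observed period, accelerating when the fitted derivative grows in
#' magnitude from first to last year.
#'
#' Populations for which no candidate model passed its assumption checks are
#' classified neutral but flagged `any_valid_model = FALSE` (they are
#' excluded from the detection-vs-duration denominator).
#'
#' @inheritParams fit_candidates
#' @param alpha significance level for trend terms and diagnostics.
#' @return an object of class `trend_classification`: list with
#'   `station_id`, `taxon_id`, `component`, `n_obs`, `span`, `first_year`,
#'   `trend_type`, `chosen` (the selected `candidate_fit` or `NULL`),
#'   `mode_year`, `any_valid_model`, and `fits` (all candidates).
#' @export
classify_trend <- function(series,
                           families = c("gaussian_ln", "poisson", "negbin"),
                           degrees = c(1L, 2L), alpha = 0.05,
                           jacobian = TRUE) {
  fits <- fit_candidates(series, families = families, degrees = degrees,
                         jacobian = jacobian)
  fits <- lapply(fits, check_assumptions, alpha = alpha)
  chosen <- select_model(fits, alpha = alpha)
  any_valid <- any(vapply(fits, function(f)
    isTRUE(f$converged) && isTRUE(f$valid), logical(1)))
  mode_year <- NA_real_
  if (is.null(chosen)) {
    type <- "neutral"
  } else if (chosen$degree == 1L) {
    type <- if (chosen$b1 > 0) "positive_linear" else "negative_linear"
  } else {
    mos <- mos_test(chosen, series, alpha = alpha)
    if (isTRUE(mos$is_unimodal)) {
      mode_year <- mos$mode_year
      type <- if (chosen$b2 < 0) "unimodal_pos_to_neg" else "unimodal_neg_to_pos"
    } else {
      type <- classify_nonunimodal_quadratic(chosen, series)
    }
  }
  structure(list(station_id = series$station_id, taxon_id = series$taxon_id,
                 component = series$component, n_obs = series$n_obs,
                 span = series$span, first_year = series$years[1L],
                 last_year = series$years[series$n_obs],
                 trend_type = type, chosen = chosen, mode_year = mode_year,
                 any_valid_model = any_valid, fits = fits),
            class = "trend_classification")
}

# Accelerating/decelerating, positive/negative labels for a quadratic best
# model without a confirmed interior extremum. Direction: sign of
# f(last) - f(first) on the link scale; accelerating iff |f'| grows over the
# period.
classify_nonunimodal_quadratic <- function(fit, series) {
  T <- max(series$years) - series$years[1L]
  b1 <- fit$b1; b2 <- fit$b2
  net <- b1 * T + b2 * T^2
  if (net == 0) net <- b1 + 2 * b2 * (T / 2)  # derivative at midpoint
  if (net == 0) return("neutral")
  dir <- if (net > 0) "positive" else "negative"
  accel <- abs(b1 + 2 * b2 * T) > abs(b1)
  paste(dir, if (accel) "accelerating" else "decelerating", sep = "_")
}

#' Fit and classify trends for many populations
#'
#' Applies [inclusion_filter()] then [classify_trend()] to each series and
#' returns both the classification objects and a tidy one-row-per-population
#' table.
#'
#' @param series_list list of [population_series()].
#' @inheritParams classify_trend
#' @inheritParams inclusion_filter
#' @return list with `classifications` (list of `trend_classification`),
#'   `trends` (data.frame: ids, n_obs, span, family, degree, coefficients,
#'   `slope_p`, `aic`, `trend_type`, `mode_year`, `any_valid_model`), and
#'   `n_excluded` (series failing the inclusion filter).
#' @export
fit_population_trends <- function(series_list,
                                  families = c("gaussian_ln", "poisson",
                                               "negbin"),
                                  degrees = c(1L, 2L), alpha = 0.05,
                                  jacobian = TRUE, min_years = 5L,
                                  min_presence = 0.5) {
  keep <- vapply(series_list, inclusion_filter, logical(1),
                 min_years = min_years, min_presence = min_presence)
  cls <- lapply(series_list[keep], classify_trend, families = families,
                degrees = degrees, alpha = alpha, jacobian = jacobian)
  list(classifications = cls, trends = trends_table(cls),
       n_excluded = sum(!keep))
}

#' Tidy table of trend classifications
#'
#' @param classifications list of `trend_classification` objects.
#' @return data.frame, one row per population.
#' @export
trends_table <- function(classifications) {
  rows <- lapply(classifications, function(cl) {
    ch <- cl$chosen
    data.frame(station_id = cl$station_id, taxon_id = cl$taxon_id,
               component = cl$component, n_obs = cl$n_obs, span = cl$span,
               first_year = cl$first_year, last_year = cl$last_year,
               family = if (is.null(ch)) NA_character_ else ch$family,
               degree = if (is.null(ch)) NA_integer_ else ch$degree,
               b0 = null_na(ch, "b0"), b1 = null_na(ch, "b1"),
               b2 = null_na(ch, "b2"), se_b1 = null_na(ch, "se_b1"),
               slope_p = null_na(ch, "slope_p"), aic = null_na(ch, "aic"),
               trend_type = cl$trend_type, mode_year = cl$mode_year,
               any_valid_model = cl$any_valid_model,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

null_na <- function(x, field) {
  if (is.null(x) || is.null(x[[field]])) NA_real_ else as.numeric(x[[field]])
}
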