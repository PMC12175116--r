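test_that("with sigma fixed at 0 the engine reproduces ordinary logit", {
  d <- sim_binomial_groups(10L, 20L, c(-1, 0.15), sigma = 0, seed = 201)
  spec <- glmm_spec("binomial", random = "taxon_id", predictor = "year",
                    reference = "neutral")
  f0 <- fit_glmm(d, spec, sigma_fixed = 0)
  g <- glm(y ~ I(x - mean(x)), data = d, family = binomial())
  expect_lt(max(abs(as.numeric(f0$B) - coef(g))), 1e-4)
})

test_that("with sigma fixed at 0 the multinomial engine matches nnet", {
  skip_if_not_installed("nnet")
  set.seed(202)
  n <- 600L
  year <- rep(1:20, length.out = n)
  xc <- year - mean(year)
  eta_pos <- 0.4 + 0.10 * xc
  eta_neg <- -0.2 - 0.08 * xc
  den <- 1 + exp(eta_pos) + exp(eta_neg)
  u <- runif(n)
  p_pos <- exp(eta_pos) / den
  p_neg <- exp(eta_neg) / den
  state <- ifelse(u < p_pos, "positive",
                  ifelse(u < p_pos + p_neg, "negative", "neutral"))
  d <- data.frame(state = state, year = year, taxon_id = "t",
                  station_id = "s")
  spec <- glmm_spec("multinomial3", random = "taxon_id")
  f0 <- fit_glmm(d, spec, sigma_fixed = 0)
  nn <- nnet::multinom(factor(state, levels = c("neutral", "negative",
                                                "positive")) ~ xc,
                       trace = FALSE)
  expect_lt(max(abs(f0$B["negative", ] - coef(nn)["negative", ])), 1e-3)
  expect_lt(max(abs(f0$B["positive", ] - coef(nn)["positive", ])), 1e-3)
})

test_that("Laplace log-likelihood matches 64-node quadrature on tiny data", {
  sg <- 0.2
  beta <- c(-0.3, 0.1)
  d <- sim_binomial_groups(3L, 4L, beta, sigma = sg, seed = 203)
  spec <- glmm_spec("binomial", random = "taxon_id", predictor = "year",
                    reference = "neutral")
  des <- seatrend:::glmm_design(spec, d)
  M <- cbind(des$X, des$Z[[1L]])
  pen <- c(0, 0, rep(1 / sg^2, ncol(des$Z[[1L]])))
  th <- c(beta, rep(0, ncol(des$Z[[1L]])))
  lap <- seatrend:::glmm_laplace_ll(th, M, des$Y, pen, sg,
                                    ncol(des$Z[[1L]]), 2L)$ll
  d$group <- d$taxon_id
  gh <- gh_loglik_binomial(d, beta, sg, x_center = mean(d$x))
  expect_lt(abs(lap - gh), 1e-3)
})

test_that("fitted slope is recovered within 2 SE under random intercepts", {
  hits <- 0L
  n_rep <- 20L
  for (r in seq_len(n_rep)) {
    d <- sim_binomial_groups(30L, 15L, c(-0.5, 0.2), sigma = 0.6,
                             seed = 300 + r)
    spec <- glmm_spec("binomial", random = "taxon_id", predictor = "year",
                      reference = "neutral")
    f <- fit_glmm(d, spec)
    if (abs(f$B[1L, 2L] - 0.2) <= 2 * f$se[1L, 2L]) hits <- hits + 1L
  }
  expect_gte(hits, 17L)
})

test_that("binomial engine tracks lme4 on crossed random intercepts", {
  skip_if_not_installed("lme4")
  set.seed(204)
  d <- expand.grid(year = 1:15, taxon_id = sprintf("sp%d", 1:12),
                   station_id = sprintf("st%d", 1:3),
                   stringsAsFactors = FALSE)
  usp <- rnorm(12, 0, 0.5); names(usp) <- sprintf("sp%d", 1:12)
  ust <- rnorm(3, 0, 0.3); names(ust) <- sprintf("st%d", 1:3)
  eta <- -0.3 + 0.12 * (d$year - 8) + usp[d$taxon_id] + ust[d$station_id]
  d$state <- ifelse(runif(nrow(d)) < plogis(eta), "directional", "neutral")
  spec <- glmm_spec("binomial", random = c("taxon_id", "station_id"),
                    predictor = "year", reference = "neutral")
  f <- fit_glmm(d, spec)
  gm <- lme4::glmer(I(state == "directional") ~ I(year - mean(year)) +
                      (1 | taxon_id) + (1 | station_id),
                    data = d, family = binomial())
  fe <- lme4::fixef(gm)
  expect_lt(abs(f$B[1L, 2L] - fe[2L]), 0.02)
  expect_lt(abs(f$B[1L, 1L] - fe[1L]), 0.1)
})

test_that("predicted state probabilities sum to one and obey the softmax", {
  d <- data.frame(
    state = rep(c("negative", "neutral", "positive"), 40L),
    year = rep(1:30, 4L), taxon_id = rep(sprintf("t%d", 1:4), each = 30L),
    station_id = "s1")
  spec <- glmm_spec("multinomial3", random = "taxon_id")
  f <- fit_glmm(d, spec)
  pr <- predict_state_probabilities(f, 1:30)
  sums <- pr$pi_negative + pr$pi_neutral + pr$pi_positive
  expect_lt(max(abs(sums - 1)), 1e-12)

  # hand-built softmax check: logits +1 / -1 at the centring point
  f2 <- f
  f2$B <- matrix(c(-1, 0, 1, 0), 2L, 2L, byrow = TRUE,
                 dimnames = list(c("negative", "positive"), NULL))
  f2$quadratic <- FALSE
  p0 <- predict_state_probabilities(f2, f2$x_center)
  den <- 1 + exp(1) + exp(-1)
  expect_equal(p0$pi_positive, exp(1) / den, tolerance = 1e-12)
  expect_equal(p0$pi_negative, exp(-1) / den, tolerance = 1e-12)
  expect_equal(p0$pi_neutral, 1 / den, tolerance = 1e-12)

  # all-zero coefficients: perfect three-way symmetry
  f2$B[] <- 0
  p1 <- predict_state_probabilities(f2, f2$x_center + c(-3, 0, 3))
  expect_true(all(abs(as.matrix(p1[, -1]) - 1 / 3) < 1e-15))
})

test_that("AIC picks the polynomial degree that generated the data", {
  mk <- function(quad, seed) {
    set.seed(seed)
    d <- expand.grid(year = 1:25, taxon_id = sprintf("g%d", 1:10),
                     stringsAsFactors = FALSE)
    d$station_id <- "s1"
    xc <- d$year - 13
    eta <- if (quad) 1.2 - 0.035 * xc^2 else -0.5 + 0.18 * xc
    d$state <- ifelse(runif(nrow(d)) < plogis(eta), "directional", "neutral")
    d
  }
  spec <- glmm_spec("binomial", random = "taxon_id", predictor = "year",
                    reference = "neutral")
  # AIC admits the spurious quadratic with prob P(chi2_1 > 2) ~ 0.16, so
  # the expected linear-choice rate under a linear truth is ~84%
  lin_wins <- sum(vapply(1:8, function(i)
    !select_polynomial(mk(FALSE, 400 + i), spec)$quadratic, logical(1)))
  qua_wins <- sum(vapply(1:8, function(i)
    select_polynomial(mk(TRUE, 500 + i), spec)$quadratic, logical(1)))
  expect_gte(lin_wins, 5L)
  expect_gte(qua_wins, 7L)
})

test_that("the year block likelihood-ratio test is calibrated under the null", {
  rejections <- 0L
  n_rep <- 40L
  for (r in seq_len(n_rep)) {
    d <- sim_binomial_groups(15L, 12L, c(-0.2, 0), sigma = 0.5,
                             seed = 600 + r)
    spec <- glmm_spec("binomial", random = "taxon_id", predictor = "year",
                      reference = "neutral")
    f <- fit_glmm(d, spec)
    if (f$year_p < 0.05) rejections <- rejections + 1L
  }
  # nominal 5%: expect few rejections out of 40
  expect_lte(rejections, 6L)
})
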