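mk_classification <- function(trend_type, b1 = NA, b2 = NA, degree = NA,
                              first_year = 1980L, last_year = 2010L) {
  chosen <- if (is.na(degree)) NULL else
    structure(list(family = "gaussian_ln", degree = as.integer(degree),
                   b0 = 3, b1 = b1, b2 = b2, converged = TRUE),
              class = "candidate_fit")
  structure(list(station_id = "s1", taxon_id = "t1", component = "fish",
                 n_obs = last_year - first_year + 1L,
                 span = last_year - first_year + 1L,
                 first_year = first_year, last_year = last_year,
                 trend_type = trend_type, chosen = chosen,
                 mode_year = NA_real_, any_valid_model = TRUE,
                 fits = list()),
            class = "trend_classification")
}

test_that("yearly states follow the analytic derivative sign", {
  lin <- yearly_states(mk_classification("positive_linear", b1 = 0.05,
                                         degree = 1))
  expect_true(all(lin$state == "positive"))
  expect_true(all(lin$rate == 0.05))

  # quadratic with derivative zero at t = 15: sign flips there
  qq <- yearly_states(mk_classification("unimodal_pos_to_neg", b1 = 0.3,
                                        b2 = -0.01, degree = 2))
  t <- qq$year - 1980
  expect_equal(qq$rate, 0.3 - 0.02 * t)
  expect_identical(qq$state[t == 10], "positive")
  expect_identical(qq$state[t == 20], "negative")
  expect_identical(qq$state[t == 15], "neutral")  # exact zero

  neu <- yearly_states(mk_classification("neutral"))
  expect_true(all(neu$state == "neutral"))
})

test_that("states equal the finite-difference sign on random quadratics", {
  set.seed(901)
  for (r in 1:100) {
    b1 <- runif(1, -0.5, 0.5)
    b2 <- runif(1, -0.02, 0.02)
    cl <- mk_classification("positive_accelerating", b1 = b1, b2 = b2,
                            degree = 2)
    ys <- yearly_states(cl)
    t <- ys$year - 1980
    f <- function(tt) 3 + b1 * tt + b2 * tt^2
    h <- 1e-6
    fd <- (f(t + h) - f(t - h)) / (2 * h)
    expected <- ifelse(abs(fd) < 1e-9, "neutral",
                       ifelse(fd > 0, "positive", "negative"))
    expect_identical(ys$state, expected)
  }
})

test_that("timeline verdicts apply overlap, threshold and majority rules", {
  tl <- data.frame(
    year = 1:3,
    pi_positive = c(0.7, 0.3, 0.35),
    pi_positive_lo = c(0.6, 0.2, 0.30), pi_positive_hi = c(0.8, 0.4, 0.40),
    pi_negative = c(0.1, 0.25, 0.10),
    pi_negative_lo = c(0.05, 0.15, 0.05), pi_negative_hi = c(0.15, 0.35, 0.15))
  v <- classify_timeline(tl)
  expect_identical(v$verdict, c("positive", "cancelled", "neutral"))

  # threshold-first ordering flips the precedence of rules 1 and 2
  v2 <- classify_timeline(tl, rule_order = "threshold_first")
  expect_identical(v2$verdict, c("positive", "neutral", "neutral"))
})

test_that("verdicts are symmetric under swapping the two directions", {
  set.seed(902)
  for (r in 1:50) {
    pp <- runif(1); pn <- runif(1, 0, 1 - pp)
    wp <- runif(1, 0, 0.2); wn <- runif(1, 0, 0.2)
    tl <- data.frame(year = 1, pi_positive = pp,
                     pi_positive_lo = max(0, pp - wp),
                     pi_positive_hi = min(1, pp + wp),
                     pi_negative = pn,
                     pi_negative_lo = max(0, pn - wn),
                     pi_negative_hi = min(1, pn + wn))
    sw <- tl
    names(sw) <- sub("negative", "tmp", names(sw))
    names(sw) <- sub("positive", "negative", names(sw))
    names(sw) <- sub("tmp", "positive", names(sw))
    v <- classify_timeline(tl)$verdict
    vs <- classify_timeline(sw)$verdict
    expect_identical(vs, switch(v, positive = "negative",
                                negative = "positive", v))
  }
})

test_that("bootstrap bands are deterministic under a seed and detect a flip", {
  sim <- simulate_seascape("flip", n_stations = 2L, n_species = 8L,
                           n_components = 1L, n_years = 31L, sigma = 0.2,
                           flip_year = 15, seed = 903)
  fp <- suppressWarnings(fit_population_trends(sim$series,
                                               families = "gaussian_ln"))
  st <- collect_yearly_states(fp$classifications)
  fit <- fit_group_timeline(st)
  expect_true(fit$significant)
  tl1 <- bootstrap_timeline(fit, st, B = 200L, seed = 42)
  tl2 <- bootstrap_timeline(fit, st, B = 200L, seed = 42)
  expect_identical(tl1, tl2)
  v <- classify_timeline(tl1)
  first_neg <- v$year[min(which(v$verdict == "negative"))]
  expect_true(abs(first_neg - (1980 + 15)) <= 3)
  # the early period is dominated by positive trends
  expect_identical(v$verdict[1L], "positive")
})

test_that("timeline models need at least two observed states", {
  st <- data.frame(station_id = "s1", taxon_id = "t1", component = "fish",
                   year = 1:10, rate = 0, state = "neutral",
                   population = "p1")
  expect_error(fit_group_timeline(st), "at least two")
})
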