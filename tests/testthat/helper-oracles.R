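# Independent oracles used across test files. These never call the code
# paths they check.

# 1-D REML grid search for the random-effects mean with known sampling
# variances (one effect per station, so the station variance is the usual
# between-study tau^2). Returns the GLS mean at the REML-optimal tau^2.
reml_grid_oracle <- function(yi, vi, tau2_max = NULL, step = 1e-6) {
  if (is.null(tau2_max)) tau2_max <- max(var(yi), 1e-4) * 2
  restricted_nll <- function(tau2) {
    w <- 1 / (vi + tau2)
    mu <- sum(w * yi) / sum(w)
    0.5 * (sum(log(vi + tau2)) + log(sum(w)) + sum(w * (yi - mu)^2))
  }
  grid <- seq(0, tau2_max, by = step)
  nll <- vapply(grid, restricted_nll, numeric(1))
  tau2 <- grid[which.min(nll)]
  w <- 1 / (vi + tau2)
  list(tau2 = tau2, mu = sum(w * yi) / sum(w),
       se = sqrt(1 / sum(w)))
}

# Gauss-Hermite marginal log-likelihood for a binomial random-intercept
# logit (one grouping factor), evaluated at given fixed effects and sigma.
gh_loglik_binomial <- function(data, beta, sigma, x_center, nodes = 64L) {
  gh <- pracma::gaussHermite(nodes)
  ll <- 0
  for (g in unique(data$group)) {
    idx <- data$group == g
    y <- data$y[idx]
    xc <- data$x[idx] - x_center
    vals <- vapply(gh$x, function(z) {
      u <- sqrt(2) * sigma * z
      eta <- beta[1] + beta[2] * xc + u
      sum(ifelse(y == 1, stats::plogis(eta, log.p = TRUE),
                 stats::plogis(-eta, log.p = TRUE)))
    }, numeric(1))
    m <- max(vals)
    ll <- ll + m + log(sum(gh$w * exp(vals - m) / sqrt(pi)))
  }
  ll
}

# Simulate a binomial random-intercept dataset for engine checks.
sim_binomial_groups <- function(n_groups, n_per, beta, sigma, seed,
                                x = NULL) {
  set.seed(seed)
  if (is.null(x)) x <- seq_len(n_per)
  d <- expand.grid(x = x, group = sprintf("g%02d", seq_len(n_groups)),
                   stringsAsFactors = FALSE)
  u <- stats::rnorm(n_groups, 0, sigma)
  names(u) <- sprintf("g%02d", seq_len(n_groups))
  eta <- beta[1] + beta[2] * (d$x - mean(d$x)) + u[d$group]
  d$y <- as.integer(stats::runif(nrow(d)) < stats::plogis(eta))
  d$state <- ifelse(d$y == 1, "directional", "neutral")
  d$taxon_id <- d$group
  d$station_id <- "s1"
  d$year <- d$x
  d
}

# Direction (positive / negative / neither) implied by a classification,
# via the five-way vote-count grouping.
classified_direction <- function(trend_type) {
  g <- group_trend_types(trend_type)
  ifelse(g %in% c("positive", "negative"), g, "other")
}
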