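#' Yearly trend-direction states from a fitted population trend
#'
#' The annual rate of change is the derivative of the chosen model's trend
#' on its link scale: constant `b1` for a linear best model,
#' `b1 + 2 b2 (year - first_year)` for a quadratic one. Each year of the
#' population's monitoring period gets a state: `positive` or `negative` by
#' the sign of the rate, `neutral` when the rate is exactly zero (tolerance
#' `1e-12`) or when the population was classified neutral.
#'
#' @param classification a `trend_classification` from [classify_trend()].
#' @param years years at which to evaluate; defaults to every calendar year
#'   of the monitoring period (first to last observed year).
#' @return data.frame: `station_id`, `taxon_id`, `component`, `year`,
#'   `rate`, `state`.
#' @export
yearly_states <- function(classification, years = NULL) {
  cl <- classification
  if (is.null(years)) years <- seq(cl$first_year, cl$last_year)
  t <- years - cl$first_year
  if (cl$trend_type == "neutral" || is.null(cl$chosen)) {
    rate <- rep(0, length(years))
  } else if (cl$chosen$degree == 1L) {
    rate <- rep(cl$chosen$b1, length(years))
  } else {
    rate <- cl$chosen$b1 + 2 * cl$chosen$b2 * t
  }
  state <- ifelse(cl$trend_type == "neutral" | abs(rate) < 1e-12, "neutral",
                  ifelse(rate > 0, "positive", "negative"))
  data.frame(station_id = cl$station_id, taxon_id = cl$taxon_id,
             component = cl$component, year = years, rate = rate,
             state = state, stringsAsFactors = FALSE)
}

#' Collect yearly states for a set of classifications
#'
#' @param classifications list of `trend_classification` objects.
#' @return row-bound [yearly_states()] tables with a `population` id column
#'   (`station_id x taxon_id`).
#' @export
collect_yearly_states <- function(classifications) {
  out <- do.call(rbind, lapply(classifications, yearly_states))
  out$population <- paste(out$station_id, out$taxon_id, sep = "\r")
  out
}

#' Mixed logit timeline model for one taxonomic group
#'
#' Fits the probability of each yearly trend-direction state against year
#' for all populations of a group, with species and station as crossed
#' random intercepts: a baseline-category multinomial logit with `neutral`
#' as reference when all three states occur, a binomial logit when only two
#' do. A quadratic year term is kept when it lowers the AIC (or forced via
#' `polynomial`). The model is flagged non-significant when the
#' likelihood-ratio test of the year block does not reject at `alpha`.
#'
#' @param states a states table from [collect_yearly_states()] (optionally
#'   filtered to one group).
#' @param polynomial `"auto"` (AIC selection, default), `"linear"` or
#'   `"quadratic"`.
#' @param alpha significance level for the year term (default 0.05).
#' @return a `glmm_fit` with extra fields `significant` (logical) and
#'   `states_present`; `NULL`-like error if fewer than two states occur.
#' @export
fit_group_timeline <- function(states, polynomial = c("auto", "linear",
                                                      "quadratic"),
                               alpha = 0.05) {
  polynomial <- match.arg(polynomial)
  present <- sort(unique(states$state))
  if (length(present) < 2L)
    stop("timeline model needs at least two observed states (got: ",
         paste(present, collapse = ", "), ")")
  kind <- if (length(present) == 3L) "multinomial3" else "binomial"
  spec <- glmm_spec(kind, random = c("taxon_id", "station_id"),
                    predictor = "year", reference = "neutral")
  fit <- if (polynomial == "auto") {
    sel <- select_polynomial(states, spec)
    fits <- attr(sel, "fits")
    if (sel$quadratic) fits$quadratic else fits$linear
  } else {
    spec$quadratic <- polynomial == "quadratic"
    fit_glmm(states, spec)
  }
  fit$significant <- fit$year_p < alpha
  fit$states_present <- present
  fit
}

#' Cluster-bootstrap confidence bands for timeline probabilities
#'
#' Resamples populations (species-by-station clusters) with replacement,
#' refits the timeline model on each replicate (random-effect variances held
#' at the full-data estimates, year centring inherited), and collects the
#' predicted per-year state probabilities; the 2.5% and 97.5% percentiles
#' bound the 95% band. Errors out when more than 20% of replicates fail.
#'
#' @param fit a [fit_group_timeline()] result.
#' @param states the states table the fit was computed from.
#' @param B number of bootstrap replicates (at least 200; default 1000).
#' @param years years at which to evaluate (default: all years present).
#' @param seed optional integer seed for reproducibility.
#' @return data.frame: `year`, point probabilities `pi_positive`,
#'   `pi_negative` (and `pi_neutral` when modelled) with `*_lo` / `*_hi`
#'   bounds, and `n_fail` attribute with the replicate failure count.
#' @export
bootstrap_timeline <- function(fit, states, B = 1000L, years = NULL,
                               seed = NULL) {
  stopifnot(B >= 200L)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(years)) years <- sort(unique(states$year))
  if (!"population" %in% names(states))
    states$population <- paste(states$station_id, states$taxon_id, sep = "\r")
  clusters <- split(seq_len(nrow(states)), states$population)
  ncl <- length(clusters)
  point <- predict_state_probabilities(fit, years)
  draws <- vector("list", B)
  n_fail <- 0L
  for (b in seq_len(B)) {
    pick <- sample.int(ncl, ncl, replace = TRUE)
    idx <- unlist(clusters[pick], use.names = FALSE)
    rep_states <- states[idx, , drop = FALSE]
    # resamples may lack a rare state: the refit keeps the original state
    # set and lets that state's probability collapse, a legitimate draw
    rfit <- tryCatch(refit_glmm_fixed_sigma(fit, rep_states, fit$spec),
                     error = function(e) NULL)
    if (is.null(rfit)) {
      n_fail <- n_fail + 1L
      next
    }
    draws[[b]] <- predict_state_probabilities(rfit, years)
  }
  if (n_fail > 0.2 * B)
    stop(sprintf("bootstrap failure rate %.1f%% exceeds 20%% (B = %d)",
                 100 * n_fail / B, B))
  draws <- draws[!vapply(draws, is.null, logical(1))]
  out <- data.frame(year = years)
  for (col in setdiff(names(point), "year")) {
    mat <- vapply(draws, function(d) d[[col]], numeric(length(years)))
    if (is.null(dim(mat))) mat <- matrix(mat, nrow = length(years))
    out[[col]] <- point[[col]]
    out[[paste0(col, "_lo")]] <- apply(mat, 1L, quantile, probs = 0.025,
                                       names = FALSE)
    out[[paste0(col, "_hi")]] <- apply(mat, 1L, quantile, probs = 0.975,
                                       names = FALSE)
  }
  attr(out, "n_fail") <- n_fail
  out
}

#' Per-year predominant-trend verdicts from a bootstrapped timeline
#'
#' For each year, in order: (1) when the confidence bands of the positive
#' and negative state probabilities overlap, the trends cancel out
#' (`cancelled`); (2) otherwise, when neither probability reaches 0.5 the
#' year is `neutral`; (3) otherwise the state with the higher point
#' probability wins. The rule order is configurable (`threshold_first`
#' checks the 0.5 rule before the overlap rule).
#'
#' @param timeline a [bootstrap_timeline()] table (needs `pi_positive`,
#'   `pi_negative` and their `_lo`/`_hi` bounds; a state absent from the
#'   model counts as probability zero with a degenerate band).
#' @param threshold predominance threshold (default 0.5).
#' @param rule_order `"overlap_first"` (default) or `"threshold_first"`.
#' @return the table with a `verdict` column appended.
#' @export
classify_timeline <- function(timeline, threshold = 0.5,
                              rule_order = c("overlap_first",
                                             "threshold_first")) {
  rule_order <- match.arg(rule_order)
  get <- function(nm, default) {
    if (nm %in% names(timeline)) timeline[[nm]] else default
  }
  zero <- rep(0, nrow(timeline))
  pp <- get("pi_positive", zero); pn <- get("pi_negative", zero)
  pp_lo <- get("pi_positive_lo", pp); pp_hi <- get("pi_positive_hi", pp)
  pn_lo <- get("pi_negative_lo", pn); pn_hi <- get("pi_negative_hi", pn)
  overlap <- pp_lo <= pn_hi & pn_lo <= pp_hi
  below <- pmax(pp, pn) < threshold
  verdict <- character(nrow(timeline))
  for (i in seq_len(nrow(timeline))) {
    verdict[i] <- if (rule_order == "overlap_first") {
      if (overlap[i]) "cancelled"
      else if (below[i]) "neutral"
      else if (pp[i] > pn[i]) "positive"
      else if (pn[i] > pp[i]) "negative" else "cancelled"
    } else {
      if (below[i]) "neutral"
      else if (overlap[i]) "cancelled"
      else if (pp[i] > pn[i]) "positive"
      else if (pn[i] > pp[i]) "negative" else "cancelled"
    }
  }
  timeline$verdict <- verdict
  timeline
}

#' Full timeline analysis for taxonomic groups
#'
#' Convenience driver: splits the yearly states by a grouping column, fits
#' the timeline model, bootstraps the bands and classifies each year.
#' Groups without a significant year effect are reported with
#' `significant = FALSE` and no verdicts.
#'
#' @param classifications list of `trend_classification`s.
#' @param group_by column of the states table to split on (default
#'   `"component"`).
#' @param B bootstrap replicates.
#' @param seed integer seed.
#' @inheritParams fit_group_timeline
#' @return named list per group: `fit`, `timeline` (with verdicts, or
#'   `NULL` when not significant / inestimable).
#' @export
group_timelines <- function(classifications, group_by = "component",
                            B = 1000L, seed = NULL,
                            polynomial = c("auto", "linear", "quadratic")) {
  polynomial <- match.arg(polynomial)
  states <- collect_yearly_states(classifications)
  out <- list()
  for (g in unique(states[[group_by]])) {
    sub <- states[states[[group_by]] == g, , drop = FALSE]
    res <- tryCatch({
      fit <- fit_group_timeline(sub, polynomial = polynomial)
      if (!isTRUE(fit$significant)) {
        list(fit = fit, timeline = NULL)
      } else {
        tl <- bootstrap_timeline(fit, sub, B = B, seed = seed)
        list(fit = fit, timeline = classify_timeline(tl))
      }
    }, error = function(e) list(fit = NULL, timeline = NULL,
                                error = conditionMessage(e)))
    out[[g]] <- res
  }
  out
}
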