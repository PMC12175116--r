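#' Collapse the nine trend types into five vote-count groups
#'
#' Positive linear, accelerating and decelerating trends are grouped as
#' `positive`; their negative counterparts as `negative`; the two unimodal
#' types and `neutral` pass through unchanged.
#'
#' @param trend_type character vector of trend-type labels.
#' @return character vector among `positive`, `negative`,
#'   `unimodal_pos_to_neg`, `unimodal_neg_to_pos`, `neutral`.
#' @export
group_trend_types <- function(trend_type) {
  map <- c(neutral = "neutral",
           positive_linear = "positive",
           positive_accelerating = "positive",
           positive_decelerating = "positive",
           negative_linear = "negative",
           negative_accelerating = "negative",
           negative_decelerating = "negative",
           unimodal_pos_to_neg = "unimodal_pos_to_neg",
           unimodal_neg_to_pos = "unimodal_neg_to_pos")
  out <- map[trend_type]
  if (anyNA(out))
    stop("unknown trend type(s): ",
         paste(unique(trend_type[is.na(out)]), collapse = ", "))
  unname(out)
}

VOTE_GROUPS <- c("positive", "negative", "unimodal_pos_to_neg",
                 "unimodal_neg_to_pos", "neutral")

#' Year-weighted vote count of trend groups
#'
#' Each population trend votes for its five-way trend group with weight
#' equal to its number of observation years, so long, well-observed series
#' count more. Shares are percentages that sum to 100 within each scope
#' (overall, and per ecosystem component when `by_component = TRUE`).
#'
#' @param trends a trends table from [fit_population_trends()] (needs
#'   columns `trend_type`, `n_obs`, and `component` for the per-component
#'   breakdown).
#' @param by_component also compute per-component shares?
#' @return data.frame with columns `scope`, `trend_group`, `weighted_share`
#'   (percent), `n_trends`, `total_weight` (years).
#' @export
weighted_vote_count <- function(trends, by_component = FALSE) {
  stopifnot(nrow(trends) > 0)
  one_scope <- function(sub, scope) {
    grp <- factor(group_trend_types(sub$trend_type), levels = VOTE_GROUPS)
    w <- sub$n_obs
    tw <- sum(w)
    if (tw <= 0) stop("zero total weight in scope ", scope)
    ws <- tapply(w, grp, sum, default = 0)
    data.frame(scope = scope, trend_group = VOTE_GROUPS,
               weighted_share = 100 * as.numeric(ws) / tw,
               n_trends = as.integer(table(grp)),
               total_weight = tw, stringsAsFactors = FALSE)
  }
  out <- one_scope(trends, "all")
  if (by_component) {
    for (cmp in unique(trends$component))
      out <- rbind(out, one_scope(trends[trends$component == cmp, , drop = FALSE],
                                  cmp))
  }
  rownames(out) <- NULL
  out
}

#' Probability of detecting a non-neutral trend vs. monitoring duration
#'
#' Binomial mixed logit of the indicator "directional trend found" on
#' monitoring duration, with station and species (taxon) as crossed random
#' intercepts. Only populations for which at least one candidate model met
#' its assumptions enter (a neutral call without any valid model says
#' nothing about detection).
#'
#' @param trends trends table from [fit_population_trends()].
#' @param predictor `"span"` (first-to-last year, default) or `"n_obs"`.
#' @return list: `fit` (the [fit_glmm()] object), `B` (duration slope),
#'   `se`, `ci` (95% Wald), `chisq` and `p` (likelihood-ratio test of the
#'   duration term), `n`.
#' @export
detection_vs_duration <- function(trends, predictor = c("span", "n_obs")) {
  predictor <- match.arg(predictor)
  sub <- trends[trends$any_valid_model, , drop = FALSE]
  if (nrow(sub) < 3L) stop("too few populations with a valid model")
  sub$state <- ifelse(sub$trend_type == "neutral", "neutral", "directional")
  duration_glmm(sub, predictor)
}

#' Probability that any model meets assumptions vs. monitoring duration
#'
#' Same binomial mixed logit as [detection_vs_duration()] but with outcome
#' "at least one candidate model met its assumptions", over all classified
#' populations.
#'
#' @inheritParams detection_vs_duration
#' @return as [detection_vs_duration()].
#' @export
validity_vs_duration <- function(trends, predictor = c("span", "n_obs")) {
  predictor <- match.arg(predictor)
  sub <- trends
  sub$state <- ifelse(sub$any_valid_model, "valid", "invalid")
  duration_glmm(sub, predictor)
}

duration_glmm <- function(sub, predictor) {
  if (length(unique(sub$state)) < 2L) {
    return(list(fit = NULL, B = NA_real_, se = NA_real_,
                ci = c(NA_real_, NA_real_), chisq = NA_real_, p = NA_real_,
                n = nrow(sub), separation = TRUE,
                note = "all outcomes identical (separation)"))
  }
  spec <- glmm_spec("binomial", quadratic = FALSE,
                    random = c("taxon_id", "station_id"),
                    predictor = predictor, reference = "neutral")
  # reference: the 'failure' level so that B > 0 means higher probability of
  # detection/validity with longer duration
  spec$reference <- if ("neutral" %in% sub$state) "neutral" else "invalid"
  fit <- fit_glmm(sub, spec)
  B <- fit$B[1L, 2L]
  se <- fit$se[1L, 2L]
  lr_df <- 1L
  chisq <- max(0, 2 * (fit$loglik - fit$null_loglik))
  list(fit = fit, B = B, se = se,
       ci = B + c(-1, 1) * qnorm(0.975) * se,
       chisq = chisq, p = pchisq(chisq, lr_df, lower.tail = FALSE),
       n = nrow(sub), separation = fit$separation)
}
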