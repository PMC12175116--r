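#' Build the meta-analysis effect-size table
#'
#' The effect size of a population is the slope of its Gaussian linear model
#' on `ln(x+1)`-transformed abundance, with sampling variance the squared
#' standard error — regardless of whether a polynomial, Poisson, or negative
#' binomial candidate had the lower AIC. Only populations whose Gaussian
#' linear fit met its residual assumptions are eligible. Taxonomy labels are
#' merged in; rows whose taxon is missing from the taxonomy are kept but
#' flagged (`taxonomy_ok = FALSE`) and should be excluded from rank-moderated
#' runs.
#'
#' @param classifications list of `trend_classification` objects.
#' @param taxonomy taxonomy data frame (see [read_taxonomy_csv()]), or
#'   `NULL` to skip the merge.
#' @return data.frame with columns `station_id`, `taxon_id`, `component`,
#'   `slope`, `v`, `n_obs`, `span`, the seven rank columns, `taxonomy_ok`.
#' @export
build_effect_table <- function(classifications, taxonomy = NULL) {
  rows <- lapply(classifications, function(cl) {
    g1 <- Filter(function(f) f$family == "gaussian_ln" && f$degree == 1L &&
                   isTRUE(f$converged), cl$fits)
    if (!length(g1)) return(NULL)
    f <- g1[[1L]]
    if (!isTRUE(f$valid)) return(NULL)
    if (is.na(f$se_b1) || f$se_b1 <= 0) return(NULL)
    data.frame(station_id = cl$station_id, taxon_id = cl$taxon_id,
               component = cl$component, slope = f$b1, v = f$se_b1^2,
               n_obs = cl$n_obs, span = cl$span, stringsAsFactors = FALSE)
  })
  eff <- do.call(rbind, rows)
  if (is.null(eff) || !nrow(eff)) stop("no eligible effect sizes")
  if (!is.null(taxonomy)) {
    taxonomy <- validate_taxonomy(taxonomy)
    idx <- match(eff$taxon_id, taxonomy$taxon_id)
    for (r in TAXONOMY_RANKS)
      eff[[r]] <- ifelse(is.na(idx), NA_character_, taxonomy[[r]][idx])
    eff$taxonomy_ok <- !is.na(idx)
  } else {
    eff$taxonomy_ok <- TRUE
  }
  rownames(eff) <- NULL
  eff
}

#' Multilevel random-effects meta-analysis of population slopes
#'
#' Pools slopes with known sampling variances under the model
#' `y_i = X beta + u_station(i) + e_i`, `u ~ N(0, sigma2_station)`,
#' `e_i ~ N(0, v_i)`, with `sigma2_station` estimated by REML and Wald
#' normal (z) confidence intervals. With a moderator and
#' `intercept = FALSE`, each moderator level gets its own pooled mean — the
#' winners-and-losers layout.
#'
#' @param effects effect table from [build_effect_table()].
#' @param moderator `NULL` (overall pooled slope) or the name of a
#'   categorical column of `effects` (e.g. `"component"`, `"class"`).
#' @param intercept keep the intercept when a moderator is present? With
#'   `FALSE` (default for moderated runs) the coefficients are per-level
#'   means rather than contrasts.
#' @param absolute pool `|slope|` instead of the signed slope (the
#'   cancellation diagnostic).
#' @return data.frame of class `meta_result`: `level`, `estimate`, `se`,
#'   `zval`, `ci_lower`, `ci_upper`, `p`, `sigma2_station`, `k`,
#'   `n_species`.
#' @export
reml_multilevel <- function(effects, moderator = NULL, intercept = is.null(moderator),
                            absolute = FALSE) {
  stopifnot(nrow(effects) >= 2L)
  eff <- effects
  if (!is.null(moderator)) {
    eff <- eff[!is.na(eff[[moderator]]) & eff[[moderator]] != "", , drop = FALSE]
    eff$.mod <- factor(eff[[moderator]])
    counts <- table(eff$.mod)
    eff <- eff[eff$.mod %in% names(counts)[counts >= 2L], , drop = FALSE]
    eff$.mod <- droplevels(eff$.mod)
    if (!nlevels(eff$.mod)) stop("no moderator level with k >= 2")
  }
  yi <- if (absolute) abs(eff$slope) else eff$slope
  res <- if (is.null(moderator)) {
    metafor::rma.mv(yi = yi, V = eff$v, random = ~ 1 | station_id,
                    data = eff, method = "REML", sparse = TRUE)
  } else {
    mods <- if (intercept) ~ .mod else ~ .mod - 1
    metafor::rma.mv(yi = yi, V = eff$v, mods = mods,
                    random = ~ 1 | station_id, data = eff,
                    method = "REML", sparse = TRUE)
  }
  lab <- if (is.null(moderator)) {
    if (absolute) "all_absolute" else "all"
  } else {
    gsub("^\\.mod", "", rownames(res$beta))
  }
  ns <- if (is.null(moderator)) length(unique(eff$taxon_id))
  else as.integer(tapply(eff$taxon_id, eff$.mod,
                         function(x) length(unique(x))))[
                           match(lab, levels(eff$.mod))]
  kk <- if (is.null(moderator)) res$k
  else as.integer(table(eff$.mod))[match(lab, levels(eff$.mod))]
  if (!is.null(moderator) && intercept) {
    ns <- rep(NA_integer_, length(lab))
    kk <- rep(res$k, length(lab))
  }
  out <- data.frame(level = lab, estimate = as.numeric(res$beta),
                    se = res$se, zval = res$zval, ci_lower = res$ci.lb,
                    ci_upper = res$ci.ub, p = res$pval,
                    sigma2_station = res$sigma2[1L], k = kk, n_species = ns,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("meta_result", "data.frame")
  out
}

#' Ecosystem-wide meta-analysis of absolute slopes
#'
#' Re-runs the overall multilevel meta-analysis with the absolute values of
#' the slopes (sampling variances unchanged): when positive and negative
#' trends cancel in the signed analysis, a clearly positive absolute-slope
#' mean reveals the underlying change.
#'
#' @inheritParams reml_multilevel
#' @return a one-row `meta_result`.
#' @export
absolute_slope_meta <- function(effects) {
  reml_multilevel(effects, moderator = NULL, absolute = TRUE)
}

#' Winner / loser calls from meta-analysis confidence intervals
#'
#' A taxon (or any moderator level) is a winner when its 95% CI lies
#' entirely above zero, a loser when entirely below, and neutral otherwise.
#'
#' @param meta a `meta_result` data frame.
#' @param rank optional label describing the taxonomic rank analysed.
#' @return data.frame: `level`, `rank`, `estimate`, `ci_lower`, `ci_upper`,
#'   `call`.
#' @export
winners_losers <- function(meta, rank = NA_character_) {
  call <- ifelse(meta$ci_lower > 0, "winner",
                 ifelse(meta$ci_upper < 0, "loser", "neutral"))
  data.frame(level = meta$level, rank = rank, estimate = meta$estimate,
             ci_lower = meta$ci_lower, ci_upper = meta$ci_upper,
             call = call, stringsAsFactors = FALSE)
}

# Component groupings used for the finer-rank (order/family/genus) runs.
COMPONENT_SUBSETS <- list(
  plants = "plants",
  phytoplankton = "phytoplankton",
  fish = "fish",
  birds = "birds",
  macrozoobenthos_zooplankton = c("macrozoobenthos", "zooplankton"))

#' Winner / loser assessment across taxonomic ranks
#'
#' Runs the moderated (no-intercept) meta-analysis with `class` as moderator
#' on the full effect table, and with `order`, `family` and `genus` as
#' moderators on ecosystem-component subsets (plants; phytoplankton; fish;
#' birds; macrozoobenthos and zooplankton pooled), collecting winner/loser
#' calls per level. Levels with fewer than two effects, and subsets where
#' the model cannot be fitted, are skipped.
#'
#' @param effects effect table from [build_effect_table()] with taxonomy.
#' @param ranks ranks to analyse (default `class`, `order`, `family`,
#'   `genus`).
#' @return data.frame of calls (see [winners_losers()]) with an extra
#'   `subset` column.
#' @export
winners_losers_by_rank <- function(effects,
                                   ranks = c("class", "order", "family",
                                             "genus")) {
  eff <- effects[effects$taxonomy_ok, , drop = FALSE]
  out <- list()
  run <- function(sub, rank, label) {
    res <- tryCatch(reml_multilevel(sub, moderator = rank, intercept = FALSE),
                    error = function(e) NULL)
    if (is.null(res)) return(NULL)
    cbind(winners_losers(res, rank = rank), subset = label,
          stringsAsFactors = FALSE)
  }
  if ("class" %in% ranks)
    out[[length(out) + 1L]] <- run(eff, "class", "all")
  for (rank in setdiff(ranks, "class")) {
    for (nm in names(COMPONENT_SUBSETS)) {
      sub <- eff[eff$component %in% COMPONENT_SUBSETS[[nm]], , drop = FALSE]
      if (nrow(sub) >= 2L)
        out[[length(out) + 1L]] <- run(sub, rank, nm)
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Export the taxonomy as a Newick tree annotated with trend calls
#'
#' Builds the kingdom-to-genus hierarchy from the taxonomy table as a tree
#' with unit branch lengths (the dendrogram carries no phylogenetic
#' distances) and suffixes every node whose label has a winner/loser call
#' with `positive` or `negative`; all other nodes get `none`.
#'
#' @param calls calls data frame from [winners_losers_by_rank()] (or
#'   [winners_losers()]).
#' @param taxonomy taxonomy data frame.
#' @param path optional file to write the Newick string to.
#' @return the Newick string, invisibly if `path` is given.
#' @export
annotate_taxonomy_tree <- function(calls, taxonomy, path = NULL) {
  taxonomy <- validate_taxonomy(taxonomy)
  ranks <- c("kingdom", "phylum", "class", "order", "family", "genus")
  call_of <- function(label) {
    hit <- calls$call[calls$level == label]
    if (!length(hit)) return("none")
    hit <- hit[1L]
    if (hit == "winner") "positive" else if (hit == "loser") "negative"
    else "none"
  }
  clean <- function(x) gsub("[^A-Za-z0-9_.]", "_", x)
  build <- function(sub, depth) {
    if (depth > length(ranks)) return(character(0))
    rank <- ranks[depth]
    labs <- unique(sub[[rank]])
    labs <- labs[!is.na(labs) & labs != ""]
    vapply(labs, function(lb) {
      kids <- build(sub[sub[[rank]] == lb, , drop = FALSE], depth + 1L)
      node <- sprintf("%s__%s", clean(lb), call_of(lb))
      if (length(kids))
        sprintf("(%s)%s:1", paste(kids, collapse = ","), node)
      else sprintf("%s:1", node)
    }, character(1))
  }
  tops <- build(taxonomy, 1L)
  nwk <- if (length(tops) == 1L && grepl("^\\(", tops))
    paste0(tops, ";") else sprintf("(%s)root:0;", paste(tops, collapse = ","))
  # validate by round-tripping through ape
  tr <- ape::read.tree(text = nwk)
  if (is.null(tr)) stop("internal error: Newick export failed to parse")
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}
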