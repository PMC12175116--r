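#' seatrend: seascape-wide synthesis of population trends
#'
#' Tools to classify long-term abundance monitoring series into nine trend
#' types, summarise them by year-weighted vote counts, pool linear slopes in
#' multilevel random-effects meta-analyses across taxonomic ranks, and model
#' the yearly direction of change with mixed binomial/multinomial logit
#' models. A synthetic monitoring-data generator with known ground truth
#' supports calibration, power, and recovery checks without external data.
#'
#' @keywords internal
#' @importFrom stats AIC aggregate anova as.formula binomial coef
#'   complete.cases fitted glm lm logLik median na.omit optim pchisq pnorm
#'   poisson predict qnorm quantile residuals rbinom rlnorm rnbinom rnorm
#'   rpois runif sd setNames shapiro.test var vcov
#' @importFrom utils read.csv write.csv head
"_PACKAGE"

#' Construct a set of monitoring records
#'
#' Validates a long-format table of abundance observations: one row per
#' station, taxon and year (possibly repeated within a year before annual
#' aggregation).
#'
#' @param station_id,taxon_id character or factor identifiers.
#' @param year integer calendar years (1900--2100). A `Date` (or a string
#'   parseable as a date) is reduced to its calendar year.
#' @param abundance non-negative numeric (counts or biomass).
#' @param component ecosystem component label, e.g. `"phytoplankton"`,
#'   `"fish"`, `"birds"`; the label set is open.
#' @return a `data.frame` of class `monitoring_records` with columns
#'   `station_id`, `taxon_id`, `year`, `abundance`, `component`.
#' @export
monitoring_records <- function(station_id, taxon_id, year, abundance,
                               component = "unspecified") {
  year <- to_year(year)
  n <- length(year)
  df <- data.frame(station_id = as.character(station_id),
                   taxon_id = as.character(taxon_id),
                   year = year,
                   abundance = as.numeric(abundance),
                   component = rep_len(as.character(component), n),
                   stringsAsFactors = FALSE)
  bad <- which(df$abundance < 0)
  if (length(bad)) {
    stop("negative abundance at rows: ",
         paste(sprintf("%d (station=%s, taxon=%s, year=%d)", bad,
                       df$station_id[bad], df$taxon_id[bad], df$year[bad]),
               collapse = "; "))
  }
  if (any(df$year < 1900 | df$year > 2100, na.rm = TRUE))
    stop("year outside [1900, 2100]")
  class(df) <- c("monitoring_records", "data.frame")
  df
}

to_year <- function(x) {
  if (inherits(x, "Date")) return(as.integer(format(x, "%Y")))
  if (is.character(x)) {
    # accept either plain years or ISO dates
    looks_date <- grepl("-", x, fixed = TRUE)
    out <- integer(length(x))
    out[looks_date] <- as.integer(substr(x[looks_date], 1L, 4L))
    out[!looks_date] <- suppressWarnings(as.integer(x[!looks_date]))
    return(out)
  }
  as.integer(x)
}

#' Aggregate monitoring records to annual means per population
#'
#' A population is one taxon at one station. Within each population, records
#' sharing a calendar year are averaged (arithmetic mean); years without any
#' record stay absent — no zero-filling or interpolation is performed.
#'
#' @param records a `monitoring_records` data frame (or any data frame with
#'   the same columns).
#' @return a list of [population_series()] objects, one per
#'   (station, taxon) pair.
#' @export
aggregate_annual_means <- function(records) {
  stopifnot(nrow(records) > 0)
  if (any(records$abundance < 0))
    stop("negative abundance in records; aggregation refused")
  key <- interaction(records$station_id, records$taxon_id, drop = TRUE,
                     sep = "\r")
  out <- lapply(split(seq_len(nrow(records)), key), function(idx) {
    sub <- records[idx, , drop = FALSE]
    m <- tapply(sub$abundance, sub$year, mean)
    yrs <- as.integer(names(m))
    o <- order(yrs)
    population_series(station_id = sub$station_id[1L],
                      taxon_id = sub$taxon_id[1L],
                      years = yrs[o], values = as.numeric(m)[o],
                      component = sub$component[1L])
  })
  names(out) <- NULL
  out
}

#' A single population time series
#'
#' Annual mean abundance of one taxon at one station on strictly increasing
#' observation years. `span` is the population's own monitoring period
#' (last - first + 1); `n_obs` the number of years actually observed.
#'
#' @param station_id,taxon_id identifiers.
#' @param years strictly increasing integer vector of observed years.
#' @param values non-negative annual mean abundances, same length as `years`.
#' @param component ecosystem component label.
#' @return an object of class `population_series`.
#' @export
population_series <- function(station_id, taxon_id, years, values,
                              component = "unspecified") {
  years <- as.integer(years)
  values <- as.numeric(values)
  stopifnot(length(years) == length(values), length(years) >= 1L)
  if (is.unsorted(years, strictly = TRUE))
    stop("years must be strictly increasing")
  if (any(values < 0)) stop("values must be non-negative")
  structure(list(station_id = as.character(station_id),
                 taxon_id = as.character(taxon_id),
                 years = years, values = values,
                 component = as.character(component),
                 span = years[length(years)] - years[1L] + 1L,
                 n_obs = length(years)),
            class = "population_series")
}

#' @exportS3Method base::print
print.population_series <- function(x, ...) {
  cat(sprintf("<population_series> %s @ %s (%s): %d obs over %d-%d (span %d)\n",
              x$taxon_id, x$station_id, x$component, x$n_obs,
              x$years[1L], x$years[x$n_obs], x$span))
  invisible(x)
}

#' Inclusion filter for population series
#'
#' A series qualifies for trend fitting when it has at least `min_years`
#' observed years and is present in at least a fraction `min_presence` of its
#' monitoring period. By default the monitoring period is the population's
#' own first-to-last observed year; set `period = "station"` and supply
#' `station_span` to measure presence against the station's full period.
#'
#' @param series a [population_series()].
#' @param min_years minimum number of observed years (default 5).
#' @param min_presence minimum fraction of the period with observations
#'   (default 0.5).
#' @param period `"series"` (default) or `"station"`.
#' @param station_span span in years of the station's monitoring period; used
#'   only when `period = "station"`.
#' @return `TRUE` or `FALSE`.
#' @export
inclusion_filter <- function(series, min_years = 5L, min_presence = 0.5,
                             period = c("series", "station"),
                             station_span = NULL) {
  period <- match.arg(period)
  span <- if (period == "station") {
    if (is.null(station_span)) stop("station_span required for period='station'")
    as.numeric(station_span)
  } else series$span
  series$n_obs >= min_years && (series$n_obs / span) >= min_presence
}

#' Read monitoring records from CSV
#'
#' Column names are mapped through `schema`, a named list (or path to a YAML
#' file holding one) with entries `station`, `taxon`, `year` *or* `date`,
#' `abundance`, and optionally `component`. Rows with unparseable year or
#' abundance, or negative abundance, are dropped and counted in the attached
#' ingest report.
#'
#' @param path CSV file path.
#' @param schema named list or YAML file path mapping roles to column names.
#' @return `monitoring_records` with attribute `ingest_report`
#'   (list: `rows_read`, `rows_kept`, `rows_dropped`, `reasons`).
#' @export
read_monitoring_csv <- function(path, schema = list(station = "station_id",
                                                    taxon = "taxon_id",
                                                    year = "year",
                                                    abundance = "abundance",
                                                    component = "component")) {
  if (is.character(schema) && length(schema) == 1L)
    schema <- yaml::read_yaml(schema)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("station", "taxon", "abundance")
  for (role in need)
    if (is.null(schema[[role]]) || !schema[[role]] %in% names(raw))
      stop("schema role '", role, "' missing or not a column of ", path)
  ycol <- if (!is.null(schema$year) && schema$year %in% names(raw))
    schema$year
  else if (!is.null(schema$date) && schema$date %in% names(raw))
    schema$date
  else stop("neither year nor date column found in ", path)

  n0 <- nrow(raw)
  year <- to_year(raw[[ycol]])
  abun <- suppressWarnings(as.numeric(raw[[schema$abundance]]))
  bad_year <- is.na(year) | year < 1900 | year > 2100
  bad_abun <- is.na(abun) | abun < 0
  keep <- !(bad_year | bad_abun)
  comp <- if (!is.null(schema$component) && schema$component %in% names(raw))
    raw[[schema$component]] else "unspecified"
  comp <- rep_len(comp, n0)
  rec <- monitoring_records(raw[[schema$station]][keep],
                            raw[[schema$taxon]][keep],
                            year[keep], abun[keep], comp[keep])
  attr(rec, "ingest_report") <- list(
    rows_read = n0, rows_kept = sum(keep), rows_dropped = n0 - sum(keep),
    reasons = c(bad_year = sum(bad_year), bad_abundance = sum(bad_abun & !bad_year)))
  rec
}

#' Read a taxonomy table from CSV
#'
#' Expects a `taxon_id` column plus the seven Linnaean rank columns
#' `kingdom, phylum, class, order, family, genus, species` (missing ranks may
#' be empty). Validates that each `taxon_id` maps to a single consistent rank
#' path.
#'
#' @param path CSV file path.
#' @return a `data.frame` with one row per taxon.
#' @export
read_taxonomy_csv <- function(path) {
  tax <- read.csv(path, stringsAsFactors = FALSE)
  validate_taxonomy(tax)
}

TAXONOMY_RANKS <- c("kingdom", "phylum", "class", "order", "family",
                    "genus", "species")

validate_taxonomy <- function(tax) {
  stopifnot("taxon_id" %in% names(tax))
  for (r in TAXONOMY_RANKS) if (!r %in% names(tax)) tax[[r]] <- ""
  tax$taxon_id <- as.character(tax$taxon_id)
  dup <- split(seq_len(nrow(tax)), tax$taxon_id)
  for (idx in dup) {
    if (length(idx) > 1L) {
      sub <- unique(tax[idx, TAXONOMY_RANKS, drop = FALSE])
      if (nrow(sub) > 1L)
        stop("taxon_id '", tax$taxon_id[idx[1L]],
             "' maps to conflicting rank paths")
    }
  }
  tax[!duplicated(tax$taxon_id), c("taxon_id", TAXONOMY_RANKS)]
}

#' Write a result table to CSV
#'
#' Plain `write.csv` without row names, so that [read_result_csv()] returns
#' the table field-for-field.
#'
#' @param x data frame.
#' @param path output path.
#' @export
write_result_csv <- function(x, path) {
  write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_result_csv
#' @export
read_result_csv <- function(path) read.csv(path, stringsAsFactors = FALSE)
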