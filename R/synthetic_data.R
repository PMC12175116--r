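#' Default archetype parameters on the ln(abundance + 1) scale
#'
#' Shapes are parameterised by the series span `T` (years from first to last
#' observation) so every archetype keeps its geometry at any length:
#' linear trends change by `slope` per year; accelerating/decelerating
#' quadratics traverse a total change of 1.5 ln-units with the derivative
#' growing (or shrinking) ninefold over the period; unimodal trends place
#' their vertex mid-period (configurable) with an amplitude of 0.9 ln-units.
#'
#' @param archetype one of the nine trend-type labels.
#' @param T span minus one (number of year steps); i.e. `last - first`.
#' @param slope linear slope per year for the linear archetypes.
#' @param vertex vertex position in year steps for unimodal archetypes
#'   (default `T/2`).
#' @param b0 baseline intercept on the ln scale; `NULL` (default) uses 3,
#'   raised where needed so the mean curve stays above 0.5 ln-units (an
#'   explicit value is taken literally).
#' @return list with `b0`, `b1`, `b2` (centred-year polynomial
#'   coefficients).
#' @export
archetype_params <- function(archetype, T, slope = 0.1, vertex = T / 2,
                             b0 = NULL) {
  auto_b0 <- is.null(b0)
  if (auto_b0) b0 <- 3
  stopifnot(T >= 1)
  par <- switch(archetype,
    neutral = c(0, 0),
    positive_linear = c(slope, 0),
    negative_linear = c(-slope, 0),
    positive_accelerating = c(0.3 / T, 1.2 / T^2),
    negative_accelerating = c(-0.3 / T, -1.2 / T^2),
    positive_decelerating = c(2.7 / T, -1.2 / T^2),
    negative_decelerating = c(-2.7 / T, 1.2 / T^2),
    unimodal_pos_to_neg = {
      cc <- 3.6 / T^2
      c(2 * cc * vertex, -cc)
    },
    unimodal_neg_to_pos = {
      cc <- 3.6 / T^2
      c(-2 * cc * vertex, cc)
    },
    stop("unknown archetype: ", archetype))
  mu_range <- par[1] * c(0, T) + par[2] * c(0, T^2)
  vtx <- if (par[2] != 0) -par[1] / (2 * par[2]) else NA_real_
  if (!is.na(vtx) && vtx > 0 && vtx < T)
    mu_range <- c(mu_range, par[1] * vtx + par[2] * vtx^2)
  shift <- if (auto_b0) max(0, 0.5 - (b0 + min(mu_range))) else 0
  list(b0 = b0 + shift, b1 = par[1], b2 = par[2])
}

#' Simulate one population series with known ground truth
#'
#' The mean curve is linear or quadratic in centred year on the
#' `ln(x+1)` scale (equivalently the log-count scale for the count
#' families). Noise families: `lognormal` adds Gaussian noise of standard
#' deviation `sigma` on the ln scale (`x = exp(mu + e) - 1`, floored at 0);
#' `poisson` draws counts with mean `exp(mu)`; `negbin` draws overdispersed
#' counts with the same mean and size parameter `theta`.
#'
#' @param archetype one of the nine trend-type labels.
#' @param years integer vector of observation years.
#' @param noise `"lognormal"`, `"poisson"` or `"negbin"`.
#' @param sigma ln-scale noise standard deviation (lognormal family).
#' @param theta negative binomial size (smaller = more overdispersed).
#' @param slope,vertex,b0 passed to [archetype_params()] (`vertex` in year
#'   steps from the first year).
#' @param station_id,taxon_id,component series labels.
#' @param seed optional integer seed.
#' @return a [population_series()] with attribute `truth` (list:
#'   `archetype`, `b0`, `b1`, `b2`, `mode_year`, `noise`, `sigma`).
#' @export
simulate_population <- function(archetype, years, noise = "lognormal",
                                sigma = 0.2, theta = 2, slope = 0.1,
                                vertex = NULL, b0 = NULL,
                                station_id = "s1", taxon_id = "t1",
                                component = "unspecified", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  years <- as.integer(sort(years))
  t <- years - years[1L]
  T <- max(t)
  if (is.null(vertex)) vertex <- T / 2
  pp <- archetype_params(archetype, T, slope = slope, vertex = vertex,
                         b0 = b0)
  mu <- pp$b0 + pp$b1 * t + pp$b2 * t^2
  if (any(mu < 0) && noise != "lognormal")
    stop("negative mean on the count scale; raise b0")
  values <- switch(noise,
    lognormal = pmax(exp(mu + rnorm(length(t), 0, sigma)) - 1, 0),
    poisson = rpois(length(t), exp(mu)),
    negbin = rnbinom(length(t), size = theta, mu = exp(mu)),
    stop("unknown noise family: ", noise))
  s <- population_series(station_id, taxon_id, years, values, component)
  attr(s, "truth") <- list(
    archetype = archetype, b0 = pp$b0, b1 = pp$b1, b2 = pp$b2,
    mode_year = if (pp$b2 != 0) years[1L] - pp$b1 / (2 * pp$b2) else NA_real_,
    noise = noise, sigma = sigma)
  s
}

# Series lengths mimicking real multi-program monitoring: 5-91 years with
# median near 30 (discretised lognormal, clipped).
sample_series_lengths <- function(n) {
  len <- round(rlnorm(n, meanlog = log(30), sdlog = 0.45))
  pmin(pmax(len, 5L), 91L)
}

# Default archetype mixture approximating a seascape-wide monitoring
# synthesis: ~61% neutral, more negative than positive directional trends,
# and a tail of unimodal reversals.
MIXED_ARCHETYPE_PROBS <- c(
  neutral = 0.609, positive_linear = 0.076, positive_accelerating = 0.020,
  positive_decelerating = 0.020, negative_linear = 0.126,
  negative_accelerating = 0.030, negative_decelerating = 0.030,
  unimodal_pos_to_neg = 0.055, unimodal_neg_to_pos = 0.034)

#' Simulate a multi-component monitoring seascape
#'
#' Generates a long-format monitoring table, a balanced synthetic taxonomy
#' (abstract labels, kingdom to species) and a ground-truth table. Presets:
#' \describe{
#'   \item{`mixed`}{the default archetype mixture over several ecosystem
#'     components with per-component noise families.}
#'   \item{`null`}{every population neutral — the calibration scenario.}
#'   \item{`classbias`}{two classes whose species carry linear slopes
#'     centred at +0.05 and -0.05 — the winner/loser recovery scenario.}
#'   \item{`flip`}{every population unimodal positive-to-negative with the
#'     vertex at `flip_year` steps after the series start — the
#'     synchronised-reversal scenario.}
#' }
#'
#' @param preset scenario name.
#' @param n_stations stations per component.
#' @param n_species species per component.
#' @param n_components number of ecosystem components.
#' @param n_years fixed series length in years (`NULL`, the default, draws
#'   lengths from the 5--91-year distribution with median 30).
#' @param start_year first calendar year of the simulated period.
#' @param sigma ln-scale noise standard deviation for lognormal components.
#' @param slope linear slope magnitude for directional archetypes.
#' @param class_effect class-mean slope for the `classbias` preset.
#' @param class_sd species-to-species slope spread around the class mean.
#' @param flip_year vertex position (year steps) for the `flip` preset.
#' @param seed integer seed.
#' @return list: `records` (`monitoring_records`), `taxonomy` (data frame),
#'   `truth` (data frame with per-population archetype and coefficients),
#'   `series` (list of [population_series()]).
#' @export
simulate_seascape <- function(preset = c("mixed", "null", "classbias",
                                         "flip"),
                              n_stations = 4L, n_species = 12L,
                              n_components = 3L, n_years = NULL,
                              start_year = 1980L, sigma = 0.25,
                              slope = 0.1, class_effect = 0.05,
                              class_sd = 0.02, flip_year = 15,
                              seed = NULL) {
  preset <- match.arg(preset)
  if (!is.null(seed)) set.seed(seed)
  comp_names <- c("phytoplankton", "macrozoobenthos", "fish", "birds",
                  "plants", "zooplankton")[seq_len(n_components)]
  noise_of <- c(phytoplankton = "lognormal", macrozoobenthos = "negbin",
                fish = "lognormal", birds = "poisson", plants = "lognormal",
                zooplankton = "negbin")
  series <- list(); truth <- list(); tax <- list()
  for (ci in seq_len(n_components)) {
    comp <- comp_names[ci]
    noise <- if (preset == "mixed") noise_of[[comp]] else "lognormal"
    for (si in seq_len(n_species)) {
      taxon <- sprintf("%s_sp%02d", comp, si)
      cls <- if (preset == "classbias") {
        sprintf("Class_%s", if (si <= n_species / 2) "A" else "B")
      } else sprintf("Class_%s_%d", LETTERS[ci], 1L + (si - 1L) %/%
                       max(1L, n_species %/% 2L))
      tax[[taxon]] <- data.frame(
        taxon_id = taxon, kingdom = "Kingdom_1",
        phylum = sprintf("Phylum_%s", LETTERS[ci]), class = cls,
        order = sprintf("%s_ord%d", cls, 1L + (si - 1L) %/% 3L),
        family = sprintf("%s_fam%d", cls, 1L + (si - 1L) %/% 2L),
        genus = sprintf("Genus_%s", taxon), species = taxon,
        stringsAsFactors = FALSE)
      sp_slope <- if (preset == "classbias") {
        rnorm(1, ifelse(grepl("_A$", cls), class_effect, -class_effect),
              class_sd)
      } else slope
      for (st in seq_len(n_stations)) {
        station <- sprintf("%s_st%02d", comp, st)
        len <- if (is.null(n_years)) sample_series_lengths(1L) else n_years
        years <- seq(start_year, start_year + len - 1L)
        arch <- switch(preset,
          null = "neutral",
          flip = "unimodal_pos_to_neg",
          classbias = if (sp_slope >= 0) "positive_linear" else
            "negative_linear",
          mixed = sample(names(MIXED_ARCHETYPE_PROBS), 1L,
                         prob = MIXED_ARCHETYPE_PROBS))
        vertex <- if (preset == "flip") flip_year else NULL
        s <- simulate_population(arch, years, noise = noise, sigma = sigma,
                                 slope = abs(sp_slope), vertex = vertex,
                                 station_id = station, taxon_id = taxon,
                                 component = comp)
        tr <- attr(s, "truth")
        series[[length(series) + 1L]] <- s
        truth[[length(truth) + 1L]] <- data.frame(
          station_id = station, taxon_id = taxon, component = comp,
          archetype = arch, b0 = tr$b0, b1 = tr$b1, b2 = tr$b2,
          mode_year = tr$mode_year, noise = noise,
          class_mean = if (preset == "classbias")
            ifelse(grepl("_A$", cls), class_effect, -class_effect)
          else NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  }
  records <- do.call(rbind, lapply(series, function(s)
    data.frame(station_id = s$station_id, taxon_id = s$taxon_id,
               year = s$years, abundance = s$values,
               component = s$component, stringsAsFactors = FALSE)))
  class(records) <- c("monitoring_records", "data.frame")
  list(records = records, taxonomy = do.call(rbind, tax),
       truth = do.call(rbind, truth), series = series)
}

#' Simulate a meta-analysis effect table with known class means
#'
#' Draws slopes directly at the effect-size level: two (or more) classes
#' with given true mean slopes, station random effects of variance
#' `sigma2_station`, and per-effect sampling variances uniform on
#' `v_range`; the observed slope adds sampling noise of variance `v`.
#' Used for parameter-recovery and CI-coverage checks of the multilevel
#' meta-analysis without re-fitting population trends.
#'
#' @param class_means named numeric vector of true class mean slopes.
#' @param n_stations number of stations.
#' @param species_per_class species per class (one effect per species per
#'   station subset; each species appears at one station).
#' @param sigma2_station between-station variance.
#' @param v_range range of sampling variances.
#' @param seed optional integer seed.
#' @return effect table as from [build_effect_table()] (with a `class`
#'   column and `truth` attribute).
#' @export
simulate_effect_table <- function(class_means = c(Class_A = 0.05,
                                                  Class_B = -0.05),
                                  n_stations = 30L, species_per_class = 30L,
                                  sigma2_station = 0.001,
                                  v_range = c(1e-4, 1e-3), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  u_st <- rnorm(n_stations, 0, sqrt(sigma2_station))
  rows <- list()
  for (cl in names(class_means)) for (sp in seq_len(species_per_class)) {
    # every class is observed across the same station network, as in a real
    # monitoring programme where one station records taxa of many classes
    st <- 1L + (sp - 1L) %% n_stations
    v <- runif(1, v_range[1], v_range[2])
    rows[[length(rows) + 1L]] <- data.frame(
      station_id = sprintf("st%02d", st),
      taxon_id = sprintf("%s_sp%d", cl, sp), component = "synthetic",
      slope = class_means[[cl]] + u_st[st] + rnorm(1, 0, sqrt(v)), v = v,
      n_obs = NA_integer_, span = NA_integer_, class = cl,
      taxonomy_ok = TRUE, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "truth") <- list(class_means = class_means,
                             sigma2_station = sigma2_station)
  out
}

#' Write a simulated seascape to CSV files
#'
#' @param sim result of [simulate_seascape()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly; writes `monitoring.csv`,
#'   `taxonomy.csv`, `truth.csv`.
#' @export
write_seascape <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_result_csv(sim$records, file.path(dir, "monitoring.csv"))
  write_result_csv(sim$taxonomy, file.path(dir, "taxonomy.csv"))
  write_result_csv(sim$truth, file.path(dir, "truth.csv"))
  invisible(dir)
}
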