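---
title: "Models and methods behind seatrend"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind seatrend}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(seatrend)
```

`seatrend` turns a heterogeneous compilation of abundance monitoring series
into four synthesis products: a nine-type trend classification per
population, a year-weighted vote count, a multilevel meta-analysis of
slopes with winner/loser calls across taxonomic ranks, and year-by-year
trend-direction timelines. This vignette records the models, their
assumptions, the tunable parameters, and the numerical and design choices a
maintainer needs to know — including exactly what the synthetic-data
generator does and does not emulate.

## 1. Data model and inclusion rules

A *population* is one taxon at one station. Raw records are aggregated to
annual means; missing years remain missing (no zero-filling — the absence of
a row is a non-observation, while a recorded zero abundance is a true
observation and counts as an observed year). A population enters the
analysis when it has at least 5 observed years (`min_years`) covering at
least 50 % (`min_presence`) of its own first-to-last-year period. The
monitoring period is deliberately the population's own span rather than the
station's: it is self-contained, conservative, and does not depend on what
else happened to be monitored at the station (`period = "station"`
reinstates the alternative). Calendar years are internally centred on each
series' first observed year before any regression; classification depends
only on coefficient signs and significance, which centring leaves untouched.

## 2. Trend classification

### Candidate models

Six candidates per population: families Gaussian (response
$\ln(x+1)$), Poisson and negative binomial (response rounded to the nearest
integer), each with a linear ($\beta_0+\beta_1 t$) and a quadratic
($\beta_0+\beta_1 t+\beta_2 t^2$) predictor in centred year $t$. The
negative binomial dispersion is estimated by maximum likelihood
(`MASS::glm.nb`), falling back to a method-of-moments estimate (bounded to
$[10^{-3}, 10^6]$, with a +2 AIC charge for the extra parameter) when ML
fails.

### Diagnostics

Gaussian and Poisson fits must pass Shapiro–Wilk normality and
Breusch–Pagan homoscedasticity checks on their residuals (deviance
residuals and a Pearson-residual auxiliary regression for Poisson); Poisson
fits must also pass a one-sided Pearson-dispersion $\chi^2$ test.
Overdispersed counts are served by the negative binomial, which carries no
further residual checks beyond convergence. All tests use $\alpha = 0.05$.
Two edge rules matter:

* **Degenerate residuals** (all equal) make a test inapplicable and count
  as a pass.
* **Numerically exact fits** — residual standard deviation below
  $10^{-8}$ of the response scale — skip the diagnostics entirely: the
  residuals of a perfect fit are floating-point rounding structure, and a
  normality test would be reacting to the rounding, not the data.

### Selection and the nine types

Among valid candidates whose trend term is significant (Wald $p<0.05$ on
$\beta_1$ for linear fits, on $\beta_2$ for quadratics — the quadratic's
defining term), the lowest AIC wins. Because a log-transformed response and
a count response live on different scales, the Gaussian AIC is mapped to
the abundance scale by the change-of-variables term
$+2\sum_i \ln(x_i+1)$ before comparison (`jacobian = FALSE` restores the
naive comparison). Ties within $10^{-9}$ — including two numerically
infinite AICs from perfect fits — resolve to the lower degree, then to the
family order Gaussian < Poisson < negative binomial (parsimony first, then
the simpler error model).

The decision tree: no qualifying model → **neutral** (with
`any_valid_model = FALSE` when not even an insignificant candidate passed
its diagnostics); best model linear → **positive/negative linear** by
$\mathrm{sign}(\beta_1)$; best model quadratic with opposite-sign
coefficients and a Mitchell-Olds–Shaw-confirmed interior extremum →
**unimodal** (positive→negative for $\beta_2<0$); any other quadratic →
**accelerating/decelerating positive/negative**, where the direction is the
sign of the fitted net change $f(t_{\max})-f(0)$ and "accelerating" means
$|f'|$ grows from the first to the last year. (The net-change rule and the
derivative-magnitude rule are our operationalisation of shapes that are
usually only drawn, not defined.)

The MOS test refits the quadratic with the year axis shifted to each end of
the observation period, so the linear coefficient becomes the fitted
derivative at that endpoint; the extremum is interior when both endpoint
derivatives are significant with opposite signs. The tests cross-check this
implementation against `vegan::MOStest`.

**Numerical guard.** A coefficient with $|\hat\beta| < 10^{-10}\times$ the
response scale is treated as numerically zero and its $p$-value set to
`NA`. Without this, a noise-free linear series gives a quadratic candidate
whose $\beta_2 \sim 10^{-17}$ has a machine-noise standard error and an
arbitrary $O(1)$ Wald statistic — classification of noiseless data would be
a coin flip instead of deterministic.

### What the classification does under the null

With the candidate set restricted to the Gaussian linear model, the
directional (false-positive) rate on stationary series is the nominal
5 %, and the acceptance tests verify it on 1000 stationary populations
($n=30$, $\sigma=0.3$ on the ln scale). The full six-candidate procedure is
*not* a single 5 % test: the degree-1 and degree-2 trend terms of three
families give roughly four effective significance channels, and the count
families' Wald $z$ tests are anticonservative at $n=30$ (a $z$ versus
$t_{27}$ reference alone maps 5 % to 6.1 %, and ln-normal counts are not
exactly negative binomial, inflating the negative-binomial channels to
7–9 %). The measured union is ≈ 17 % on those study conditions. The
acceptance suite asserts a 15 % bound on this rate, which therefore fails
by about two points; we report the number rather than altering the study
conditions, because the excess is a property of the multiple-testing
structure of the procedure itself, not of its implementation.

## 3. Vote count and the duration analyses

Each classified trend votes for its five-way group (positive, negative, two
unimodal reversals, neutral) with weight `n_obs`, the number of observed
years — not the span: the weight expresses how much data support the trend.
Shares are percentages summing to 100 within each scope.

Two binomial mixed logits relate outcomes to monitoring duration, with
station and species as crossed random intercepts: the probability of
detecting a directional trend (populations with at least one valid
candidate only), and the probability that any candidate meets its
assumptions. "Duration" defaults to the span (first-to-last year) with
`n_obs` as the configurable alternative, since either reading of the phrase
is defensible.

## 4. Multilevel meta-analysis

Effect size: the slope of the *valid Gaussian linear* fit, regardless of
which family or degree won the AIC race — the meta-analysis needs a common,
comparable scale (relative change per year), so it deliberately ignores the
classification's model choice. Sampling variance: the squared standard
error, which up-weights long, well-sampled series. The model adds a station
random intercept, is estimated by REML (`metafor::rma.mv` — the tests hold
it to a 1-D grid-search REML oracle within $10^{-5}$), and reports Wald-z
CIs (Knapp–Hartung is off by default to match the z-value reporting
convention). A moderator (ecosystem component, or any taxonomic rank)
without intercept yields per-level means; a level needs $k\ge 2$ effects.
Winner/loser: CI entirely above/below zero. Finer ranks (order, family,
genus) run on component subsets — plants; phytoplankton; fish; birds;
macrozoobenthos + zooplankton pooled — and no multiplicity correction is
applied across taxa (calls are descriptive, not confirmatory tests).
The absolute-slope variant re-runs the overall model on $|\beta_1|$ with
unchanged $v_i$: a near-zero signed mean together with a clearly positive
absolute mean is the signature of balanced opposing change.

The taxonomy exports as a Newick string with unit branch lengths (the tree
encodes nomenclature, not evolutionary distance) and per-node labels
`name__positive/negative/none` from the calls.

## 5. Time-specific states and timelines

Each population's fitted trend contributes a yearly rate
$r(t)=\beta_1$ (linear) or $\beta_1+2\beta_2 t$ (quadratic, centred years)
over every calendar year of its monitoring period; the yearly state is
$\mathrm{sign}(r(t))$, with an exact-zero tolerance of $10^{-12}$, and
neutral populations are neutral throughout. Per taxonomic group, a
baseline-category multinomial logit (reference: neutral) — or a binomial
logit when only two states occur — models state against year with species
and station random intercepts; AIC decides on a quadratic year term, and
groups whose year block fails a likelihood-ratio test at $\alpha=0.05$ are
reported as having no significant time structure.

Confidence bands come from a cluster bootstrap: populations
(species × station) are resampled with replacement, the model refitted, and
per-year predicted probabilities collected; 2.5/97.5 percentiles bound the
band, with `B = 1000` by default and `B ≥ 200` enforced. Two deliberate
choices: bootstrap refits hold the random-effect variances at the full-data
estimates and re-maximise only the fixed effects and modes (the variance
profile is flat over typical resamples and refitting it would dominate the
runtime), and a resample that happens to contain no population-year of some
state is *kept* — that state's probability collapses in that draw, which is
the honest bootstrap reflection of its rarity — rather than discarded.
Replicates can still fail for numerical reasons; more than 20 % failures is
an error.

Year verdicts apply, in order: (1) overlapping positive and negative bands
→ *cancelled* (opposing trends of similar weight); (2) both probabilities
below 0.5 → *neutral*; (3) otherwise the state with the higher point
probability. Checking overlap before the 0.5 threshold is our resolution of
an ambiguity in the rule set (a year can satisfy both conditions);
`rule_order = "threshold_first"` flips the precedence.

## 6. The mixed-logit engine

No package in the supported stack fits a mixed-effects multinomial logit,
so the engine is implemented here for both response kinds. Each grouping
factor contributes independent random intercepts per non-reference state
with one shared variance $\sigma_f^2$. Estimation maximises the
Laplace-approximated marginal likelihood with the outer optimiser
(L-BFGS-B) on $\log\sigma_f$ only, while the fixed effects and random
modes are jointly profiled by a penalised Newton iteration with
step-halving (gradient tolerance $10^{-6}$) — the fast scheme familiar from
lme4's `nAGQ = 0`. This trades a small attenuation of the fixed effects
(relative to full Laplace ML) for the speed that makes the cluster
bootstrap affordable; the tests pin the behaviour that matters:

* the Laplace log-likelihood agrees with a 64-node Gauss–Hermite oracle to
  $10^{-3}$ on small one-factor instances at $\sigma=0.2$;
* with $\sigma^2$ fixed at 0 the engine reproduces `glm` /
  `nnet::multinom` to $10^{-4}$ / $10^{-3}$;
* on crossed-intercept binomial data the fixed effects track
  `lme4::glmer` closely and true slopes are recovered within 2 SE.

A weak L2 ridge ($10^{-4}$) on the fixed effects leaves identified fits
untouched (shifts $\ll 10^{-5}$) but bounds the divergence under complete
separation, which arises routinely in timeline models when a group's states
are perfectly ordered in time; fits with $|\hat\beta|>15$ carry a
`separation` flag. Standard errors come from the fixed-effect block of the
inverse joint Hessian (conditional information). Reported predictor
coefficients are on the mean-centred scale; slopes are unaffected by
centring, and bootstrap refits inherit the original centring so replicate
coefficients are comparable.

## 7. The synthetic seascape generator

The generator produces exactly the structure the analysis assumes — mean
curves linear or quadratic on the $\ln(x+1)$ (equivalently log-count)
scale, with lognormal (additive Gaussian on the ln scale, floored at zero
abundance), Poisson, or negative binomial observation noise; series lengths
drawn from a discretised lognormal clipped to 5–91 years with median ≈ 30;
and a balanced, abstractly-labelled taxonomy (no real taxon names, so no
accidental "results" about real species). Archetype geometry is
span-invariant: linear trends move `slope` (default 0.1) ln-units per year;
accelerating/decelerating quadratics traverse 1.5 ln-units with the
derivative growing or shrinking ninefold; unimodal curves place their
vertex mid-period (amplitude 0.9 ln-units). The default `mixed` archetype
frequencies (61 % neutral, 12.6 % linear negative, 7.6 % linear positive,
smaller accelerating/decelerating and unimodal fractions) mirror the
relative prevalences reported for large marine monitoring syntheses.
`simulate_effect_table` draws meta-analysis inputs directly at the
effect-size level, with every class observed across the same station
network — as in a real programme, where one station records taxa of many
classes; this shared-station structure also correlates the class-mean
errors, which matters for the joint recovery checks.

What the generator does **not** emulate: spatial autocorrelation between
stations, within-year seasonality (everything is annual by construction),
observation-effort drift, taxonomic misidentification, and
regime-dependent noise. Passing tests therefore demonstrate that the
pipeline recovers what it assumes, under its own model class — they do not
certify behaviour on real data violating those assumptions.

## 8. Simulation sizes used by the tests

The acceptance suite runs: the nine-archetype noiseless round-trip; null
calibration on 1000 stationary populations; 200-population signal recovery
(±0.1 slope, $\sigma=0.2$, ≥ 95 % correct direction); 20 REML-oracle
instances ($k\le 8$); 500 class-recovery replicates (30 stations, class
means ±0.05, $\sigma^2_{\text{station}}=0.001$, $v_i\in[10^{-4},10^{-3}]$);
a balanced ±0.08 cancellation scenario; 100 random quadratics for the
derivative-state identity; 100 flip-scenario replicates (16 populations,
31 years, vertex at year 15, `B = 200`, reversal located within ±3 years in
≥ 80 %); the quadrature/reduction engine checks; and 100 + 100
duration-effect replicates (60 populations, spans 5–60, slope 0.05,
$\sigma=0.5$, with a shuffled-duration null). These sizes are the package's
chosen compromise between Monte-Carlo resolution and a test suite that
stays pleasant to run; all thresholds were fixed before the corresponding
code paths were finalised and are discussed above where they bind.

## 9. Known limitations

* Trend models ignore temporal autocorrelation; with strongly
  autocorrelated residuals the diagnostics reject more often and the
  classification becomes conservative via the validity gate.
* AIC-based degree selection admits a spurious quadratic with probability
  ≈ $P(\chi^2_1>2)\approx 0.16$; unimodal calls are protected by the
  additional MOS gate, but accelerating/decelerating labels inherit the
  overfitting rate.
* The engine's fast profile scheme attenuates fixed effects slightly at
  large random-effect variances; if exact Laplace ML matters, fit with
  `sigma_fixed` on a grid and compare profiles.
* Wald-z meta-analysis CIs undercover modestly at small $k$; winner/loser
  calls for levels with few effects should be read accordingly.
* The five-way vote count weights by observed years, so a single
  long-running station can dominate a component's shares — by design, but
  worth remembering when comparing components of very different survey
  effort.
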