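---
title: "Assessing population exposure to peat-fire smoke with low-cost sensors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing population exposure to peat-fire smoke with low-cost sensors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(peatsmoke)
library(dplyr)
```

## The problem

Tropical peatlands in Indonesia burn extensively during El Niño dry
seasons. Peat fires smoulder below ground for weeks, and their PM2.5
emissions dominate regional air quality, yet both the emissions and the
population's exposure are poorly constrained: reference-grade monitors are
sparse, burn depth is rarely observed, and most of the day is spent
indoors, where ambient model output does not apply directly.

`peatsmoke` implements an exposure-assessment chain that addresses each
link: quality control and humidity correction for low-cost optical PM2.5
sensors; a per-fire emission model whose peat burn depth scales with soil
moisture; indoor concentrations inferred from observed indoor/outdoor
(I/O) ratios; time-activity weighting from pebble-allocation
questionnaires; and air-quality category tallies over a population grid.
A synthetic-data generator with known ground truth makes the whole chain
testable end to end without any external downloads.

## Sensor quality control

Optical particle counters overread at high relative humidity because
hygroscopic particles swell. Raw 2-minute CF_1 readings are corrected by
the RH-growth model

$$PM_{adj} = \frac{PM_{CF1}}{1 + \dfrac{0.24}{100/RH - 1}},$$

with RH first clipped to 30–70% (`clip_rh()`) to avoid over-correction at
the extremes — necessary here, since fire-season humidity sits above 70%
for roughly three quarters of all readings. The correction is applied at
the native 2-minute resolution, before any averaging, because it is
defined on instantaneous readings; with constant humidity within an hour
the order does not matter, and a test pins that equivalence.

Each monitor carries two independent counters. An hour is discarded as
discordant when the two hourly channel means differ by more than 50% of
their mean (strict inequality; boundary equality passes). Hourly means
require strictly more than 75% of the expected 2-minute samples, and
daily (UTC) means require strictly more than 75% of usable hours — hours
lost to discordance or incompleteness count as missing at the daily
level. These two defaults resolve questions the QC protocol leaves open;
both are parameters (`min_frac`, and exclusion tables for known channel
failures). When one channel is missing but not excluded, the other is
passed through and the hour marked `single_channel` (reduced confidence)
rather than discarded.

## Peat-fire emissions

For a fire detected on peatland, the emitted mass of species $s$ is

$$E_s = BA \times BD \times \rho \times EF_s,$$

with burned area $BA$ fixed at 40 ha per peat-fire detection (100 ha for
surface fires), peat density $\rho = 0.11$ g cm$^{-3}$ and
$EF_{PM2.5} = 22.3$ g kg$^{-1}$. Burn depth $BD$ is the link to drought:
at or above an upper soil-moisture threshold fires burn to 5 cm, at or
below a lower threshold to 37 cm, linearly in between. The threshold pair
is the key uncertain tuning; `sweep_thresholds()` recomputes the whole
emission scenario for a list of candidate pairs, and
`evaluate_scenarios()` + `select_best_scenario()` choose the pair whose
dispersed concentrations best match the sensor observations (lowest RMSE,
ties broken by |NMBF| then NMAEF).

```{r}
tp <- threshold_pair(0.5, 0.1)
burn_depth(c(0.05, 0.3, 0.9), tp)
emission_mass(ba_ha = 40, bd_cm = 37, rho_g_cm3 = 0.11, ef_g_kg = 22.3)
```

Each hotspot-day is treated as an independent fire: multi-day smouldering
is not modelled, which is a recognised source of uncertainty. Soil
moisture is sampled at the hotspot's containing grid cell for that day.
Emission records are assigned wholly to their containing cell-day, so
gridding conserves mass exactly; burn-depth summaries (mean/max) are
per-record, i.e. hotspot-day weighted.

## Evaluation statistics

Model–observation agreement is scored on pooled daily pairs (all outdoor
sites stacked; per-site tables are also emitted) with Pearson $r$, RMSE,
and the sign-symmetric normalized mean bias and absolute error factors:

$$NMBF = \begin{cases}\bar m/\bar o - 1 & \bar m \ge \bar o\\ 1 - \bar o/\bar m & \bar m < \bar o\end{cases}
\qquad
NMAEF = \frac{\sum_i |m_i - o_i|}{\sum_i o_i \text{ or } \sum_i m_i},$$

the denominator of NMAEF following the same branch as NMBF. These factor
forms treat over- and under-prediction symmetrically (swapping the
arguments flips the sign of NMBF exactly) and satisfy
$NMAEF \ge |NMBF|$, both of which are property-tested against brute-force
recomputation.

## From outdoor fields to population exposure

The observed I/O ratio converts modeled outdoor concentrations to indoor
ones ($Mod_{in} = Mod_{out} \times I/O$). The default ratio is the pooled
dry-season median of *fire-derived* daily ratios — each series minus its
own wet-season mean — so persistent indoor sources do not inflate the
inferred infiltration of smoke. Negative fire-derived values are retained
(not clipped); days with non-positive fire-derived outdoor values are
excluded from the ratio, which is required to be positive.

Daily exposure weights the two micro-environments by the time budget:

$$Exposure = \frac{c_{in}\,t_{in} + c_{out}\,t_{out}}{24},$$

with the budget either fixed or aggregated from questionnaires in which
each respondent splits exactly 24 pebbles (hours) between home and up to
three livelihoods, indoor versus outdoor. Aggregation is two-stage —
means per location, then across locations — so unevenly sampled villages
carry equal weight.

Exposure is classified per cell-day into five categories with inclusive
upper bounds: good ≤ 12.0, moderate ≤ 55.4, unhealthy ≤ 150.4, very
unhealthy ≤ 250.4, dangerous above (µg m$^{-3}$). Only the 55.4 boundary
is fixed by the "unhealthy or worse" convention this package follows; the
full ladder adopts the US EPA 24-hour PM2.5 breakpoints with the
"sensitive groups" band folded into moderate to keep five labels, and the
scheme is fully overridable. Population tallies sum the population of the
cells in each category and partition the total exactly every day; both
daily and weekly (`weekly_mean_field()`) cadences are available. WHO
(15 µg m$^{-3}$) and Indonesian (65 µg m$^{-3}$) guideline exceedances
are separate booleans, independent of the category ladder.

## The synthetic scenario

`gen_scenario()` builds every input on one shared grid and date axis with
the injected truth retained:

- **Sensor network.** Outdoor truth is a baseline (default 40 µg m$^{-3}$)
  plus a *spatially homogeneous* dry-season Gaussian fire hump (peak
  160 µg m$^{-3}$, centred 65% through the dry season), matching the
  observation that fire smoke raises concentrations across sites
  together; that homogeneity is what makes I/O-ratio recovery well posed.
  Indoor truth is the site's injected ratio times outdoor truth plus
  episodic 2-hour indoor bursts. Channels A and B are independent noisy
  copies (default SD 5 µg m$^{-3}$ — sensor noise is not observationally
  constrained, so it is a parameter, not a constant), and raw CF_1 values
  include the hygroscopic overread implied by the drawn RH (mean 78%, SD
  10.4%, ~78% of draws above 70%), so QC genuinely has work to undo. An
  optional failure site ramps outdoor channel A to +1500 µg m$^{-3}$
  within five days, emulating a foreign-object fault; at most one channel
  fails per scenario.
- **Fire scene.** Domain-mean soil moisture declines monotonically
  (half-cosine) from 0.45 to 0.08 m$^3$ m$^{-3}$ at the driest day, then
  recovers within 15 days; the daily hotspot count is a deterministic
  decreasing function of mean soil moisture, so the driest day carries
  the maximum and wet days carry none. The southern half of the domain is
  peat; 85% of hotspots fall there.
- **Dispersion toy.** Emissions are spread with a per-source-normalised
  Gaussian kernel (width 2 cells), which conserves mass exactly on the
  closed domain, scaled to concentration (1.5 × 10⁻⁶ µg m$^{-3}$ per gram
  of daily cell mass, chosen so the default scene's dry-season
  enhancement is of order 90 µg m$^{-3}$) and added to a uniform
  25 µg m$^{-3}$ background. This is a smoothing kernel, not atmospheric
  physics: no transport, chemistry or meteorology. The without-fires
  field is the background alone, so the fire contribution is non-negative
  and exactly linear in emissions.
- **Population and questionnaires.** Lognormal cell weights emulate
  settlement clustering (deterministic shares when explicit weights are
  given); each synthetic respondent allocates 24 integer pebbles with
  per-pebble indoor probability `mean_indoor_hours / 24`.

All randomness flows through one seed with fixed per-component
sub-streams, so adding a component never perturbs another and identical
seed + parameters reproduce a scenario bit-for-bit.

What passing tests on this scenario do **not** show: performance on real
sensor data with drift, temperature effects or non-Gaussian noise; real
fire detection and burned-area errors; real transport. The generator's
role is to verify the *pipeline's* algebra and recovery properties under
known truth, not to validate the science against the field.

## Numerical and design choices

- Period defaults: pre-dry Aug 16–31, dry Sep 1–Oct 31, wet Nov 1–Dec 1;
  all configurable and validated as disjoint.
- Completeness and concordance thresholds are strict inequalities;
  boundary cases (exactly 75% complete, channel difference exactly half
  the mean) pass/fail deterministically as documented above.
- Sites on a cell edge snap to the lower-index cell, a deterministic
  tie-break used both for soil-moisture lookup and field extraction.
- Medians are the standard midpoint convention; even counts average the
  two central values.
- Scenario selection is invariant to row order: ties beyond NMAEF fall
  back to the scenario name.
- Degenerate inputs error early: empty date ranges, non-positive
  cadences, inverted thresholds, negative raw PM2.5 at ingest, budgets
  not summing to 24, category ladders that are not strictly increasing.

A full synthetic run (10 × 10 grid, 120 days, 5 sites, 2-minute cadence)
executes in well under five minutes on one CPU; the test-suite examples
use coarser cadences (6–20 minutes) and smaller grids where the property
under test does not need the full problem size.

## A worked run

```{r, eval = FALSE}
run <- run_pipeline(pipeline_config(
  seed = 7,
  grid = grid_spec(nlon = 10, nlat = 10),
  dates = seq(as.Date("2023-08-16"), as.Date("2023-12-01"), by = "day"),
  truth = list(n_sites = 5, true_io_ratio_per_site = 0.9)
))
tidy(run$sweep)       # total Tg and burn depths per threshold pair
tidy(run$evaluation)  # pooled r / RMSE / NMBF / NMAEF per scenario
run$io_ratio          # pooled dry-season fire-derived median (~0.90)
autoplot(run$sweep); autoplot(run$evaluation)
plot_exposure_tally(run$tallies)
```

## Known limitations

The dispersion stand-in cannot reproduce observed spatio-temporal
structure beyond smooth plumes, so evaluation metrics on synthetic runs
measure *relative* scenario ranking, not absolute model skill. Surface
(non-peat) fire emissions are accepted only as a pass-through field.
Exposure uses two micro-environments; vehicles, workplaces with
filtration, and demographic stratification are out of scope, as are
health-impact (concentration–response) calculations.
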