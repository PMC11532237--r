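# peatsmoke

Population exposure to PM2.5 from tropical peatland fires, from raw
low-cost-sensor records to people-per-air-quality-category tallies.

During El Niño dry seasons, fires on drained Indonesian peatland smoulder
below ground and dominate regional PM2.5. Quantifying who breathes what
requires stitching together several weakly constrained pieces: noisy
dual-channel optical sensors that overread in humid air, fire emissions
whose burn depth nobody measures directly, indoor concentrations that
ambient models do not provide, and time budgets that decide how much of
the day each concentration applies to. `peatsmoke` implements that chain
as composable, tested functions with tibbles in and out:

- **Sensor QC** (`qc_hourly()`, `qc_daily()`) — RH-growth correction of
  raw CF\_1 readings, `PM_adj = PM_CF1 / (1 + 0.24 / (100/RH − 1))` with
  RH clipped to 30–70%; channel-concordance flagging (hours where the two
  channels differ by more than 50% of their mean); strict >75%
  completeness rules at hourly and daily level.
- **Peat emissions** (`fire_emissions()`, `sweep_thresholds()`) — per-fire
  mass `E_s = BA × BD × ρ × EF_s` with burn depth BD scaled linearly from
  5 cm to 37 cm between an upper and a lower soil-moisture threshold;
  mass-conserving gridding; threshold-pair sweeps.
- **Evaluation** (`evaluate_scenarios()`, `select_best_scenario()`) —
  Pearson r, RMSE and the sign-symmetric normalized mean bias / absolute
  error factors (NMBF, NMAEF) on pooled daily model–observation pairs;
  scenario selection by lowest RMSE.
- **Exposure** (`compute_io_ratio()`, `time_weighted_exposure()`,
  `tally_population()`) — indoor/outdoor ratios, fire-derived baselines,
  `Exposure = (c_in·t_in + c_out·t_out)/24`, five air-quality categories
  (unhealthy starts strictly above 55.4 µg m⁻³), and per-day population
  tallies with and without fires.
- **Synthetic data** (`gen_scenario()` and friends) — every input with
  known injected truth, so the whole chain is testable offline.
- **Pipeline** (`pipeline_config()`, `validate_config()`,
  `run_pipeline()`) — validated config, deterministic seeded runs, a
  manifest, and CSV outputs; a thin CLI lives in `inst/cli/peatsmoke.R`.

## Worked example

```r
library(peatsmoke)

run <- run_pipeline(pipeline_config(
  seed = 7,
  grid = grid_spec(nlon = 10, nlat = 10),
  dates = seq(as.Date("2023-08-16"), as.Date("2023-12-01"), by = "day"),
  truth = list(n_sites = 5, true_io_ratio_per_site = 0.9)
))
run
#> <peatsmoke_run>
#>   best emission scenario: 0.45/0.1
#>   I/O ratio: 0.897; budget 15.9 h indoor / 8.1 h outdoor

tidy(run$sweep)
#> # A tibble: 4 × 6
#>   scenario upper_sm lower_sm total_tg_PM25 mean_bd_cm max_bd_cm
#> 1 0.5/0.25     0.5      0.25         0.402       34.9        37
#> 2 0.5/0.1      0.5      0.1          0.351       30.4        37
#> 3 0.45/0.1     0.45     0.1          0.341       29.5        37
#> 4 0.35/0.1     0.35     0.1          0.311       26.8        37
```

The sweep table reads like an emission-scenario summary: each candidate
soil-moisture threshold pair produces a total dry-season PM2.5 emission
(Tg) and the mean/max burn depth over all hotspot-days; wider threshold
bands assign deeper burns and larger totals. `tidy(run$evaluation)` holds
the pooled daily metrics per scenario, and `run$best_scenario` is the
RMSE minimiser. The recovered I/O ratio (0.897 here) is the pooled
dry-season median of fire-derived daily indoor/outdoor ratios and sits
within noise of the injected 0.9; the time budget (15.9 h indoor) is the
two-stage mean of the synthetic pebble questionnaires. `run$tallies`
counts people per air-quality category per day, with and without fires —
`plot_exposure_tally(run$tallies)` draws the stacked time series.

Individual stages work standalone, e.g.

```r
burn_depth(c(0.05, 0.3, 0.9), threshold_pair(0.5, 0.1))
#> [1] 37 21  5
time_weighted_exposure(90, 100, time_budget(16.2, 7.8))
#> [1] 93.25
```

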