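# dylld — social disparities in heat-attributable years of life lost

Epidemiologists studying heat and health usually ask *how many* deaths hot
days cause. This package asks *how unequally* the burden falls. It implements
a daily index of social disparity in years of life lost (YLL), models its
relation to temperature, and projects how climate change will scale the
disparity — as a complete, tested analysis pipeline driven by a synthetic
data generator, because individual death records of this kind cannot be
shared.

It is written for environmental-epidemiology and climate-health researchers
who want to apply (or scrutinize) the approach on their own mortality, life
table and climate-scenario data, all exchanged as plain delimited text.

## The method in brief

1. **YLL**: each death contributes its remaining life expectancy at the sex
   and completed age of death, from a single-year life table. (Administrative
   descriptions sometimes say "life expectancy at birth matched by age and
   sex"; this package uses the standard remaining-life-expectancy
   construction and documents the distinction in the methods vignette.)
2. **DYLLD** (daily YLL disparity): stratify each day's YLL total by terciles
   of an area-deprivation indicator (% adults without a high-school diploma)
   and average the excess of the non-reference terciles over the most
   advantaged one:
   `DYLLD_d = mean_j( dYLL_{j,d} - dYLL_{ref,d} )`.
3. **Exposure–response**: a hockey-stick quasi-Poisson GLM of DYLLD on
   same-day temperature, `log E[DYLLD_d] = a + b (T_d - tau)+ + season +
   trend + humidity`, with the threshold `tau` selected by profile deviance
   over a 1 °C grid and the slope interval calibrated for that search.
4. **Attributable burden**: summer DYLLD attributable to above-threshold
   heat, per 100,000 persons — attributable-fraction form `(RR-1)/RR` on the
   observed series for historical estimates, constant-baseline excess
   `(RR-1)` for projections.
5. **Projection**: 30-member climate-scenario ensembles, bias-corrected by
   empirical quantile–quantile mapping; the impact of climate change (ICC)
   is each scenario's future/historical ratio of attributable rates.
6. **Meta-analysis**: DerSimonian–Laird random-effects pooling of ICCs
   (log scale) and warming deltas per city; cities compared by z-tests and
   by random-effects meta-regression of the 2×30 per-scenario outcomes on a
   city indicator.

The synthetic generator (`simulation_config()`, `generate_*()`) encodes every
designed parameter — per-tercile heat effects above a known threshold, AR(1)
summer weather, Gompertz life tables, scenario bias and warming — as ground
truth that the pipeline's estimates are tested against.

## Worked example

```r
library(dylld)

cfg     <- simulation_config(n_years = 10L, seed = 42)   # 10 synthetic summers
weather <- generate_temperature_series(cfg)
lifetab <- generate_life_table()
deaths  <- generate_deaths(cfg, weather, lifetab)
daily   <- aggregate_daily(assign_terciles(deaths), lifetab, weather$date)
disp    <- dylld_series(daily)                           # daily disparity (years)

fit <- fit_exposure_response(disp, weather)
fit
#> DYLLD-temperature threshold model (quasi-poisson-log)
#>   threshold: 21.0 degC (422 days above, of 920 used)
#>   slope above threshold: 0.0905 per degC (SE 0.0223)
#>   47.2% of days had negative DYLLD floored at 0

rate <- attributable_rate(fit, population = 1.8e6, mode = "observed-dylld", seed = 1)
#> historical attributable rate: 13.0 y per 100,000 per summer (95% CI 7.4-17.8)

ens    <- generate_scenario_ensemble(cfg)                # 30 scenarios
imp    <- scenario_impacts(fit, ens, weather, population = 1.8e6, seed = 1)
pool_icc(imp$icc[!imp$excluded], imp$log_icc_se[!imp$excluded])
#> pooled estimate 1.7269 (95% CI 1.6718 to 1.7839), k = 30, tau^2 = 0.008095
```

Reading: over these 10 synthetic summers the disparity starts rising at
21 °C (the design planted 23 °C; a 10-summer study resolves the breakpoint
only coarsely — the shipped 18-summer analysis recovers 23), each degree
above the threshold multiplies the disparity by `exp(0.0905) ≈ 1.09`, heat
accounts for 13 years of life lost *disparity* per 100,000 residents per
summer, and under the scenario ensemble that burden grows by a pooled factor
of 1.73 between the historical and future periods.

## The analysis workflow

`analysis/01_simulate.R` … `analysis/05_meta.R` run the full two-city study
(an 18-summer index city and a 6-summer reference city, each with a
30-member scenario ensemble), writing small tables under `results/tables/`:
descriptives, disparity summaries, exposure-response fits and RR curves,
per-scenario impacts, pooled and between-city contrasts. Each script is a
thin driver over the package functions and prints what it found; pass
`--seed <int>` to change the study seed (default 1). `run_pipeline()` runs
the same chain end to end with a hashed manifest of every artifact.

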