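---
title: "Modelling social disparities in heat-attributable years of life lost"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling social disparities in heat-attributable years of life lost}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dylld)
```

## The question and the index

Heat kills unevenly: within a city, mortality on hot days rises more in
deprived neighbourhoods than in affluent ones. This package quantifies that
inequality on the scale of *years of life lost* (YLL) rather than death
counts, so that deaths at younger ages — more frequent in deprived areas —
weigh more.

Each death contributes its remaining life expectancy at the sex and completed
age of death, read from a single-year life table. (Some administrative
sources describe this quantity loosely as "life expectancy at birth matched
by age and sex"; we use the standard YLL construction, remaining life
expectancy at death, and say so here because the two readings differ by
almost an order of magnitude in the daily totals.) Daily YLL totals are
stratified by terciles of an area-level deprivation indicator — the
percentage of adults without a high-school diploma, on a 0–100% scale, where
higher means more deprived. The daily disparity index is the mean excess of
the non-reference terciles over the most advantaged (reference) tercile:

$$\mathrm{DYLLD}_d \;=\; \frac{1}{J}\sum_{j=1}^{J}\left(\mathrm{dYLL}_{j,d} - \mathrm{dYLL}_{\mathrm{ref},d}\right),$$

with $J = 2$ non-reference terciles here. The index is linear, invariant to
adding a constant to all groups, and can be negative on days when the
advantaged tercile happens to carry the larger burden; negative days are kept
in the series and handled explicitly by the exposure model.

### Tercile cuts

Cut points are the 1/3 and 2/3 empirical quantiles (inverse-CDF, type 1) of
the indicator over **all deaths** of the study period — deaths-weighted, not
area-weighted — with ties going to the less-deprived group. One consequence
worth knowing: if deprivation raises a group's overall share of deaths (not
just its hot-day share), the deaths-weighted cut migrates into the deprived
band and relabels a near-constant share of deaths across groups. That offsets
the *level* of the disparity series — it can even make its long-run mean
negative — while leaving its *response to temperature* essentially intact,
which is what the exposure model estimates. The test suite checks the
designed disparity sign on the generator's true strata and the heat response
under empirical cuts separately.

## Exposure–response model

The daily disparity is related to same-day (lag 0) mean temperature through a
hockey-stick model inside a GLM:

$$g\!\left(E[\mathrm{DYLLD}_d]\right) = \alpha + \beta\,(T_d - \tau)_+ +
s(\text{day of summer}) + \gamma\,\text{year} + \delta\,\text{humidity}_d ,$$

* family: quasi-Poisson with log link by default, treating the (floored)
  disparity as a nonnegative intensity; then $RR(t) = e^{\beta (t-\tau)_+}$
  and $RR = 1$ at or below the threshold. A Gaussian identity family is
  available as a sensitivity option, with $RR$ formed relative to the period
  mean.
* negative-disparity days are floored at 0 before a log-link fit
  (`floor_negative_dylld = TRUE`); the floored fraction is recorded on the
  fit object. With a symmetric noise floor this is roughly half of all
  below-threshold days, and the flooring acts like a constant absorbed by the
  intercept.
* season: natural cubic spline of day-of-summer with 3 df; trend: linear in
  year (factor or none as options); humidity: linear (or none). All are
  confounder adjustments, not effects of interest.
* threshold $\tau$: profile deviance over a 1 °C grid. The grid is aligned
  to whole multiples of the grid step and restricted to the 50th–98th
  percentile window of observed temperature; alignment matters, because a
  grid anchored at the data-dependent 50th percentile systematically misses
  round-number thresholds.

### Inference after threshold selection

Because $\tau$ is selected by searching the grid, the usual $\pm 1.96\,SE$
interval for $\beta$ is anti-conservative: under a true null the search picks
the candidate whose slope looks most extreme. At a *fixed* threshold the
quasi-Poisson interval is well calibrated, so the package corrects only for
the search: the candidate slope estimates are jointly asymptotically normal
linear functionals of the daily series, their correlation matrix follows
from the candidate design matrices and working weights, and the reported
`slope_ci` uses the 0.95 quantile of $\max_i |Z_i|$ over that correlated
Gaussian vector (single-step adjustment, computed by fixed-seed Monte Carlo
that does not disturb the caller's RNG stream). This sits between the naive
1.96 (too narrow here) and a Bonferroni-style 2-df bound (too wide, because
neighbouring hinge terms are highly correlated). The suite verifies null
coverage lands in the nominal band over 100 simulated null studies.

## Attributable burden

Two attributable forms are deliberately distinct:

* **observed-dylld** (historical estimates):
  $\sum_{d:\,T_d>\tau} \mathrm{DYLLD}_d \,\frac{RR(T_d)-1}{RR(T_d)}$ — the
  attributable-fraction form applied to the observed series;
* **constant-baseline** (projections):
  $\sum_{d:\,T_d>\tau} \overline{\mathrm{DYLLD}}\,(RR(T_d)-1)$ — an excess
  form on the period-mean disparity, usable for future periods where no
  disparity series exists.

Either sum is divided by the number of summers and expressed per 100,000
persons. Standard errors come from 1,000 seeded multivariate-normal draws of
the model coefficients (percentile 95% intervals).

## Climate-scenario projection

Each scenario supplies daily summer temperature for a 30-year historical and
a 30-year future period. Scenario series are bias-corrected against observed
temperatures by empirical quantile–quantile mapping calibrated on the
historical period: matched order statistics when the calibration series have
equal length (which makes the calibration identities exact), otherwise
type-7 quantiles at plotting positions of the shorter series (≤ 2000 knots);
values beyond the calibration range shift by the endpoint offset, keeping the
map monotone. Mapping pools all summer days rather than mapping per calendar
month — with 92-day summer seasons the within-summer cycle is small relative
to the day-to-day noise.

The impact of climate change (ICC) for a scenario is the ratio of future to
historical constant-baseline attributable rates, with the fitted model and
population held fixed (no acclimatization, no demographic change). The
baseline disparity and the population cancel algebraically in the ratio —
asserted numerically in the suite — so the ICC reduces to the ratio of summed
excess relative risks. Its log-scale SE reuses the same coefficient draws in
numerator and denominator, honouring their correlation.

## Meta-analysis across scenarios and cities

Per-scenario estimates are pooled by DerSimonian–Laird random-effects
meta-analysis (method-of-moments $\tau^2$ floored at 0, weights
$1/(SE^2+\tau^2)$, normal-theory CIs with $z = \Phi^{-1}(0.975)$); ICCs are
pooled on the log scale and exponentiated. REML was considered and not
adopted: the moment estimator is closed-form, deterministic, and standard
for scenario ensembles of this size. Cities are compared by a z comparison
of pooled estimates and by random-effects meta-regression of the 2×30
per-scenario outcomes on a 0/1 city indicator (WLS with method-of-moments
residual $\tau^2$). Future rates are regressed on the natural-log scale;
the ICC contrast is also run on the identity scale, where the city
coefficient reads directly as an ICC difference. The implementation is
in-package (the estimators are part of the method); `metafor` serves as an
independent cross-check in the tests.

## What the synthetic generator emulates — and what it does not

The generator is first-class, tested code: every designed parameter is a
ground truth that downstream stages must recover.

* **Weather**: daily mean temperature = within-summer sinusoid (amplitude
  1.5 °C, peak July 15) + stationary AR(1) noise (lag-1 correlation 0.55);
  the noise variance is set so the *marginal* SD of the series equals
  `temp_sd_c` (20.4 ± 3.24 °C by default, a typical northern-city summer).
  Humidity is i.i.d. Gaussian (70 ± 10%) truncated to [0, 100].
* **Life table**: Gompertz hazard $h(x) = a e^{bx}$ with $b = 0.09$; the
  male level is solved for a life expectancy at birth of 77 y and the female
  level for a +4 y gap, by adaptive quadrature of the conditional survival
  curve.
* **Deaths**: per day and tercile, Poisson with mean
  $\text{baseline} \times p_j \times e^{\beta_j (T_d-\tau)_+}$ — the heat
  effect acts on counts, and the disparity's response *emerges* from
  aggregation, mirroring the real data-generating process. Defaults: 37
  deaths/day (≈ 3,400 per 92-day summer), equal tercile probabilities,
  threshold 23 °C, and $\beta = (0.06, 0.03, 0.01)$ per °C for the
  (low, mid, high)-SES terciles. The gradient was chosen a priori so that a
  J-shaped, tercile-ordered response is visible over an 18-summer study —
  at +5 °C above threshold the deprived tercile's RR is ≈ 1.35, in the range
  reported for deprived groups in the heat-mortality literature. Ages at
  death are truncated-Gaussian (78 ± 12, on [35, max age]); sexes equal;
  the SES indicator is uniform within its tercile's band of the 0–100%
  scale.
* **Scenario ensemble**: 30 members; each historical series carries a mean
  bias drawn from N(0, 1 °C²) — the miscalibration quantile mapping must
  remove — and each future series adds a warming delta drawn from
  N(1.35, 0.25² °C), consistent with mid-century warming of order 1.1–1.4 °C
  for such cities. Per-output-type RNG streams are derived from the master
  seed by fixed offsets, so adding scenarios never perturbs the death series.

Not emulated, hence not demonstrated by passing tests: spatial structure
(neighbourhood maps), multi-day heat-wave episodes and distributed lags
(only lag 0 is modelled), mortality displacement, cause-of-death coding,
demographic or acclimatization trends, and any dependence of humidity on
temperature. Daily YLL totals are of order 400 y/day under the default
ages — lower than figures produced by life-expectancy-at-birth weighting;
all rate comparisons in the package are internally consistent on the
remaining-life-expectancy scale.

## Numerical choices and degenerate inputs

* Tercile cuts: type-1 quantiles; ties at a cut go to the less-deprived
  group; all-identical indicator values are a configuration error.
* Zero-death days are kept as explicit zeros so the modelling series is
  complete; a death dated outside the calendar is an error naming the date.
* GLM convergence is tightened to `epsilon = 1e-12` so that fits agree with
  an independent IRLS implementation to well beyond 6 significant figures.
* Candidate thresholds where the GLM fails to converge are dropped from the
  profile; if all fail, the fit errors with the grid range. Fewer than 10
  days above the selected threshold leaves a recorded warning on the fit.
* A scenario with a zero historical attributable rate has an undefined ICC;
  it is flagged, excluded from pooling, and warned about.
* Quantile mapping requires ≥ 30 calibration values per series.
* The end-to-end driver writes only plain text with metadata headers
  (package version, configuration hash, seed — never timestamps), so a rerun
  of the same configuration is byte-identical, manifest hashes included.

## Problem sizes

The shipped analysis uses an 18-summer index city and a 6-summer reference
city (92-day summers; ≈ 3,200–3,400 deaths per summer each), 30 scenarios per
city with 30-year periods, and 1,000 coefficient draws per uncertainty
propagation. The simulation-based checks use 50 seeds for threshold recovery,
100 for null calibration, and 100 replicates for meta-regression coverage;
module tests run on 3–10-summer configurations.
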