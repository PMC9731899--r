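---
title: "Methods: IDW-residualized boosted trees for PM2.5 exposure surfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: IDW-residualized boosted trees for PM2.5 exposure surfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(aerosurf)
```

## The estimation problem

A metropolitan region is covered by a grid of square ~1 km cells; a few
dozen monitors report hourly PM2.5.  We want, for *every* cell and day, two
quantities: the daily mean concentration and the daily 1-h maximum.  The
monitors are the only direct observations; satellite aerosol optical depth
(AOD), a chemistry-model PM field, meteorology, and road density are
available everywhere and carry indirect signal.

The region of interest is defined topographically: the largest
edge-connected set of grid cells at or below 3 km above sea level
(`region_mask()`), reflecting a high plateau ringed by mountains that trap
pollution.  Connectivity is 4-neighbour: square cells share a boundary
only along edges, so diagonal ridges do not join components.  Coordinates
are planar meters; at a ~130 km domain the geodesic correction to planar
distances is negligible, so no geodesy is used anywhere.

## Targets and ingest rules

A station-day enters the analysis only if it has at least 18 distinct
observed hours (`aggregate_station_days()`, `min_hours = 18`); its targets
are the mean and the max of the available hourly values.  Days are civil
days at UTC−6 with no daylight-saving adjustment, and the loader refuses
timezone-annotated timestamps rather than converting them.  Hours are
counted as distinct clock hours carrying a valid value, not as wall-clock
span.  Duplicate station-hours and negative concentrations are hard errors:
both indicate corrupted input rather than missingness.

Seasons follow the region's three-season climatology — cold dry
(November–February), warm dry (March–May), rainy (June–October) — and all
seasonal stratifications pool across years.

## The residualized learner

Plain tree ensembles produce piecewise-constant surfaces.  To recover
spatial smoothness where it is warranted while keeping the trees'
flexibility, the dependent variable handed to xgboost is not the
concentration but the residual from an inverse-distance-weighted (IDW,
exponent 2) interpolation of all *other* same-day observations of the same
target; the interpolation is added back at prediction time
(`fit_exposure_model()`, `predict()`).  The IDW baseline is also one of
the 14 predictors, so the trees can modulate it.

Numerical conventions for the IDW kernel (`idw_interpolate()`):

* a target within 1 m of a source returns that source's value exactly
  (avoids division by zero; a station colocated with a cell centroid
  reproduces its own observation);
* weights are normalised before the weighted sum, so a single-source day
  returns that source's value bit-exactly;
* a day with no same-day source observation has an undefined baseline: the
  row is dropped (from training, or from the prediction surface) with a
  message, never imputed.

The objective is log-cosh, `L(r) = log cosh r`, a twice-differentiable
approximation to absolute loss (`logcosh_objective()`): gradient
`tanh(r)`, hessian `1 − tanh²(r)`, stable to |r| of 10⁴ and beyond.
Absolute loss is the right currency here because a minority of very high
concentrations would dominate squared loss.  The ensemble's base score is
pinned at 0 since the target is already a residual.  Training uses exact
(histogram-free) tree growth on a single thread by default so fits are
bit-reproducible; `nthread` trades that for speed.

Missing AOD values are passed through to the learner as missing — tree
learners route missing values natively — rather than imputed; imputation
would manufacture spatial information exactly where the satellite failed
to provide it.

### Hyperparameters

Four are tuned: number of trees in {10, 25, 50, 100}, maximum depth in
{3, 6, 9}, learning rate η in [0.01, 0.5], ridge penalty λ in
[2⁻¹⁰, 2¹⁰].  `sample_hyperparameters()` draws a maximin Latin hypercube
(via `lhs::maximinLHS`) on the unit 4-cube and maps it to the domains:
discrete axes by equal-width binning, η and λ on the log scale, since both
act multiplicatively.  Tuning (`tune_hyperparameters()`) is twofold
station-wise cross-validation scored by pooled MAE — MAE, not log-cosh,
because the objective is only a smooth stand-in for the absolute loss we
actually care about.  Ties break toward the earlier candidate, which makes
duplicated candidates deterministic.  One random station split is drawn
per tune call; with a single-station fold the IDW baseline is undefined on
the training side, so that direction is skipped (with a warning if nothing
remains scoreable).

## Leakage-aware evaluation

`loso_cv()` holds out one station per fold.  The subtle leak in this design
is the IDW predictor: computed naively it would carry the held-out
station's observations into every training row.  Every fold therefore
recomputes all baselines — training *and* test — from the source set minus
the held-out station, and hyperparameter tuning runs nested inside the
fold on training stations only.  The test suite verifies the guard by
bitwise-perturbing the held-out station's observations and checking that no
training-side feature changes, and that a deliberately leaky variant
(`include_held_out_in_idw = TRUE`) fails the same check.

Metrics (`compute_metrics()`) are absolute-loss-first: MAE against MAD
(mean absolute deviation of the observations from their median — the
spread a median-everywhere predictor would leave), with RMSE, SD and
`R² = 1 − MSE/variance` for completeness.  Variance and SD use the
population (divide-by-n) convention; the identity between R²,
MSE and variance holds under either convention as long as one is used
consistently, and per-stratum R² uses the stratum's own variance.

## Exposure applications

All applications consume an `exposure_surface` (cells × days).

* **Regulatory annual mean** (`regulatory_annual_mean()`): the mean of
  four 3-month means, per the Mexican annual standard.  Quarters are
  calendar quarters (Jan–Mar, …) — the standard's alignment had to be
  fixed somewhere, and calendar quarters are the documented choice.  On
  unbalanced data this deliberately differs from the plain mean; a
  missing quarter makes the cell-year missing, with a message.
* **Compliance** (`compliance_report()`): strict exceedance (">", i.e.
  *worse than* the limit) against the annual (10 μg/m³) and daily
  (41 μg/m³) limits; person-days are `Σ_cells persons × exceedance days`.
  The mean exceedance days per person is population-weighted, with the
  unweighted variant reported alongside.  Cell populations come from an
  exact area-weighted mean of a misaligned density raster
  (`populate_cells()`), both grids being axis-aligned so intersection
  areas are interval-overlap products.
* **Population ECDF** (`population_ecdf()`): the weighted ECDF of per-cell
  regulatory annual means; quantile queries return the smallest
  concentration at which the cumulative population fraction reaches p.
* **Max:mean ratio** (`daily_ratio_series()`): per day, the ratio of the
  spatial mean of the max surface to the spatial mean of the mean surface
  — collapsing across cells by averaging surfaces first; the per-cell
  alternative is available behind `per_cell_ratio`.  Days split at 1 mm
  mean per-cell precipitation.
* **Heat co-occurrence** (`heat_cooccurrence()`): Kendall tau-b between
  cell-day PM and temperature, conditional PM quartiles given temperature
  binned to 0.1 °C per season, and medians across the daily-limit and
  20 °C splits.  `kendall_tau()` is Knight's O(n log n) algorithm with
  full tie correction — several hundred thousand cell-days make the
  quadratic definition impractical — and is tested against an exhaustive
  pair-enumeration oracle.
* **Areal linkage** (`areal_link()`): each polygon unit gets the
  unweighted mean of the annual means of the cells whose centroids fall
  inside it; boundary centroids count as inside (a deterministic tie
  rule), units with no centroid are missing, and exposure is summarised
  against the marginalization score overall (tau-b) and in 0.5-unit score
  bins.  The annual value here is the plain calendar-year mean — the
  linkage summarises predictions, not regulatory compliance.
  Point-in-polygon is even-odd ray casting with an explicit on-edge test,
  cross-checked against a winding-number oracle and `mgcv::in.out`.

## The synthetic study region

`make_region_fixture()` + `make_truth_field()` + `simulate_observations()`
+ `simulate_predictors()` generate everything the analysis consumes, from
a seed.  The default conditions — a 20 × 20 grid of 927 m cells (~394
in-region cells), 8 stations, 2 calendar years, predictor informativeness
0.8, 10% hourly missingness, 6 scored polygons, 10⁶ residents — are a
deliberate down-scaling of the full study geometry (7745 cells, 25
stations, 16 years) that keeps a complete cross-validated analysis in the
minutes range; the structure, not the scale, is what the package's checks
exercise.

What the generator emulates:

* strictly positive, right-skewed concentrations (lognormal noise,
  station-day σ = 0.3);
* a diurnal multiplier profile with unit mean and its modal peak at a
  configurable hour (default 10), so daily means are preserved and the
  max:mean ratio is about 2;
* three seasons with lower concentrations in the rainy season, day-to-day
  autocorrelated regional anomalies, mild washout on ≥ 1 mm days;
* a positive coupling between a day's temperature anomaly and its PM
  (configurable, sign-reversible, severable: `temperature_coupling`,
  `seasonal_temperature`, `temperature_spatial_sd`);
* smooth spatial fields (Gaussian-kernel-smoothed noise; the spatial
  covariance of real residuals is unknown, so the smoothing range is an
  explicit knob, `spatial_range`);
* predictors as monotone transforms of truth blended with independent
  noise by an informativeness weight, AOD with realistic day/cell gaps,
  boundary layer and winds anti-correlated with PM, and 10:00 variants of
  the sub-daily layers;
* a population raster on its own, deliberately offset grid, and simple
  star-shaped scored polygons.

Two generator decisions deserve justification.  First, station noise is
split into a station-day lognormal factor (σ = 0.3) and a smaller
independent hourly jitter (σ = 0.15): if all noise were hourly-independent,
the sampled daily maximum would be an extreme-value artifact of the noise
rather than a reflection of the shared diurnal peak, and no spatial model
could — or should — predict it.  Real daily maxima ride a common
atmospheric cycle; the generator must reproduce that predictability for
the max target to be a meaningful benchmark.  Second, calibration
configurations: because the calendar couples PM and temperature through
their shared seasonal cycles, and because two independent smooth static
fields align by chance at small cell counts, the independence
configuration used for null calibration flattens the seasonal temperature
cycle, removes the static temperature field, and sets the coupling to 0
(or, equivalently, pairs the PM surface with an informativeness-0 measured
temperature, which is independent by construction).

What the generator does *not* emulate: satellite retrieval physics,
chemistry-model error structure, real geography or station siting,
instrument drift, or multi-network calibration differences.  Passing
checks on this fixture therefore demonstrate correctness of the machinery
and the qualitative orderings (model beats the MAD baseline and the
IDW-only surface; maxima are harder than means), not the quantitative
accuracy attainable on any real archive.

## Problem sizes and determinism

The packaged checks run the full cross-validated analysis at the default
conditions with 6-candidate tuning designs, the acceptance script with 10
candidates, and replicate-based calibrations at 25 cells × 400 days × 100
replicates — sizes chosen so a complete run stays in the minutes range on
one core.  The full-study tuning design of 25 candidates is available by
passing `sample_hyperparameters(25, seed)` anywhere a candidate table is
accepted.  Every stochastic step takes an explicit seed, xgboost runs
single-threaded with exact tree growth by default, and `run_pipeline()`
writes byte-identical reports across same-seed runs.

## Known limitations

* With very few stations, the nested twofold tuning split can produce
  one-station folds whose IDW baselines are undefined; those directions
  are skipped, and with only two stations tuning degenerates to the first
  candidate (with a warning).
* Days on which no station reports have undefined IDW baselines and are
  absent from surfaces; the applications assume such days are rare, as
  they are in a real monitoring archive.
* No uncertainty quantification is attached to predictions, and no
  ensemble averaging over learners is attempted.
* The marginalization linkage with 6 synthetic polygons yields a very
  coarse tau; it exercises the machinery, not the sociology.
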