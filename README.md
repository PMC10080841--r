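# hastack

Stacked-ensemble forecasting of daily hospital admission counts from lagged
admissions, air-quality, meteorological and calendar features — with
label-distribution-smoothing (LDS) re-weighting for imbalanced count targets
and a permutation-Shapley explanation layer.

## The problem

Hospitals planning bed and staff allocation need day-ahead forecasts of
admission counts for conditions, such as cerebrovascular disease, whose
incidence responds to short-term environmental exposure (particulate matter,
gaseous pollutants, temperature, humidity).  The daily series mixes a rising
multi-year trend, annual and weekly seasonality, holiday dips, and volatile
short-lag environmental effects; its extreme days — the peaks that matter
most for resource planning — are rare, so ordinary least-squares training
underfits them.

## The method

Given a daily panel `(date, y_t, P_t)` with `P ∈ {PM2.5, PM10, PMc, SO2,
NO2, CO, O3, AQI, TEM, RH}`, the package builds the supervised design of
single-day lags `x = 1..L` (default `L = 6`), cumulative lag means/SDs over
`[1, L]`, and calendar codes (DOW, MON, SEA, YEAR one-hot; TS, HOL, WD,
FWD, LWD), min–max normalized with training-set statistics
(`X' = (X − min X)/(max X − min X)`), and splits it chronologically
(years 1–3 train, year 4 test).

**Phase one.**  Four heterogeneous base learners — ridge regression, a
random forest, gradient-boosted trees, and a single-hidden-layer network —
are each fitted 5 times on chronological folds `S_1..S_5` of the training
block: the model for fold `i` is trained on all other folds and predicts
`S_i`, giving out-of-fold meta features
`M_j(X_train) = {P_j(X_1), …, P_j(X_5)}` (4 × 5 = 20 fits).  Each fold
model also predicts the test rows, and
`N_j(X_test) = (1/5) Σ_i Q_ji(X_test)` is the test-side meta feature.

**Phase two.**  An elastic net (squared error + combined L1/L2 penalty) is
fitted on `(M_1..M_4, key features)`, where the key features are the
original calendar and lagged-admissions columns, and scores
`(N_1..N_4, key features)` for the final forecast.

**LDS re-weighting.**  Within each calendar year the training labels are
binned (width 1 count), the empirical bin density is convolved with a
symmetric kernel (Gaussian, size 5, σ = 2 by default) to form the
*effective* label density, and each row is weighted by its inverse —
up-weighting rare peak/trough days — before the meta fit.

**Evaluation and explanation.**  Models are compared by MAE, RMSE, MAPE
(as a fraction) and R², with paired t-tests on per-day losses.  A
permutation Shapley estimator attributes every forecast to the original
input columns (exact additivity `φ0 + Σ attributions = prediction`); lag
columns are aggregated per underlying variable, and each forecast is
decomposed into baseline + regular (calendar/HAs) + volatile
(environmental) parts, with waterfall and dependence exports.

Because the hospital data the method was developed on are restricted, the
package ships a calibrated synthetic generator (`generate_panel()`): 1461
days, counts with mean ≈ 70 and SD ≈ 30, rising trend, annual/weekly
seasonality, holiday dips, ≤ 6-day lagged environmental effects and
configurable missingness, so every stage is testable end to end.

## Worked example

```r
library(hastack)
exp <- run_experiment(run_config(seed = 1))
print(exp)
#> <ha_experiment> 20 base-learner fits; test rows: 365
#>           model   mae  rmse   mape     r2
#> 1         ridge 14.11 18.71 0.1596 0.4998
#> 2 random_forest 15.93 21.15 0.1783 0.3607
#> 3          gbdt 15.62 20.26 0.1852 0.4132
#> 4           ann 18.36 23.57 0.2028 0.2062
#> 5      stacking 13.17 17.27 0.1561 0.5737
#> 6  stacking_lds 13.07 16.46 0.1636 0.6127
print(exp$weights)
#> <ha_sample_weights> 1090 rows, 3 stratum(a), kernel=gaussian;
#>   weight range [0.343, 14.232], mean 1.000
```

The table is the four-metric comparison on the held-out fourth year (365
days): each base learner's averaged fold predictions, the unweighted
stacked model, and the stacked model with LDS re-weighting.  Here stacking
beats the best individual learner (MAE 13.17 vs 14.11) and the re-weighted
variant improves RMSE and R² further; the weights summary shows rare-label
days up-weighted by an order of magnitude while the mean weight stays 1.

A thin command-line wrapper is provided at `inst/cli/hastack.R`
(`simulate`, `run-all`, `evaluate` subcommands).

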