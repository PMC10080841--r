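---
title: "Stacked forecasting of daily admission counts: model, re-weighting and explanation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stacked forecasting of daily admission counts: model, re-weighting and explanation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hastack)
```

## The forecasting model

The target is a daily count of hospital admissions, observed jointly with
ten environmental series (six pollutant concentrations, an air-quality
index, temperature, relative humidity) over four consecutive years.  The
model is a two-phase stacked ensemble:

1. **Base learners.**  Ridge regression, a random forest, gradient-boosted
   regression trees, and a single-hidden-layer feedforward network are fitted
   on a common design: single-day lags 1..L of the count and of each
   environmental variable, cumulative lag mean and sample SD over the
   previous 1..L days, and calendar features (one-hot day-of-week, month,
   season, year; serial timestamp; holiday/workday indicators).  The lag
   depth defaults to L = 6 days, the short-term exposure window conventional
   in environmental epidemiology.  The four families are deliberately
   heterogeneous — linear, bagged trees, boosted trees, network — so their
   errors decorrelate.
2. **Out-of-fold meta features.**  The training block is cut into five
   contiguous chronological folds.  For each learner j and fold i, a model
   is fitted on the other four folds and predicts fold i; the concatenated
   predictions form meta feature M_j with exactly one honestly-predicted
   value per training row (20 fits in all).  The same fold models predict
   the test rows, and their 5-way mean N_j is the test-side meta feature.
   Note the fold-i model legitimately sees chronologically *later* folds;
   this matches the procedure the package implements, and a
   `forward_chaining` flag offers the strictly-causal variant.
3. **Meta learner.**  An elastic net — squared error plus the combined
   L1/L2 penalty — is fitted on (M_1..M_4, key features), where the key
   features are all calendar and lagged-admissions columns, and scores
   (N_1..N_4, key features) to produce the final real-valued forecast.
   Forecasts are not rounded to integers; all metrics operate on real
   values.

Assumptions worth keeping in sight: the chronological split (years 1–3
train, year 4 test) means the test year's one-hot year indicator is a
category never seen in training — its indicators are all zero, with a
warning — so the year level must be carried by the timestamp, the trend in
the lagged counts and the meta features; and because lag features are
computed on the full panel before splitting, early test rows keep their
true late-training history (no fabricated padding).

## Label-distribution-smoothing re-weighting

Daily counts are label-imbalanced: peak and trough days are rare, and a
squared-error fit concentrates on the dense middle of the label range.
Re-sampling is unattractive for a seasonal count series (it would distort
the temporal pattern), so the package re-weights instead.  Within each
calendar year (the distribution shifts upward year over year) the training
labels are binned at width 1 count, the empirical bin density is convolved
with a symmetric kernel — Gaussian, window 5 bins, σ = 2 bins by default,
the canonical smoothing choice for this re-weighting family; triangular,
Laplace and delta kernels are available — and each row's weight is the
inverse of the effective density at its label's bin.  The kernel window is
truncated at the label-range boundary without renormalization (simple and
exactly testable).  Weights are optionally clipped, then rescaled to mean
one *globally* rather than per stratum, so a year whose labels are
concentrated is genuinely down-weighted relative to a year with wide
spread.  A stratum with fewer than two distinct labels falls back to
uniform weights with a warning.  With the delta kernel the scheme reduces
exactly to classical inverse-frequency weighting, which the tests use as an
oracle.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `lag_spec(L)` | 6 | days | short-term exposure window |
| fold count `k` | 5 | folds | chronological blocks of ~218 rows |
| ridge `lambda` | 0.1 | penalty | mild shrinkage for a 119-column design |
| forest `num_trees` / `min_node_size` | 300 / 5 | — | stable variance at this n |
| boosting `nrounds` / `eta` / `max_depth` | 300 / 0.05 / 3 | — | slow learning, shallow trees |
| network `size` / `decay` / `maxit` | 16 / 0.1 / 200 | units | see below |
| meta `alpha` / `lambda` | 0.5 / 0.5 | mixing / penalty | see below |
| LDS `kernel` / `kernel_size` / `sigma` | gaussian / 5 / 2 | bins | canonical smoothing defaults |
| `bin_width` | 1 | counts | labels are integers |
| explainer background / permutations | 100 rows / 2 pairs | — | cost–accuracy balance |

Two defaults deserve their reasoning spelled out.

**The network.**  The natural single-hidden-layer regressor in R is
`nnet`: logistic hidden units trained by BFGS with weight decay as the
regularizer.  It has no rectified-linear option and no early stopping;
weight decay plays the same anti-overfitting role.  Sixteen hidden units
on ~119 inputs (≈ 1 900 weights for ≈ 1 090 rows) keeps the network the
ensemble's nonlinear "different perspective" without dominating runtime;
everything is configurable through `base_learner_spec("ann", ...)`.

**The meta penalty.**  The elastic-net penalty must be strong enough that
the meta fit does not lean on the degenerate year indicators (all-zero at
test time): with λ ≲ 0.01 a weighted fit can shift level through the year
dummies and extrapolate poorly into the held-out year, while λ around
0.5 at α = 0.5 is stable for both the weighted and unweighted fits.
The holdout grid-search protocol — fit on the first 80% of the (new)
training block, score each grid point by MAE on the last 20%, break ties
by grid order, no refit inside the search — is implemented in
`grid_tune()` and available via `run_config(tune = "meta")` or
`tune = "full"`, but it is not the default: a holdout drawn from inside
the training years cannot penalize reliance on the year indicators, so
it systematically prefers the weakest penalty.  Fixed, documented
hyperparameters are the more honest default for this design.

## The synthetic generator

`generate_panel()` emulates the study-shaped data: 1461 consecutive days
from 2015-01-01; counts drawn negative-binomially (size 50 by default,
i.e. mild overdispersion beyond Poisson) around a log-linear intensity
with baseline 49, +0.15/year trend, an annual harmonic of amplitude 0.45
peaking in mid-January, weekday effects with weekend dips, holiday dips of
−0.25, and short-lag effects of the standardized environmental series
(positive temperature and pollutant coefficients, a small negative
humidity coefficient).  The environmental series are seasonal sinusoids
with lag-1 autocorrelated noise calibrated to realistic urban means and
SDs; coarse particulate matter is constructed as pm10 − pm25 exactly, and
the air-quality index is a documented deterministic proxy —
100 · max over pollutants of concentration/reference — standing in for
the official sub-index rules, which the modeling layer never needs.
Missingness blanks all environmental cells on whole days (matching how
station outages appear in day-counted audits), and linear interpolation
restores them, with nearest-value extension at the edges.

This calibration puts most count variance in *systematic* structure
(trend, seasonality, calendar) with modest observation noise, so the
series is predictable to roughly the degree the method's source setting
was (test R² ≈ 0.5–0.6 here).  What the generator does **not** emulate:
spatial station structure and hourly-to-daily aggregation, true holiday
calendars, regime changes, autocorrelated count innovations, or any causal
pollutant–health mechanism.  Passing tests therefore demonstrate that the
machinery recovers structure it is pointed at — not that the method will
achieve any particular accuracy on real hospital data.

## Numerical choices and degenerate inputs

- Elastic-net fits run on a short decreasing λ-path ending at the target
  (a lone small λ converges poorly in coordinate descent) with a 1e-16
  convergence threshold, tight enough that the zero-penalty fit matches
  the normal-equations solution to ~1e-8 on small designs.
- A constant training target short-circuits to a constant predictor
  (the solver cannot standardize a zero-variance response).
- Min–max scaling of a constant column yields all-zeros with a warning;
  binary indicator columns are left unscaled (the transform is a no-op on
  {0, 1}); the serial timestamp is normalized like any continuous column.
- `Lag 1L std` uses the sample (n−1) formula, matching the summary
  statistics; summary percentiles use R's default quantile rule (type 7).
- Seasons map meteorologically: Mar–May = 1 (spring) … Dec–Feb = 4
  (winter).  First/last-workday flags mark workdays whose previous/next
  calendar day is not a workday.
- Uneven fold division sends the extra rows to the earlier folds.
- Paired two-sided t-tests compare per-day losses (absolute for MAE,
  squared for RMSE, absolute-percentage for MAPE); a zero-variance
  difference vector reports p = 1 at zero mean and p = 0 with a warning
  otherwise.  MAPE is reported as a fraction and requires positive
  observations unless an epsilon guard is configured.
- The permutation Shapley estimator batches all coalition rows of a
  permutation walk into one prediction call; forward and reverse passes of
  each permutation are averaged.  Additivity
  (φ0 + Σ attributions = prediction) holds exactly by construction for
  any number of permutations, and linear models are recovered in closed
  form — both are asserted in the tests.

## Problem sizes used by the test-suite

Module tests run on small generated panels (40–220 days).  The stochastic
benchmark assertions use the full default shape — 1461 days, 4 learners ×
5 folds — across ten generator seeds for the ensemble-dominance and
tail-error properties, and one seed-fixed explained run (background 25
rows, 40 explained days, one permutation pair) for the attribution
sign-recovery checks; these sizes are the package's chosen compromise
between statistical resolution and a test suite that completes in
minutes.

## Known limitations

- The test-year one-hot category is structurally unseen; models lean on
  the timestamp and lagged counts for the level of the held-out year.
- Inverse effective density can produce order-of-magnitude weight ratios
  on long-tailed label ranges; the overall test MAE of the re-weighted
  model is sometimes slightly worse than the unweighted stack even as its
  tail error improves — the trade the re-weighting deliberately makes.
  `max_weight` clipping is available.
- The permutation explainer's cost grows as features × background ×
  permutations × explained rows; the defaults favor exactness of the
  additivity identity over Monte-Carlo precision of individual
  attributions.
- No probabilistic intervals, no recurrent/sequence baseline, and no
  epidemiological effect estimation: attributions describe the fitted
  model, not causal exposure effects.
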