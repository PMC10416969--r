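---
title: "Cluster-stratified CGM calibration: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cluster-stratified CGM calibration: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgmcal)
```

## The problem and the model

Minimally invasive CGM sensors estimate blood glucose from interstitial
fluid. Their error is not white noise: it varies systematically with the
glucose range (insulin dynamics differ across the hypo- to hyperglycemic
spectrum) and with personal physiology — activity, posture, heart and
breath rate, skin temperature and recent food intake all modulate the
sensor/blood relationship, within and between patients.

`cgmcal` treats calibration as supervised error regression, stratified by
glucose range. For a paired reading with measured value $g_m$ and
invasive reference $g_r$, the target is the signed sensor error

$$d = g_m - g_r,$$

predicted from eight features: $x_1 = g_m$ and the seven covariates $x_2$
(physical activity, g), $x_3$ (peak acceleration, g), $x_4$ (posture,
degrees), $x_5$ (heart rate, BPM), $x_6$ (breath rate, BPM), $x_7$ (skin
temperature, °C), $x_8$ (food intake, calories). The corrected estimate is

$$g_p = g_m - \hat d.$$

Training is stratified over six fixed, knowledge-based clusters
(`cluster_scheme()`): ≤ 80, 81–115, 116–150, 151–180, 181–250 and
> 250 mg/dL. Intervals are half-open at the top — a value equal to a
threshold belongs to the lower cluster. (Published descriptions of these
ranges sometimes disagree by one mg/dL at the 180/181 boundary; we fix
the convention above once and use it everywhere.) Each cluster gets its
own regressor because the error pattern differs by range; clusters with
fewer than `min_samples` readings (default 10) fall back to the identity
correction $\hat d = 0$ rather than extrapolating from too little data.

## Regressor families and the MLP

Six families are supported behind one interface
(`regressor_config()` / `fit_regressor()`): SVR (`e1071`), KNN
(`caret::knnreg`), decision tree (`rpart`), random forest
(`randomForest`), AdaBoost.R2 (implemented in-package with `rpart` base
learners and weighted-median prediction, since no installed package
offers boosting for regression of this form), and a multilayer
perceptron implemented in-package.

The MLP (`mlp_fit()`) is a standard feed-forward network with linear
output and squared-error loss plus an L2 penalty, trained by
backpropagation. We wrote it ourselves because the calibration method is
defined over a hyperparameter surface — arbitrary hidden-layer stacks,
ReLU/tanh activations, L-BFGS/SGD/ADAM solvers,
constant/invscaling/adaptive learning-rate schedules, momentum — that no
single-layer R implementation exposes. Conventions follow mainstream MLP
regressor implementations (Glorot-uniform initialization, penalty scaled
by sample size) so grids expressed in those terms carry over. Training is
full-batch: cluster datasets here are hundreds of rows, where full-batch
gradients are cheaper and less noisy than minibatching. The analytic
gradient is verified against central finite differences in the test
suite, and the per-iteration sum of squared errors is recorded for
convergence diagnostics (`plot_loss_curves()`).

Numerical choices: features are standardized per cluster using
training-split statistics only (stored in the fitted model so inference
applies the identical transform); the regression target is internally
centered/scaled inside the MLP and restored at prediction; a target with
numerically zero variance short-circuits to an exact constant predictor;
corrected glucose is floored at 1 mg/dL so relative metrics stay defined;
SGD divergence (non-finite weights) triggers a restart with a 10-fold
smaller learning rate.

## Hyperparameter search

`hyperparameter_grid()` declares the search space; its defaults are seven
hidden-layer options (20, 100, 200 single-layer; 10 or 20 in each of two
layers; 10 or 20 in each of four layers), learning rates
{0.001, 0.01, 0.05, 0.1, 0.5, 1}, three schedules, {relu, tanh},
{lbfgs, sgd, adam}, iteration counts {100, 500, 1000} and momenta
{0.9, 0.99} — 4536 combinations. Momentum only affects SGD but remains an
axis for all solvers, so the enumerated cardinality is the full product.

`grid_search_cluster()` trains every candidate on a single fixed 70:30
train/test split per cluster (stratification and split seed are explicit
in `calibration_split()`) and scores the corrected glucose on the held-out
30%. The winner minimizes held-out relative RMSE, with MARD and then
enumeration order as tie-breaks: "smallest RMSE and smallest MARD" is
ambiguous when the two minimizers differ, and RMSE is named first in the
selection criterion, so we resolve it lexicographically. Per-candidate
seeds are derived deterministically from (cluster, candidate index), so a
rerun reproduces the winner bit for bit. An optional preset accuracy goal
can stop the search early; it is disabled by default because no
principled threshold exists a priori. Cross-validation is deliberately
not the default — the contract is a single split — though users can rerun
with different split seeds.

## The synthetic cohort and what it does (not) show

`generate_cohort()` emulates the structure of a free-living
type-1-diabetes study: 9 patients wearing a 5-minute CGM for several
days, ~6 fingerstick references per day taken 15 minutes before and two
hours after meals, and wearable covariates on the CGM grid. Reference
glucose follows a mean-reverting (Ornstein–Uhlenbeck) process (mean 140,
SD 45 mg/dL, 50-minute time constant) plus exponentially decaying meal
spikes, clipped to 40–400 mg/dL — parameters chosen so that all six
clusters are populated at realistic frequencies. Covariates are AR(1)
processes inside physiological ranges (heart rate 50–160 BPM, breath
rate 8–30 BPM, skin temperature 30–38 °C, posture ±90°, non-negative
activity/acceleration, calories decaying after meals).

Sensor error is generated as cluster bias + cluster slope × $g_r$ +
linear covariate contributions + a per-patient offset + Gaussian noise
(`error_model_spec()`). The defaults give an uncorrected MARD in the
mid-teens percent, comparable to uncalibrated interstitial sensors.
Reference draws are snapped to the CGM sampling grid, so with zero noise
the error of every reading is exactly recomputable from the spec — the
basis of the ground-truth recovery tests.

Two honest limitations. First, the generator's error mechanism is the
same functional family the calibrator can represent, so recovery tests
demonstrate correctness of the pipeline, not performance on real
sensors, whose error includes drift, lag and artifacts not modeled here.
Second, cluster-dependent bias jumps make the error *non-identifiable
from the measured value alone* near cluster boundaries: a measured
90 mg/dL may be an under-read 101 or an over-read 71, which no regressor
on $(g_m, x)$ can distinguish. Recovery experiments therefore assign
clusters by the reference value (`assign_by = "reference"`), under which
the within-cluster error is an exact linear function of the features and
is recovered to below 1% held-out MARD. Deployment uses the default
`assign_by = "measured"` — the reference is unknown at wear time — and
correspondingly retains a residual error floor near boundaries; both
modes are exposed because the right choice depends on whether the goal is
method validation or deployment.

## Evaluation

`mard()`, `rmse()` (absolute mg/dL and relative %), `relative_errors()`,
Clarke error grid analysis and FDA compliance make up the report surface.
The Clarke zones are computed by an ordered piecewise-linear rule set
(priority A, E, C, D, else B, which resolves boundary overlaps); the test
suite and the acceptance script verify it against an independent
point-in-polygon oracle built from the canonical zone polygons on
10,000 random pairs. The FDA rule is keyed on the sensor value: below
100 mg/dL an absolute bound applies (±20 mg/dL adjunctive,
±10 nonadjunctive), at or above 100 a relative bound (±20% / ±10%).
Reports quote both RMSE units because "RMSE" for glucose is quoted
sometimes in mg/dL and sometimes in percent; percentages are printed to
one decimal, counts exactly.

## Problem sizes

The shipped experiments use cohorts of about 1,026 paired readings
(9 patients × 19 days × 6 references), a reduced 8-candidate MLP grid for
recovery and noise studies, and 10 simulation seeds for the
noise-improvement comparison; these sizes keep every property sharp
(cluster counts of 20–290 per cluster) while the full suite runs in a few
minutes. The full 4536-point grid is exercised combinatorially
(enumeration, cardinality, ordering) rather than trained exhaustively in
tests; `run_calibrate()` defaults to the full grid for real use.

## Known limitations

- No modeling of sensor drift over wear time or of interstitial lag;
  readings are treated as exchangeable within a cluster.
- The 70:30 split is a single random split, not patient-blocked;
  between-patient generalization is only partially probed by the
  patient-offset term.
- AdaBoost.R2 and the MLP are the only in-package learners; the other
  families inherit their libraries' behaviors and defaults.
- Food-quality labels of wearable datasets are reduced to calories; the
  cohort reader accepts an optional ordinal `food_quality` column but the
  generator does not produce one.
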