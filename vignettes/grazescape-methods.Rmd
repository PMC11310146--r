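---
title: "Methods: foraging-distribution modelling with grazescape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: foraging-distribution modelling with grazescape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grazescape)
```

# The scientific problem

Free-ranging cattle do not graze a paddock evenly. On rugged rangeland —
here, a desert ranch of vegetated lowland threaded by 5–8 m sand-dune
ridges with a single water point — foraging pressure concentrates where
forage is green, water is near and climbing cost is low, and that
concentration shifts over the grazing season as herbage conditions decline.
`grazescape` implements the full analysis chain for quantifying this:

1. **Behaviour classification** — movement metrics computed from 50-s GPS
   fixes separate foraging from non-foraging gaits.
2. **Resource selection function (RSF)** — a used–available logistic
   regression links foraging locations to landscape covariates.
3. **Moderation analysis** — Johnson–Neyman regions quantify how greenness
   (NDVI) conditions the effects of elevation and distance to water.
4. **Map validation** — the predicted probability surface is segmented into
   twenty 5 % intervals and confronted with the observed location
   frequencies.

Because the motivating field data (two GPS-collared cattle, a
photogrammetric elevation model and two satellite NDVI scenes) are not
publicly deposited, the package ships a synthetic dune–lowland generator
with known ground truth. Every claim the test suite makes is made against
that generator or against published summary tables, never against
irreproducible raw data.

# The synthetic ranch

`generate_landscape()` builds all covariate layers on one grid of 2 × 2 m
cells, by default 224 × 448 cells (≈ 100,000 cells, ≈ 20 ha — the scale of
the motivating ranch):

* **Elevation.** A lowland baseline at the 100 m datum with ±0.5 m of
  smooth undulation, plus elongated anisotropic Gaussian ridges (crest
  heights 5–8 m, lengths 400–600 m, widths 20–40 m, oriented roughly
  east–west). Ridges are added (pointwise maximum, so stacked ridges never
  exceed the crest range) until the target fraction of cells — 60 % by
  default — carries more than 2.5 m of dune relief.
* **Slope and aspect** are derived from elevation by central differences;
  aspect is reduced to binary north/south facing, matching how rangeland
  RSF analyses usually encode it.
* **Distance to water (DWP)** is the Euclidean distance from each cell
  centre to the single water point.
* **NDVI** couples to elevation with a period-dependent sign: early in the
  season greenness concentrates in the lowland (strongly negative
  NDVI–elevation correlation, mean ≈ 0.42), late in the season the lowland
  is grazed down and the coupling turns weakly positive (mean ≈ 0.30). The
  field literature for this system reports only the *signs* of these
  correlations, so the magnitudes here are our choice; a smooth random
  patchiness field (SD 0.05) is superimposed and values are clipped to
  [−1, 1].

What the generator deliberately does **not** emulate: photogrammetric
noise, NDVI sensor artefacts, fence effects, social behaviour between
animals, and diurnal rhythm in the mode chain. Tests passing on this
generator therefore demonstrate the *correctness of the estimators under
the stated model*, not robustness to every field pathology.

# Track simulation

`simulate_track()` draws a two-state (foraging / non-foraging) Markov chain
over 50-s fixes. The default transition matrix has stationary distribution
80 % foraging, consistent with direct visual observation of grazing herds
in this system. Each mode has a movement kernel: gamma step lengths
(shape 2) with mean 4 m per fix when foraging versus 20 m when travelling,
and wrapped-normal heading changes with SD 70° versus 15°. At each step a
set of candidate destinations is drawn from the kernel; while foraging, one
candidate is accepted with probability proportional to the true selection
surface

$$w(x) = \frac{\exp(\beta_1 x_1 + \dots + \beta_n x_n)}{1 + \exp(\beta_1 x_1 + \dots + \beta_n x_n)},$$

while travelling the choice is uniform. The boundary is reflective, so no
fix leaves the ranch. The default coefficient vector is the early-season
standardised estimate set for this system (elevation −0.20, DWP −0.14,
slope −0.06, NDVI 0.22, NDVI × elevation 0.01, NDVI × DWP 0.31, intercept
−0.67).

# Movement metrics and classification

For each lag $L = k \cdot 50$ s, `compute_features()` returns per fix the
linear displacement over $k$ fixes, the cumulative path length over the
same window, and the absolute turning angle (degrees, [0°, 180°]) between
the two adjacent $L$-second segments. The default lag set
{100, 200, 400, 800} s spans the range over which these metrics separate
foraging from travel in cattle. Turning angles at zero-length segments are
flagged missing rather than zeroed, because a stationary animal has no
heading. The triangle inequality (cumulative ≥ linear) and rigid-motion
invariance of the angle are enforced as property tests.

`fit_behavior_classifier()` trains a random forest (500 trees, √p
candidate features per split) and evaluates it by stratified 10-fold
cross-validation; folds are assigned cyclically over class-sorted rows, so
fold sizes differ by at most one overall and within class. The accuracy
confidence interval is the percentile interval over fold accuracies — a
deliberate choice, since no more specific CI method is standard for
CV-based accuracies. Fixes with incomplete features are excluded from both
training and prediction and counted in the report.

# The RSF core

## Design and standardisation

Used points are foraging-classified fixes at the native 50-s interval; no
thinning for serial autocorrelation is applied (a known limitation of this
family of analyses — effective sample size is overstated, so p-values on
the used side are anti-conservative). Available points are sampled
uniformly over ranch cells *with replacement*, at cell centres.

Main covariates are centred and scaled; interactions are products of
standardised mains, so their coefficients read as effects per SD. Two
standardisation populations are supported: the pooled used + available
rows (the pipeline default, stored on the fit and reused for prediction
surfaces) and the ranch-wide cell population
(`landscape_standardization()`), which is the scale on which ground-truth
coefficients are defined and therefore the scale used in every
parameter-recovery experiment.

## Fitting

`fit_rsf()` maximises the logistic likelihood by iteratively reweighted
least squares with an explicit step-halving safeguard, so the
log-likelihood trace is non-decreasing by construction (and asserted in
tests). Convergence requires a relative log-likelihood change below 1e-8
within 100 iterations. Perfect separation (non-overlapping linear
predictors) and quasi-separation (|η| > 30 without convergence) raise
errors instead of returning runaway coefficients; a singular information
matrix is reported as rank deficiency. The coefficient covariance is the
inverse observed information. AICc is
$-2\ell + 2k + 2k(k+1)/(n-k-1)$; `select_models()` ranks candidates by it,
flags ΔAICc < 2 as the supported set, and admits an interaction only when
both parent mains are present.

## Simulating used points for estimator checks

A subtlety worth recording: the used–available logistic estimator is
consistent for the slope coefficients when used locations follow an
intensity proportional to $\exp(\eta(x))$ — the classical
weighted-distribution result. Sampling used points with density
proportional to the *inverse-logit* $w(x)$ instead would make the true
log density-ratio $\log w(x)$, which is not linear in the covariates, and
would shrink every recovered coefficient by roughly the average
non-selection probability. `sample_used()` therefore draws recovery-study
points with weight $\exp(\eta)$, while the track simulator — which is a
behavioural model, not an estimator check — keeps the inverse-logit
candidate weighting. Recovery experiments confirm per-coefficient absolute
bias well below 0.05 with ~95 % Wald coverage at 5,000 used / 10,000
available points.

## How many available points?

`convergence_study()` refits the model with fresh available samples of
increasing size (default 100, 1,000, 5,000, 10,000, 30,000; 200 replicates
by default, configurable up to the 500–1,000 used in large published runs)
and summarises each monitored coefficient by its mean and 95 % simulation
envelope (order-statistic percentiles, so two replicates degenerate to
min/max). `converged_at` is the smallest size whose envelope widths are all
within 15 % of the largest size's. Because the used sample is held fixed,
envelope width keeps shrinking roughly as $n_a^{-1/2}$; with the default
geometric size ladder the 15 % criterion is typically first met only at the
top size, which is the honest reading — more available points keep helping
until the available-sampling noise is negligible against the fixed used
sample.

# Moderation: simple slopes, Johnson–Neyman, bootstrap

For a fitted interaction, the conditional (simple) slope of a focal
covariate at standardised moderator value $m$ is
$\beta_f + m\,\beta_{fm}$ with variance
$v_{ff} + m^2 v_{mm} + 2m\,v_{fm}$. Significance uses the normal
reference — defensible here because the designs have $n \sim 10^4$–$10^5$.
`jn_boundaries()` solves
$(\beta_f + \beta_{fm} m)^2 = z_{\alpha/2}^2\,(v_{ff} + 2mv_{fm} + m^2v_{mm})$
as a quadratic in $m$; the significance pattern of each interval is
established by probing, and the degenerate no-interaction case falls back
to the main effect's own test ("significant everywhere" or "nowhere").
Boundaries are reported both in SD units and, via the stored
standardisation, on the raw moderator scale. `jn_sd_scan()` implements the
complementary stepping rule used in applied reports: walk the moderator in
0.05-SD increments until the slope first reaches significance and return
that grid value (NA if the scan exits ±5 SD).

`bc_bootstrap()` is a case-resampling bootstrap, stratified by the
used/available role so both strata keep their sizes, with a single
median-bias correction $z_0 = \Phi^{-1}(\#\{\hat\theta^*_b < \hat\theta\}/B)$
(BC, not BCa — no acceleration term, since only median-bias correction is
specified for this family of analyses). Interval endpoints are bootstrap
order statistics at the adjusted levels; no interpolation. The default
$B$ in scripted runs is 2,000; full-fidelity runs use 50,000. Nested
Monte-Carlo calibration (mean of 50 standard normals, 500 outer
replicates, $B = 1000$) attains 94–95 % coverage.

# Prediction and validation

`predict_surface()` standardises each cell with the fit's stored
parameters and evaluates $w$; `bin_surface()` segments [0, 1] into twenty
half-open 5 % intervals with the top interval closed (the edge convention
is our choice — published validation tables depend only on counts, not
edges). `interval_frequencies()` tabulates observed locations per
interval; percentages are always computed against the sum of the counts,
which is the convention under which the published early-period table is
internally consistent (its printed grand total disagrees with its own
column sum; the percentages follow the sum, and so do we — the discrepancy
is noted in the data accessor's documentation). `threshold_summary()`
reports the share of locations above interval-edge thresholds (50 % and
75 % by default).

# Numerical and design choices, in brief

* Half-open cell membership `[left, right) × [bottom, top)`; cell centres
  at `origin + (i + 0.5) · cellsize`; row 1 is the northernmost row.
* One master seed per run, split deterministically into named substreams
  (`substream_seed()`), so stages are reproducible independently and
  recorded in the pipeline manifest.
* Available points drawn with replacement (unstated in the motivating
  analyses; with-replacement is the simpler exchangeable choice).
* Aspect is generated and annotated but not part of the default candidate
  set, mirroring its absence from the published coefficient tables; it can
  be added as a candidate term.
* Inverse logit is evaluated via `plogis`, stable to |η| ≈ 700; tails
  saturate to 0/1 rather than NaN.
* Rasters are exchanged as plain-text ESRI ASCII grids and tables as CSV,
  keeping every artefact diffable and platform-neutral.

## Problem sizes used in scripted checks

The packaged checks run at desk scale, chosen to keep the full suite under
a few minutes while leaving every conclusion unchanged at larger settings:
recovery and coverage use 200 replicates of 5,000 used / 10,000 available
on the full 224 × 448 ranch; the convergence study uses 100 replicates per
size up to 30,000; bootstrap calibration uses 500 outer replicates at
$B = 1000$; classifier checks use 2,500-fix tracks. The corresponding
full-fidelity settings (up to 1,000 convergence replicates, $B = 50{,}000$,
100,000 available points) are plain configuration changes.

# Known limitations

* Serial autocorrelation of 50-s fixes is not corrected; used-sample
  information is overstated.
* No individual random effects (the motivating data pool two animals) and
  no step-selection variant.
* The NDVI–elevation coupling magnitudes in the generator are invented;
  only their signs are anchored in the motivating system.
* The JN machinery treats "indirect effects" as conditional (moderation)
  effects; no causal-mediation decomposition is attempted.

# A worked example

```{r example, eval = FALSE}
library(grazescape)

land <- generate_landscape(period = "early", seed = 1)
track <- simulate_track(land, n_fixes = 5000, seed = 1)

features <- compute_features(track)
clf <- fit_behavior_classifier(features, track$mode, seed = 1)
glance(clf)

used <- track[classify_track(clf, features)$label == "foraging", c("x_m", "y_m")]
avail <- sample_available(land, 100000, seed = 1)
design <- build_design(used, avail, land)
fit <- fit_rsf(design)
tidy(fit)

jn_boundaries(fit, focal = "dwp", moderator = "ndvi")
surface <- predict_surface(fit, land)
freq <- interval_frequencies(used, bin_surface(surface))
threshold_summary(freq)
autoplot(freq)
```
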