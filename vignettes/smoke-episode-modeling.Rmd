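---
title: "Modeling hourly wildfire PM2.5 by fusing monitors, low-cost sensors, satellite and meteorology"
author: "plumefuse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling hourly wildfire PM2.5}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

During a severe wildfire episode, surface PM2.5 varies sharply from hour to
hour and from one valley to the next, but the regulatory monitoring network
is sparse: stations report only a fraction of hours and few sit near the
fire. `plumefuse` implements a fusion pipeline that estimates hourly PM2.5
on a modeling grid by combining

* sparse, trusted regulatory ("AQS-like") monitors,
* a dense but biased network of low-cost ("PurpleAir-like") optical
  sensors, calibrated against collocated regulatory monitors,
* geostationary-satellite aerosol optical depth (AOD) and binary
  smoke/dust/aerosol detection masks,
* hourly meteorology (2-m temperature, surface pressure, 10-m winds,
  boundary-layer height, relative humidity), and
* static land-use, elevation and road-distance covariates,

with a weighted random forest, minority oversampling (SMOTE) for the rare
high-concentration observations, and leakage-guarded spatial and temporal
cross-validation. Because the real satellite/meteorology archives are far
too heavy for routine testing, the package ships a seeded synthetic-domain
generator that reproduces the statistical structure of such an episode with
known truth, so every stage of the pipeline can be validated end to end.

## The synthetic smoke episode

`domainConfig()` describes the study domain. The defaults are a 40 x 40
grid of 3 x 5 km cells observed for 120 hours (five days), 30 regulatory
monitors and 240 low-cost sensors — preserving the roughly 1:8
regulatory-to-low-cost ratio and the sparse regulatory reporting rate
(25% of hours, about six hourly reports per station per day) of a real
wildfire-season archive, at a size where a three-variant, multi-seed
cross-validation study completes in minutes on one CPU.

The true field is `background + plume`:

* **Background.** Exponentiated smooth Gaussian noise (spatial field,
  AR(1) hourly trend, white noise), scaled so ambient PM2.5 has the
  configured mean and SD (9 +/- 5 ug/m3 by default). The exponential
  guarantees positivity and right skew, both characteristic of PM2.5.
* **Plume.** A Gaussian blob of scale `plumeSigmaKm` whose center follows
  a Lagrangian track `x[t+1] = x[t] + u * dt`, advected by a steady
  easterly wind with a slow meridional oscillation and reflected at the
  domain boundary; intensity ramps up over the first day and breathes
  diurnally. This is the cheapest mechanism that yields realistic
  space-time correlation of smoke.

Low-cost sensor clusters are drawn preferentially along the smoke corridor
(dense sensor metros sit downwind of large fires), with a uniform tail so
some clusters stay clean. `plumeAmplitude = 170` ug/m3 and
`plumeSigmaKm = 24` were chosen so that, averaged over seeds, about 2% of
sampled ground observations are at or above the 100 ug/m3 minority cutoff
— the imbalance level the method is designed around. Individual seeds
scatter around that value; the suite checks the share aggregated over ten
seeds.

Raw low-cost values follow

```
raw = truth * (1 + paBiasMult) + paBiasAdd
      + paBiasRhCoef * (RH - rhMean) + noise,  floored at 0,
```

with `paBiasAdd = 1.9` ug/m3 (the mean raw bias reported for such
networks), a humidity term expressed around the domain-mean RH so the
additive term *is* the mean bias, and a small multiplicative term.
Regulatory monitors measure truth plus small zero-mean noise; their noise
SD is a free parameter (`aqsNoiseSd`, default 0.75 ug/m3) because no
authoritative value exists for it. AOD is proportional to true PM2.5
(0.008 per ug/m3) with retrieval failure whose probability *increases*
with PM2.5, emulating failed retrievals inside thick smoke — the pipeline
is deliberately exercised under informative missingness.

What the generator does **not** emulate: fire emission chemistry, terrain
channeling of smoke, multi-plume events, satellite viewing-geometry
artifacts, sensor-specific drift families, or the real archives' file
formats. Passing tests therefore demonstrate that the pipeline's
machinery is correct and that it recovers known structure under realistic
sparsity, bias and missingness — not that any particular real-world
accuracy number would be attained.

## Sensor calibration by geographically weighted regression

`findCollocations()` pairs each low-cost sensor with the nearest
regulatory monitor within 500 m (great-circle), one pair per sensor-hour.
`fitGWR()` then regresses regulatory PM2.5 on the raw sensor value,
temperature, relative humidity, uptime and operating time by weighted
least squares at every anchor (collocated sensor site), with Gaussian
spatial kernel weights. Design choices the data do not dictate, decided
here once:

* **Kernel and bandwidth.** Gaussian kernel; bandwidth chosen by
  leave-one-station-out CV RMSE over a logarithmic ladder (2–300 km).
  Station-level (not row-level) hold-out is essential: rows from one site
  are strongly dependent.
* **Rank deficiency.** A locally singular design is refit with a doubled
  kernel (up to six doublings) before failing with the anchor's name.
* **Transfer to non-collocated sensors.** Kernel-weighted averaging of
  anchor coefficient vectors — the standard GWR prediction at unobserved
  locations; a sensor outside kernel reach falls back to its nearest
  anchor.
* **Floor.** Calibrated values are floored at 0 ug/m3 (physical
  non-negativity); the raw value is kept alongside.

With a single anchor and an effectively infinite bandwidth the procedure
reproduces ordinary least squares exactly, which the tests assert.

## Fusion and features

`dedupGround()` keeps one value per cell-hour: regulatory values supersede
low-cost ones (in mixed cell-hours the low-cost values are deleted), and
surviving same-network values are averaged. Regulatory cell-hours carry
weight 1.0, low-cost cell-hours 0.15. `joinMetToGrid()` assigns
meteorology points to cells injectively by a greedy walk over point–cell
pairs in increasing distance (the constraint is that no two points share a
cell; the greedy order is this package's choice, with lexical
tie-breaking). `aggregateSatelliteHourly()` averages valid sub-hourly AOD
retrievals and ORs the detection masks within each hour.

The *convolutional layer* is the inverse-distance-weighted average of the
five nearest same-hour ground measurements, with distances between cell
centers. For training rows the target cell's own measurement is excluded
— including it would leak the label, and the neighbor count is kept at
five because wider neighborhoods correlate too strongly with the label.
For prediction rows (cells without a measurement) all same-hour
measurements are eligible. Only rows with every predictor present
(`complete`) are used for training or prediction.

## SMOTE for a continuous target

A row is *minority* when its target is at or above 100 ug/m3 (inclusive).
For each minority row, its five nearest minority neighbors are found in
z-scored continuous-predictor space (standardized on the minority subset:
the predictors mix Pa, m/s, meters and fractions), and each synthetic draw
interpolates continuous predictors *and* target by
`seed + g * (neighbor - seed)`, `g ~ U(0,1)`; binary predictors, cell,
hour, station and the observation weight are copied from the seed row, so
a synthetic low-cost-derived point never gains regulatory-level trust. The
count law `|output| = |input| + nSynth * |minority|` holds exactly. The
RNG contract (one block of neighbor picks, then one block of gaps, minority
rows in input order) is documented so an independent implementation can
reproduce the output bit for bit — the test suite does exactly that.

Inside cross-validation, SMOTE is applied *after* the fold split, to the
training portion only; metrics are always computed on original rows.

## The weighted forest and its evaluation

`trainForest()` delegates tree growing to `ranger` configured to the
pipeline's contract: weight-proportional bootstrap (`case.weights`),
`mTry = ceiling(sqrt(p))` predictors per split, minimum node size 5,
maximum depth 20, 500 trees by default, out-of-bag predictions and
permutation importance. Three variants are compared: regulatory-only,
plus weighted low-cost sensors, plus fold-safe SMOTE.

Evaluation reports R² as the squared Pearson correlation of measured and
predicted, RMSE, and the slope/intercept of the OLS regression of
predicted on measured; the *high-range slope* repeats that regression on
rows measured at or above 100 ug/m3 and quantifies underestimation of
smoke-impacted concentrations. For the SMOTE variant the out-of-bag
metrics are computed on the augmented training set (synthetic rows
included) — the alternative of excluding them is equally defensible, but
this choice keeps OOB a pure property of the fitted ensemble.

Fold construction:

* **Temporal:** rows sorted by hour (ties by station), cut into ten
  contiguous blocks whose sizes differ by at most one.
* **Spatial:** monitors ordered along a Hilbert space-filling curve and
  dealt round-robin into groups of ten, so each group spans the domain
  (heterogeneous groups); monitors sharing a grid cell are forced into one
  group because deduplication merges their observations. All of a
  monitor's observations travel with its group, and the code asserts that
  no station spans a train/validation split, that temporal blocks never
  interleave, and that synthetic rows are never scored.

`modelOrderingStudy()` runs the full pipeline over several seeds and
evaluates the three variants by spatial CV. It uses 50 trees per forest —
the comparison averages over folds and seeds, where tree-count noise
cancels — while `forestConfig()` keeps the 500-tree default for ordinary
fits. The suite asserts the study's qualitative structure: adding
weighted low-cost data does not worsen spatial-CV RMSE relative to the
regulatory-only model, and SMOTE moves the high-range slope strictly
closer to 1.

## Prediction surfaces and export

`predictHour()` predicts every complete cell of an hour (floored at 0,
`NA` elsewhere). Surfaces export as CSV or as a georeferenced ESRI/GDAL
ASCII grid (`AAIGrid` with `dx`/`dy` keywords, since the cells are not
square) plus a WGS84 `.prj` sidecar, with missing cells encoded as the
declared nodata value; the text raster was chosen over binary formats so
exports are diffable and round-trip exactly through `readSurfaceAsc()`.
Grid geometry is equirectangular about the domain origin; all distances
in the package are great-circle (haversine) on lon/lat.

## Numerical choices and degenerate inputs

* Identical configs (including seed) give bit-identical domains,
  observations, folds, SMOTE draws and forests (`num.threads = 1`).
* Zero plume amplitude degenerates to pure background; zero-noise,
  zero-bias monitors reproduce truth exactly — both are tested.
* An exact zero IDW distance returns that neighbor's value; fewer than
  five neighbors use all available; no same-hour neighbor yields a
  missing layer (the row becomes incomplete).
* Fewer than `k + 1` minority rows shrink the SMOTE neighborhood with a
  message; zero minority rows return the input unchanged with a warning.
* A single-fold CV plan, augmented rows fed to CV, missing predictors fed
  to the forest, and zero meteorology points are all rejected with
  informative errors.

## Limitations

The synthetic episode is stationary in its statistical structure; real
smoke events have regime changes the generator cannot produce. Absolute
accuracy metrics measured here do not transfer to real archives. The
spatial-CV study sizes (five seeds, 50 trees, five-day domain) are the
package's chosen compromise between statistical resolution and a
single-CPU runtime of a few minutes; rerunning with more seeds or trees
only sharpens the same comparisons.
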