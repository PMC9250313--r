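---
title: "Indirect remote sensing of biodiversity change: models and methods"
author: "divcast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Indirect remote sensing of biodiversity change: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The monitoring problem

Most of a region's biodiversity — understory plants, amphibians, insects —
cannot be observed from space. What satellites do observe, repeatedly and
for free, are the environmental conditions that constrain where those
organisms occur: temperature, precipitation, and canopy greenness (NDVI).
`divcast` implements an *indirect* monitoring framework built on that fact.
It learns, over a training window, the statistical association between
remotely sensed climate summaries and two community-level diversity
surfaces — species richness (SR, the count of species per pixel) and
Faith's phylogenetic diversity (PD, the summed branch lengths of the
minimal rooted subtree spanning the species present in a pixel) — and then
re-applies that association to each new year's climate to flag where
diversity is potentially being gained or lost.

The pipeline is: monthly climate grids → 19 bioclimatic summaries + annual
NDVI median → variance-inflation-factor (VIF) pruning → a spatially
cross-validated ensemble of four regression learners → yearly projections →
per-pixel trend slopes, richness/PD mismatch maps, and a
direction-of-change validation against field inventories scored with a
permutation null.

## Bioclimatic predictors

`deriveBioclim()` computes the standard 19 bioclimatic variables cell-wise
from 12 monthly layers each of minimum temperature, maximum temperature
(°C) and precipitation (mm/month). Conventions, fixed so that an
independent implementation can reproduce every value to machine precision:

* Mean monthly temperature is `(tmin + tmax)/2`; no separate mean input is
  accepted.
* A *quarter* is any of the 12 cyclic windows of 3 consecutive months
  (December–January–February wraps). Wettest/driest quarters maximize or
  minimize summed precipitation; warmest/coldest maximize or minimize mean
  temperature. Ties are broken by the lowest starting-month index.
* bio4 (temperature seasonality) and bio15 (precipitation seasonality) use
  the population standard deviation (divide by 12); bio4 is scaled by 100
  and bio15 is `100 · sd(prec) / (1 + bio12/12)`.
* bio3 (isothermality) is `100 · bio2 / bio7` and is undefined (masked)
  where bio7 = 0.

Temperatures are assumed to already be in °C; any sensor scaling is the
caller's responsibility. NDVI enters as the cell-wise annual median of the
dated layers (`annualNdviMedian()`), mirroring how greenness composites are
usually reduced.

## Predictor pruning

Collinear predictors destabilise regression ensembles, so the training
predictor table is pruned by stepwise VIF elimination (`vifStepwise()`):
repeatedly drop the variable with the largest VIF while that VIF exceeds
10, recomputing after every drop. VIF is `1/(1 − R²)` of regressing one
standardized column on all others plus an intercept; perfect collinearity
reports `Inf` rather than failing. Ties go to the earlier-listed variable,
so the procedure is deterministic and seed-free. Constant columns (a
bioclim variable can genuinely be constant over a region — e.g. a fixed
diurnal range) are removed beforehand by `informativeVars()`, since VIF is
undefined for them. Pruning is applied once, on the training-window
predictors, and the retained set is reused everywhere downstream.

## Diversity surfaces

Richness comes either from stacking binary range rasters
(`stackRanges()`) — the range maps themselves are inputs, produced
upstream by hull-based range estimation — or from gridding occurrence
records (`gridOccurrences()`) with half-open cell binning. PD
(`faithPD()`) is *rooted* Faith's PD: the union of root-to-tip paths, so a
single-species pixel carries that species' root-to-tip distance. Rooted
and unrooted PD differ for small assemblages, which is why the choice is
stated explicitly; rooted matches the default of the standard PD software.
Internally PD is computed by marking, for every edge, whether any present
species descends from it — a cells × edges Boolean product — which is
exact and fast for community matrices of thousands of pixels.

## Spatial block cross-validation

Random hold-outs test interpolation; a monitoring model must *transfer*
across space and time. `assignBlocks()` therefore partitions pixels into
four contiguous quadrants: a latitude-first median split, then a
longitude median split within each half, labels 1–4 (NW, NE, SW, SE).
Points exactly on a split line go to the lower-index side; collinear
point sets fall back to a warned 1-D quartile split. For points in general
position the four folds are balanced within ±2. Blocks are computed on the
pixel centers of the modelled cells, because the response lives on pixels,
not on occurrence points.

## The ensemble

Four regression families are tuned and combined (`fitEnsemble()`):

| member | implementation | tuning grid |
|---|---|---|
| random forest | `ranger`, 500 trees | mtry ∈ {⌈p/3⌉, ⌈√p⌉, p} |
| neural network | `nnet`, 1 hidden layer | size ∈ {3, 5, 8} × decay ∈ {0.01, 0.1} |
| radial SVM | `e1071::svm` | cost ∈ {1, 10}; kernel width by the median-distance heuristic |
| GLM | `lm`, Gaussian identity | none |

Each candidate is fit on three spatial blocks and scored on the held-out
block; pooled out-of-fold RMSE selects the winner (ties: first grid row).
Winners are refit on all data and combined linearly with weights
proportional to inverse CV-RMSE, `w_i = (1/rmse_i)/Σ_j(1/rmse_j)` — the
weighting rule directly readable from "weighted according to RMSE". A
nonnegative-least-squares stacking alternative is available behind
`weighting = "nnls"`. A member that fails to fit (e.g. the SVM on a
constant response) is dropped with a warning and the weights renormalized.

Neural-net and SVM inputs (and the nnet response) are standardized
internally and back-transformed on output. One master seed derives
per-member, per-fold seeds; `ranger` runs single-threaded so fits are
bit-reproducible.

Reported fit: `fitR2` is the squared Pearson correlation between the
*pooled out-of-fold* ensemble predictions and the response — the
transferability-honest figure — while `trainR2` is the full-data fit.
Both are reported and labelled because a training-fit R² flatters the
model.

## Trends, mismatch, validation

`projectYearly()` applies the model to each projection year's predictor
set; `trendSlope()` reduces the stack to a per-pixel OLS slope on calendar
year (years centered; a pixel must be valid in every layer). Direction is
the sign of the slope, with an optional `eps` band for a "no change"
class; the default `eps = 0` matches a sign-based validation. The
richness/PD mismatch (`pdSrResiduals()`) regresses PD on SR across pixels
independently for each year and maps the residuals: positive residuals
mark pixels holding more evolutionary diversity than expected for their
species count.

Validation grids inventory records per year on a coarse grid, holds out
the last four *observed calendar years*, trains a fresh richness model on
the pooled training pixel-years, projects it onto the holdout years, and
compares predicted vs observed per-pixel trend signs
(`directionAgreement()`; pixels with an exactly zero observed slope are
excluded, as are pixels sampled in fewer than two years). Significance
comes from `permutationPvalue()`: 10,000 random gain/loss prediction maps,
each pixel called "gain" independently with probability `pGain` (default
0.5), scored by their match counts, with the add-one estimator
`p = (1 + #{correct ≥ k}) / (nPerm + 1)` so p is never exactly zero. With
`pGain = 0.5` this null is Binomial(n, ½) regardless of the observed
gain/loss composition; the frequency-matched alternative
(`matchPredictedFrequency = TRUE`) uses the predicted gain fraction and
then requires the observed composition, which the wrapper supplies.
Both variants are exposed because the randomization scheme behind a
"random prediction" admits either reading; neither is claimed to
reproduce any particular published p-value, which also depends on data
we do not ship.

## The synthetic landscape

`synthConfig()`/`simulateClimate()`/`simulateTree()`/
`simulateSpeciesRanges()`/`simulateInventory()` generate a fully known
ground truth with the statistical structure the framework assumes:

* **Climate.** Mean temperature = latitudinal gradient (0.7 °C/degree,
  warmer toward the equator) + a fixed spatially autocorrelated
  heterogeneity field (Gaussian-smoothed white noise, σ = 3 cells) + a
  seasonal cosine (amplitude 4 °C, peaking in January, i.e. austral
  summer) + per-(year, month) smoothed noise of SD `noiseSd` + a linear
  drift of `climateTrend[1]` °C/year. `tmin`/`tmax` sit 5 °C either side
  of the mean. Precipitation has a longitudinal gradient (wetter east),
  the same seasonal phase, and is truncated at zero. NDVI tracks
  precipitation and temperature with small noise, clipped to [−1, 1].
* **Clade.** A Yule topology conditioned on the tip count with
  independent exponential branch lengths; niche optima evolve by Brownian
  motion along the tree (so niches carry phylogenetic signal and the
  PD–SR mismatch is non-trivial) and are rescaled to an SD of 10% of the
  observed temperature range. That 10% makes the clade a coherent band of
  thermal specialists: richness is then a smooth, unimodal function of
  the climate axis peaking near the mean optimum, which is the regime the
  framework assumes. A species occupies a pixel where its Gaussian
  suitability (SD `nicheBreadth`, default 1.5 °C) reaches a global
  threshold. The threshold is calibrated in closed form — the
  `(1 − rangeScale)` quantile of per-pixel maximum suitability — so the
  clade's total range (union of ranges) is exactly `rangeScale` × grid
  area; an iterative calibration was rejected because it degenerates at
  full coverage, where the largest threshold attaining coverage 1 is the
  right answer, not a vanishing one.
* **Inventories.** Each year a pixel is visited with probability
  `effort`; each truly present species in a visited pixel is recorded
  with probability `detectionProb`. Records land at cell centers.

Defaults (50 × 50 cells of 0.2°, years 2002–2019, 30 species, trend
0.1 °C/year, `noiseSd` 0.5 °C, detection 0.7, effort 0.3, range scale 0.5)
describe a strongly warming subtropical region with moderate interannual
variability — deliberately on the strong-signal side of realistic, since
the package's purpose is to test whether the machinery recovers a signal
that is genuinely there. The "strong determinism" scenario used for
end-to-end recovery checks sets `noiseSd = 0.1` and `rangeScale = 0.75`:
low observation-independent climate noise and a broad (but not
saturating) clade.

What the generator does **not** emulate: land-use change, dispersal
limitation, species interactions, observation biases that correlate with
climate, and multi-axis niches (occupancy responds to the single
temperature axis, even though the models see all retained predictors).
Passing tests on synthetic data therefore show that the machinery is
correct and that the statistical pipeline recovers a climate-driven
signal under its own assumptions — not that any particular real clade is
climate-determined.

### Ground truth for drift recovery

The end-to-end check asks whether the modelled richness trend recovers
the *imposed* drift. The imposed drift is defined by the noise-free twin
of the climate series (same seed, `noiseSd = 0`, so the deterministic
fields are identical): pixels whose richness slope under that twin is
nonzero are the "drifting" pixels, and the model's predicted trend sign
is scored against that slope's sign. Scoring against the noise-realized
trajectory instead would conflate generator weather with model error.

## Numerical choices and degenerate inputs

* Masked cells are `NA` end to end and never enter any statistic; rasters
  store them as IEEE NaN with a declared nodata tag.
* Raster I/O is a deliberately narrow single-band float32 GeoTIFF dialect
  (uncompressed, one strip, ModelPixelScale/ModelTiepoint georeferencing,
  EPSG code in a minimal GeoKey directory). Multi-band or compressed
  files are rejected with explicit errors; round trips are exact up to
  float32 storage precision.
* Grid extents are half-open `[min, max)`; cell (1, 1) is the north-west
  corner; point binning is by half-open cell membership, so a point on a
  shared edge belongs to exactly one cell.
* `alignStack()` defaults to mean aggregation for continuous fields
  (preserves means, matching how monthly summaries are usually reduced)
  and offers nearest-neighbour for categorical layers; a target cell with
  no valid source cell is masked.
* Inverse-RMSE weights handle the limits: a zero-RMSE member takes all
  the weight (split equally among exact ties at zero), an infinite-RMSE
  member takes none.
* Trend slopes use centered years; reversal of the year order negates
  slopes exactly, and adding a constant to every layer leaves them
  unchanged — both asserted as properties.
* The permutation p-value is bounded below by `1/(nPerm + 1)`.

## Problem sizes

The bundled study design is a scaled-down analog of a regional
application: a 50 × 50 grid (2,500 pixels), 30 species, a 13-year
training climatology (2002–2014) and five projection years (2015–2019),
with validation on a 5× coarser grid. These sizes keep a full end-to-end
run in the low minutes on a single core while leaving every statistical
feature of the design — spatial blocks, quarter windows, sparse
inventories, permutation null — fully exercised.

## Known limitations

* Trend detection is linear per pixel; change points or nonlinear
  trajectories are out of scope.
* The ensemble cannot extrapolate far outside the training climate range
  (tree-based members saturate), so projections are meaningful only
  within the region and era of training — which is also how the framework
  is intended to be used.
* Magnitude of change is less trustworthy than direction; the validation
  machinery accordingly scores signs.
* The model-fit R² of the inventory-validation stage is limited by
  sampling sparsity: observed zero-richness cells are indistinguishable
  from unvisited ones and are treated as unsampled.
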