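---
title: "Methods: CNN-improved CASA estimation of crop NPP"
author: "cropCASA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CNN-improved CASA estimation of crop NPP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cropCASA)
```

## The model

CASA is a light-use-efficiency model: monthly net primary productivity is
the product of the photosynthetically active radiation a canopy absorbs
and the efficiency with which it converts that radiation to carbon,

$$\mathrm{NPP}(x,t) = \mathrm{APAR}(x,t)\,\varepsilon(x,t), \qquad
\mathrm{APAR}(x,t) = \mathrm{SOL}(x,t)\,\mathrm{FPAR}(x,t) \times 0.5,$$

with SOL the monthly shortwave total (MJ/m²/month) and the factor 0.5 the
conventional PAR fraction of shortwave. The actual efficiency is the
crop's maximum $\varepsilon_{\max}$ (default 0.389 gC/MJ, a single scalar
for cropland; a per-pixel grid can be supplied where a crop-class lookup
is available) down-regulated by three dimensionless stress scalars,

$$\varepsilon = T_{\varepsilon 1}\,T_{\varepsilon 2}\,W_\varepsilon\,
\varepsilon_{\max}.$$

The stress-scalar forms are the ones in common use for regional CASA
runs (they are conventions of that lineage, not quantities this package
estimates):

* $T_{\varepsilon 1} = 0.8 + 0.02\,T_{opt} - 0.0005\,T_{opt}^2$,
  clamped to $[0,1]$, and forced to 0 in months whose mean temperature is
  at or below $-10$ °C. $T_{opt}$ is the mean temperature of the month of
  peak greenness (ties break to the earlier month; `estimateTopt()`).
* $T_{\varepsilon 2} = 1.1814 / \{(1+e^{0.2(T_{opt}-10-T)})
  (1+e^{0.3(-T_{opt}-10+T)})\}$, clamped to $[0,1]$. At $T = T_{opt}$
  this evaluates to $1.1814/((1+e^{-2})(1+e^{-3})) \approx 0.9912$.
* $W_\varepsilon = 0.5 + 0.5\,\mathrm{EET}/\mathrm{PET} \in [0.5, 1]$,
  with $\mathrm{EET} = \min(P, \mathrm{PET})$ as a supply–demand bound
  and PET from Thornthwaite's monthly formulation (heat index over the
  12 monthly temperatures, day-length correction at the site latitude via
  `geosphere::daylength`). Where PET = 0 there is no atmospheric demand
  and $W_\varepsilon = 1$. Externally computed EET/PET grids can be
  passed to `runCasa()` for users running a full regional
  evapotranspiration chain.

Growing-season NPP is the April–October sum by default (configurable).
The strict masking policy masks a pixel's seasonal total if any month is
masked; a "partial" mode sums available months instead.

## Vegetation indices

`computeIndices()` evaluates 15 standard indices per pixel. Conventions
worth stating explicitly, since flattened journal typography often loses
radicals and groupings:

* MSAVI $= (2 B_8 + 1 - \sqrt{(2 B_8+1)^2 - 8(B_8-B_4)})/2$;
  TNDVI $= \sqrt{\mathrm{NDVI} + 0.5}$ (masked where the radicand is
  negative); GEMI uses
  $n = (2(B_{8A}^2 - B_4^2) + 1.5 B_{8A} + 0.5 B_4)/(B_{8A}+B_4+0.5)$
  and equals $n(1-0.25n) - (B_4 - 0.125)/(1-B_4)$.
* ARVI is implemented with the canonical atmospheric correction
  $\gamma = 1$: $(B_8 - (2B_4 - B_2))/(B_8 + (2B_4 - B_2))$. A literal
  reading of some printed forms would give $\gamma = 2$; the canonical
  form is used and noted here.
* GNDVI is computed from B7 and B3 — the red-edge/green pair used in the
  source convention this package follows — rather than the B8/B3 pair
  some references use.
* The soil line (NIR $= a + s\,\mathrm{red}$) is parameterized once:
  intercept $a = 0.08$, slope $s = 1.2$, soil-noise factor $X = 0.08$,
  SAVI's $L = 0.5$ (`indexParams()`). PVI divides by $\sqrt{s^2+1}$ with
  the slope multiplying the red band; WDVI $= B_8 - s B_4$; TSAVI uses
  the same single slope. All are standard published defaults and
  overridable.
* Degenerate pixels are masked, never infinite: any denominator within
  $10^{-9}$ of zero, or a negative radicand, yields NA. Reflectance in
  $(-0.01, 0)$ is clamped to 0 at stack construction; values outside
  $[-0.01, 1.2]$ are masked, and masking any band masks the pixel in all
  bands.

## FPAR retrieval

**Features.** Index samples are min–max normalized to $[0,1]$ per
feature, with the affine map recorded on the model and re-applied at
prediction time (`normalizeFeatures()` / `applyScaling()`); FPAR targets
are already dimensionless in $[0,1]$ and stay on their native scale.
Constant features are dropped with a warning.

**Recursive feature elimination.** `rfeRank()` fits gradient-boosted
trees (xgboost; depth 3, 60 rounds, $\eta$ = 0.3), scores the current set
by 5-fold cross-validated RMSE, removes the lowest-gain feature, and
repeats. The base estimator and step size are implementation choices —
any importance-producing regressor works. The pipeline default keeps all
15 features for the CNN, because the network's configuration table lists
a 15-index input layer and, empirically, the truncated input also
underfits within the fixed 10-epoch budget (held-out R² ≈ 0.93 vs ≈ 0.98
on the default scene); the RFE ranking and per-step CV scores are still
computed and recorded in the run manifest, and `rfeKeep` in
`pipelineConfig()` prunes the input when set.

**The 1-D CNN.** `trainFparCnn()` trains a small convolutional network on
the index vector: three conv layers (16, 32, 64 filters, kernel 2, 'same'
zero padding) each followed by ReLU and max-pooling (size 2, stride 2,
ceiling — a 15-length input survives the three poolings as 8 → 4 → 2),
a dropout layer (rate 0.3, inverted scaling) on the flattened features,
then dense layers of 64 and 32 ReLU units and a linear scalar output.
(A softmax output is ill-defined for scalar MSE regression; the linear
output is the deliberate choice.) Training is Adam at learning rate
0.001 on MSE for 10 epochs over a seeded 7:3 shuffle split. Batch size
(32) and Glorot-uniform initialization follow common deep-learning
framework defaults; He-normal initialization converges visibly slower
inside the 10-epoch budget. Forward and backward passes are vectorized
base-R array algebra; gradients are verified against numerical
differentiation in the test suite. Predictions are clipped to $[0,1]$.

**Baselines.** `trainFparTree()` wraps gradient-boosted regression trees
under the same split protocol, in two presets: "gbdt" (deterministic
full-sample boosting) and "xgb" (row/column subsampling with L2
regularization); defaults 500 trees, depth 6, learning rate 0.05 — the
tree hyperparameters are documented defaults, not fitted ones.
`empiricalFpar()` implements the classical stretch: NDVI and RVI are
mapped linearly between scene bounds onto $[f_{\min}, f_{\max}]$
(defaults 0.001 and 0.95), clamped, and blended with weight $\alpha$
(default 0.5). Stretch bounds default to the 5th/95th percentiles of
vegetated pixels (NDVI > 0.2) per scene, overridable by configuration.

## Evaluation metrics

`evaluatePredictions()` returns R², explained variance score (population
variances; equal to R² whenever the mean residual is zero), MSE, RMSE,
MAE, and MAPE in percent. Metrics that are undefined for the data at
hand — MAPE with a zero observation, R²/EVS with zero observed variance
— are reported as NA and named in the report's flags rather than
silently dropped. NPP accuracy in the pipeline is scored as MAPE over
vegetated pixels only, because bare-soil truth NPP is exactly zero and a
percentage error there is undefined.

## Meteorology preparation

Station radiation reported in J/m²/day is converted to MJ/m²/month by
multiplying with the month length (non-leap calendar). Gridding uses
ordinary kriging with an exponential variogram fitted by weighted least
squares to the binned empirical semivariogram (weights npairs/h²; nugget
0 by default, which makes the surface exact at station cells). The
fitted range is clamped to at most three times the maximum station
separation: trend-like, unbounded semivariograms otherwise push the
range to infinity and the kriging system toward singularity. A tiny
(relative $10^{-9}$) diagonal jitter keeps near-flat covariance systems
solvable; station-cell exactness holds far beyond reporting precision.
A singular system falls back to inverse-distance weighting with a
warning, and IDW is also the documented small-network path (kriging
requires at least 3 stations; a single station yields a constant field).

## The synthetic scene generator

`generateScene()` builds the test world the pipeline is verified on:

* **Layout.** A blocky rice/corn/forest/bare-soil map (default fractions
  0.35/0.35/0.10/0.20) on a 32 × 32, 10 m grid.
* **Phenology.** Per-class double-logistic LAI over the season (corn
  peaks at LAI 4.5 in late July, rice 4.0, forest 5.0 with a wider
  curve), modulated by a smooth ±15% "fertility" field.
* **FPAR truth.** Beer–Lambert, $\mathrm{FPAR} = 1 - e^{-k\,\mathrm{LAI}}$
  with $k = 0.5$ — the standard canopy extinction assumption.
* **Reflectance.** Linear mixing of canopy and soil endmembers with
  fractional cover set to FPAR, plus independent Gaussian band noise
  (default SD 0.01). The soil endmembers sit on the default soil line;
  the canopy spectrum has the red edge between B4 and B7.
* **Meteorology.** Sinusoidal monthly cycles matching a 9.3 °C annual
  mean (half-amplitude 15.5 °C), 710.2 mm annual precipitation with a
  summer peak, and 420 ± 250 MJ/m²/month radiation, with mild spatial
  gradients; all 12 months are generated so the Thornthwaite heat index
  is well defined.
* **Truth NPP.** The CASA forward model run on the true FPAR and scene
  meteorology — so the stored truth is self-consistent with `runCasa()`
  by construction, and the pipeline's recovery error isolates the FPAR
  retrieval.
* **Clouds.** `injectClouds()` overwrites random rectangular patches in
  chosen months with bright cloud-top reflectance and flags them;
  contamination is observational, truth is untouched.

What the scenes do **not** emulate: radiative-transfer canopy physics
(no PROSAIL-grade BRDF, no view/illumination geometry), atmospheric
residuals, correlated band noise, topography, mixed pixels at field
boundaries, or label noise in the FPAR reference (scene labels are exact
truth, whereas real reference FPAR carries its own retrieval error).
Passing tests therefore demonstrate that the machinery recovers a known
signal under the model's own assumptions — not that the accuracy numbers
transfer to any particular real campaign.

## Problem sizes and numerical choices

The verification experiments use a 32 × 32 scene, 2,756 training samples
pooled evenly over the seven season months, and the default network. The
CNN's recovery experiment draws the 15 indices from the scene's own
mixing model (so features carry realistic mutual correlation) and maps
them to FPAR through a logistic function of a weighted index sum — a
known, monotone, saturating relation of the kind FPAR retrieval
presents. Whether samples pool months (the default here) or train one
model per month is configurable via `buildTrainingSet(months = ...)`;
neither mode is asserted as the only valid one.

Tie-breaks and degenerate inputs are fixed as follows: peak-greenness
ties resolve to the earlier month; RFE importance ties drop the
first-listed minimum; all-constant stations yield a constant kriging
field; a fully masked index layer warns rather than fails; non-finite
training loss aborts with a diagnostic rather than returning a model.
All randomness (splits, initialization, dropout, scene noise, patch
placement) flows from explicit seeds, and rerunning any stage with the
same configuration and seed is bit-reproducible.

## Limitations

A single $\varepsilon_{\max}$ for all crops biases C4 crops (corn) low
relative to C3 (rice); the per-pixel grid hook exists but no calibration
is shipped. The stress scalars are the adopted regional-CASA forms, not
site-calibrated. The empirical-FPAR baseline's percentile stretch bounds
are scene-dependent; on scenes with little bare soil the 5th percentile
is not a soil signal. The CNN is trained per run — no transfer learning
or weight reuse across scenes — and the package deliberately stops at
NPP (no soil respiration, NEP/GPP partitioning, or multi-year carry).
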