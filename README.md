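# cropCASA

Crop net primary productivity (NPP) estimation with a CNN-improved CASA
light-use-efficiency model, in R.

## The problem

NPP — the carbon fixed by vegetation per unit area and time after
autotrophic respiration — is the standard currency for assessing cropland
carbon sinks and agricultural productivity. The CASA
(Carnegie–Ames–Stanford Approach) model estimates it from two drivers:

```
NPP(x, t) = APAR(x, t) × ε(x, t)
APAR(x, t) = SOL(x, t) × FPAR(x, t) × 0.5
ε(x, t)    = Tε1 × Tε2 × Wε × εmax
```

where APAR is absorbed photosynthetically active radiation (half the
incident shortwave, times the fraction FPAR the canopy absorbs), and the
actual light-use efficiency ε is the biome maximum εmax (0.389 gC/MJ for
cropland here) down-regulated by low/high temperature stress (Tε1, Tε2)
and water stress (Wε, from precipitation vs Thornthwaite potential
evapotranspiration).

The weak link is FPAR. Classically it is stretched linearly from NDVI and
the simple ratio (RVI), which saturates over dense canopies. This package
instead computes **15 vegetation indices** (ARVI, DVI, EVI, GEMI, GNDVI,
MSAVI, NDI45, NDVI, PVI, RVI, REIP, SAVI, TNDVI, TSAVI, WDVI) from
Sentinel-2-style band stacks, ranks them by **recursive feature
elimination** over gradient-boosted trees, and regresses FPAR with a small
**1-D convolutional neural network** (three conv layers of 16/32/64
filters, kernel 2, max-pooling, dropout 0.3, three dense layers, Adam at
lr 0.001, MSE loss, 7:3 split) implemented natively in vectorized R.
The empirical NDVI/RVI stretch stays available as the built-in baseline,
and gradient-boosted tree regressors (via xgboost) as reference models.

Because real campaigns rarely ship with truth, the package includes a
seeded **synthetic scene generator**: a rice/corn/forest/soil layout with
double-logistic LAI phenology, Beer–Lambert FPAR (k = 0.5), linear
canopy/soil spectral mixing with band noise, sinusoidal monthly
meteorology (9.3 °C annual mean, 710.2 mm precipitation by default),
optional cloud contamination, and ground-truth FPAR/NPP computed by the
same forward model — so every stage is testable end to end.

## Worked example

```r
library(cropCASA)

scene <- generateScene(sceneConfig(seed = 1))
scene
#> SceneTruth: 32 x 32 pixels, season months 4-10, seed 1

res <- runPipeline(pipelineConfig(list(seed = 1)))
print(res$model$report)
#> EvalReport (n = 827)
#>   R2 0.9901 | EVS 0.9903 | MSE 0.00124742 | RMSE 0.0353188 | MAE 0.028226 | MAPE NA%
#>   undefined: mape

round(res$evaluation$fparRmse, 4)
#>      4      5      6      7      8      9     10
#> 0.0378 0.0375 0.0312 0.0330 0.0318 0.0303 0.0404

cat(sprintf("NPP MAPE: %.2f%% (CNN) vs %.2f%% (empirical NDVI/RVI)\n",
            res$evaluation$nppMape, res$evaluation$nppMapeEmpirical))
#> NPP MAPE: 2.18% (CNN) vs 12.39% (empirical NDVI/RVI)
```

The held-out report scores the CNN on the 30% test split of 2,756
index/FPAR samples (MAPE is undefined because bare-soil samples have FPAR
exactly 0). The per-month numbers are FPAR RMSE of the predicted grids
against the scene truth; the final line compares growing-season
(April–October) NPP error over vegetated pixels for the two FPAR sources
— the CNN pipeline cuts the error by a factor of ~6 on this scene.

## Command line

A thin CLI over the same functions lives at `inst/cli/casa-npp.R`:

```sh
Rscript inst/cli/casa-npp.R simulate --seed 5 --out scene/
Rscript inst/cli/casa-npp.R indices --input scene/stack_7 --out idx/
Rscript inst/cli/casa-npp.R fpar-train --features samples.csv --model cnn --out model.json
Rscript inst/cli/casa-npp.R fpar-predict --model model.json --input scene/stack_7 --out fpar7.asc
Rscript inst/cli/casa-npp.R meteo --stations stations.csv --method kriging --out meteo/
Rscript inst/cli/casa-npp.R npp --fpar-dir fpar/ --meteo-dir meteo/ --season 4-10 --out npp/
Rscript inst/cli/casa-npp.R evaluate --observed obs.csv --predicted pred.csv
Rscript inst/cli/casa-npp.R run --seed 1 --out out/
```

Rasters are exchanged as plain-text ESRI ASCII grids (`.asc`, one file
per band/layer, with a JSON sidecar for band order and CRS), station
tables and samples as CSV, models as versioned JSON archives, and each
pipeline run writes a manifest recording the config hash, seed and
per-stage metrics.

## Vignette

`vignettes/casa-npp-methods.Rmd` documents the model equations and
adopted stress-scalar forms, the index formula conventions, the CNN
architecture and training protocol, what the synthetic scenes do and do
not emulate, and the package's numerical choices and limitations.
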