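Package: cropCASA
Title: Crop Net Primary Productivity with a CNN-Improved CASA Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates monthly and growing-season crop net primary productivity
    (NPP) with the Carnegie-Ames-Stanford Approach (CASA) light-use-efficiency
    model, driven by the fraction of absorbed photosynthetically active
    radiation (FPAR) retrieved from Sentinel-2-style multiband reflectance.
    Fifteen vegetation indices are computed from a band stack, ranked by
    recursive feature elimination, and fed to a small one-dimensional
    convolutional neural network that regresses FPAR; the classical empirical
    NDVI/RVI FPAR stretch is included as a baseline. Station meteorology is
    converted and interpolated to model grids (ordinary kriging or
    inverse-distance weighting), temperature and water stress scalars
    down-regulate the maximum light-use efficiency, and monthly NPP is
    aggregated over the growing season. A seeded synthetic-scene generator
    produces seasonal crop reflectance, meteorology, cloud contamination and
    ground-truth FPAR/NPP so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    xgboost,
    geosphere,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'cropCASA-package.R'
    'AllClasses.R'
    'constructors.R'
    'casa.R'
    'cnn.R'
    'metrics.R'
    'indices.R'
    'fpar.R'
    'scene.R'
    'io.R'
    'meteo.R'
    'pipeline.R'
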