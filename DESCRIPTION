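Package: woodtrend
Title: Woody Plant Cover Change Mapping and Driver Attribution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating three decades of fractional woody-plant-cover
    change from multispectral scene time series and attributing its spatial
    variation to climatic, edaphic and disturbance drivers. Implements the
    full pipeline at desk scale: an analysis mask excluding closed forest,
    forestry and non-natural landcover; per-epoch time-series spectral
    metrics (percentiles, windowed means, vegetation-index variance and
    range); a random-forest fractional-cover regressor trained on
    photo-interpretation quadrats; per-pixel ordinary-least-squares cover
    trends with quality weighting; a covariate suite (means and trends,
    extreme-rainfall counts, precipitation concentration index, depth-weighted
    soils, terrain ruggedness, boosted-tree hindcasting); and weighted
    Gaussian boosted regression trees with cross-validated deviance explained,
    relative importance, model simplification, partial dependence and a
    permutation sanity check. A seeded synthetic-landscape generator with
    known ground truth exercises every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    ranger,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
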