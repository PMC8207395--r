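Package: landmlpe
Title: Landscape Genetics Pipelines with Maximum-Likelihood Population
    Effects Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for individual-based landscape genetics on categorical
    land-use rasters: moving-window class-percentage (PLAND) surfaces,
    monomolecular and Ricker resistance transformations, commute-time
    (random-walk) distances on raster lattice graphs, PCA-based genetic
    distances from codominant genotypes, Mantel correlograms and
    semivariograms, and maximum-likelihood population effects (MLPE)
    mixed models with AICc-based optimization of resistance-surface
    scale and transformation. Includes seeded synthetic-data generators
    (patchy landscapes, nested sampling designs, genotypes, pairwise
    distances with MLPE covariance) and a congruence classifier for
    comparing inferences across nested sampling schemes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    MASS,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
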