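Package: ecovuln
Title: Spatial Ecological Vulnerability Assessment from Raster Indicator Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A raster pipeline for regional ecological vulnerability
    assessment under the exposure-sensitivity-adaptability (VSD) framework.
    Standardizes multi-source indicator surfaces to a common 0-10 scale,
    runs spatial principal component analysis to build an ecological
    vulnerability index (EVI), standardizes it across epochs (SVI), grades
    it into five vulnerability levels and aggregates the grades into a
    comprehensive index (CEVI) globally and by zone. Includes per-pixel
    least-squares trend detection with Jenks natural-breaks classing,
    FRAGSTATS-style landscape-pattern metrics (NP, LPI, AI, DIVISION, SHDI)
    globally and in moving windows, partial-regression contribution
    analysis linking landscape pattern to vulnerability, inverse-distance
    weighted interpolation of station data, and a seeded synthetic-landscape
    generator so the whole pipeline runs and validates without external
    rasters.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    EBImage
Config/testthat/edition: 3
RoxygenNote: 7.3.3
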