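---
title: "Assessing spatial ecological vulnerability with ecovuln: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing spatial ecological vulnerability with ecovuln}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The assessment model

`ecovuln` implements a raster workflow for regional ecological
vulnerability assessment under the exposure–sensitivity–adaptability
framework: external pressure on an ecosystem (population, tourism,
pollutant discharge), its propensity to be harmed (terrain, climate,
vegetation condition, land use), and its capacity to adjust (economic
resources, protection policy) are each represented by co-registered
indicator rasters, typically 30 m cells over a mountainous study region
observed in several epochs.

The pipeline runs in a fixed order, because the cross-year standardization
needs every epoch's index surface:

1. **Standardization.** Numeric indicators are rescaled to a common 0–10
   scale by the range method. For a positive-polarity indicator (larger raw
   value means more vulnerable) \(Y = 10\,(X - X_{min})/(X_{max} -
   X_{min})\); negative polarity mirrors it, \(Y = 10\,(X_{max} -
   X)/(X_{max} - X_{min})\). Categorical surfaces (land use above all) are
   scored by a hierarchical assignment table; the default gives forest and
   water 2, grassland 4, cultivated land 6 and construction land 8.
   Station-sampled indicators are first spatialized by inverse-distance
   weighting (power 2 over the 12 nearest stations by default; both exposed
   in configuration). Policy surfaces that arrive pre-scored on 0–10 are
   passed through unchanged.
2. **Spatial PCA.** Every valid cell of the common mask is an observation,
   every standardized layer a variable. The covariance matrix — not the
   correlation matrix — of this table is decomposed: the layers already
   share the 0–10 scale by construction, and rescaling to unit variance
   would re-weight indicators whose spread is itself informative. Scores
   are the mean-centered data projected on the eigenvectors, written back
   to grid geometry.
3. **Vulnerability index.** With contribution rates \(r_i = \lambda_i /
   \sum_j \lambda_j\), the ecological vulnerability index of a cell is
   \(EVI = \sum_{i \le k} r_i Y_i\) over the first \(k\) component scores,
   where \(k\) is the smallest count whose cumulative contribution reaches
   90%. The rates are used exactly as computed, not renormalized over the
   selected \(k\).
4. **Cross-year standardization and grading.** Each epoch's EVI is mapped
   to \(SVI = 10\,(EVI - EVI_{min})/(EVI_{max} - EVI_{min})\) with the
   extremes pooled over *all* epochs, making levels comparable across
   years. The SVI is cut into five equal-interval grades — micro (I),
   mild (II), moderate (III), severe (IV), extreme (V) — with lower-closed
   intervals: I \([0,2)\) … V \([8,10]\). The comprehensive index of a
   region is the area-weighted mean grade \(CEVI = \sum_i L_i A_i / S \in
   [1,5]\), reported for the whole region and per zone (towns), with zone
   membership decided by the cell-center-in-polygon rule.
5. **Trend.** At every cell valid in all epochs an ordinary least-squares
   line of EVI against the 1-based epoch index gives the slope \(K\);
   positive \(K\) means vulnerability increasing. The slope surface is cut
   into five change levels by Jenks natural breaks. (The source literature
   for this workflow contains a prose statement reading a predominance of
   positive slopes as an overall *downward* trend; the package follows the
   slope formula's sign semantics — positive means increasing — and leaves
   the interpretation to the analyst.)
6. **Landscape pattern and its contribution.** Five FRAGSTATS
   landscape-level metrics are computed from the land-use map, globally
   and in moving windows: patch count NP, largest patch index LPI,
   aggregation index AI, division DIVISION and Shannon diversity SHDI.
   Each window's metrics are paired with the window-mean EVI; per-metric
   univariate regressions and a full multiple regression with intercept
   follow. The contribution of metric \(X_i\) is measured by the partial
   regression sum of squares \(P_i = U - U_i\), the drop in the regression
   sum of squares \(U = \sum(\hat y - \bar y)^2\) when \(X_i\) is removed
   (intercept retained, so the models stay nested), and reported as the
   share \(S_i = 100\,P_i / \sum_j P_j\).

## Conventions that had to be fixed

Several details of this workflow are underdetermined in the literature and
are fixed here as package conventions, each chosen for determinism and
documented behaviour:

* **Raster model.** Row 1 is the northernmost row; cell \((r,c)\) covers a
  half-open square anchored at the upper-left `origin`. A single nodata
  sentinel per file marks invalid cells; the in-memory mask is
  authoritative, and every multi-layer statistic uses the intersection of
  the layer masks. Supported formats are ESRI ASCII grid and single-band
  GeoTIFF (uncompressed, strip-organised, with ModelPixelScale,
  ModelTiepoint and GDAL-nodata tags); zone polygons arrive as GeoJSON and
  are rasterized at load time.
* **Eigenvector signs.** Within one fit, each loading vector is oriented so
  its largest-magnitude entry is positive. Across epochs this per-fit rule
  is not stable: when two loadings are nearly tied the convention can flip
  a whole component between years, which injects an arbitrary static
  pattern into every cross-year quantity. The pipeline therefore
  additionally aligns each epoch's eigenvectors with the first epoch's
  (flipping any component whose dot product with the reference is
  negative), the standard practice for comparing empirical orthogonal
  functions over time.
* **Common component count.** The ≥90% rule is evaluated per epoch, and the
  maximum over epochs is used for every epoch. Mixing different \(k\)
  across years would compare sums over different subspaces; a single
  shared count keeps EVI surfaces commensurable for the SVI pooling and
  the trend fit.
* **Grading boundaries.** Lower-closed intervals, top class closed at 10,
  matching the published pattern "< 2.0" for level I and "≥ 8.0" for
  level V. CEVI tables are exported at two decimals, rounded half-up.
* **Jenks classing.** Fisher's exact dynamic program over the sorted
  distinct values (multiplicities as weights) minimizes the within-class
  sum of squared deviations; among equal-cost partitions the one with the
  smallest first break is returned. Above 10&nbsp;000 distinct values the
  breaks are fitted on a deterministic regular subsample of the sorted
  values and then applied to all cells; the trend surfaces classified in
  this package are far below that threshold, so the exact program runs in
  practice.
* **Landscape metrics.** The FRAGSTATS landscape-level definitions are
  adopted: NP is the patch count under 8-neighbour connectivity (4 is
  available); LPI is the largest patch's percentage of the landscape;
  DIVISION is \(1 - \sum (a_i/A)^2\) over patches; SHDI is
  \(-\sum p_c \ln p_c\) over class area shares; AI is
  \(100 \sum_c P_c\, g_{cc}/\max g_{cc}\) with single-count like
  adjacencies and the largest-integer-square bound for
  \(\max g_{cc}\) (classes of one cell contribute zero). Moving windows
  that would leave the grid are masked rather than padded, since padding
  distorts adjacency counts; adjacency is counted within the window only.
* **Regression sampling.** The sampling unit for the contribution analysis
  is the moving-window center on a regular stride (default: one window,
  i.e. non-overlapping windows), pairing the window's metrics with its
  mean EVI.

## The synthetic-landscape generator

Because the original rasters of any particular study are not required, the
package ships a seeded generator whose defaults define the study
conditions used by the tests and the acceptance script: a 200 × 200 grid of
30 m cells, three epochs, a forest share of 91%, eight towns with
log-uniform disturbance intensities, and a prescribed trend field in which
90% of cells drift toward higher vulnerability. Sixteen indicators are
emitted across the three framework dimensions, including a categorical
land-use mosaic grown from potential surfaces (construction and cultivated
land around the towns, grassland on high ground, a valley river system),
elevation-linked climate surfaces, kernel-based population and disturbance
fields, graded protection-policy scores and a station-sampled water-quality
field that the pipeline must interpolate itself.

The trend mechanism deserves explanation, because its design follows from
how the pipeline measures change. The SPCA centers each epoch's scores, so
the EVI trend at a cell measures its drift *relative to the
loading-weighted regional mean drift*; and the per-epoch range
standardization removes any common affine change. A prescribed trend field
therefore has to satisfy three structural conditions to be recoverable at
all:

* the degrading majority drifts with a tight magnitude spread (about ±3%
  around the configured scale), keeping every degrading cell above the
  regional mean drift;
* the recovering minority — protected cores under restoration — drifts
  about four times as fast in the opposite direction, which is what keeps
  the regional vulnerability load roughly stationary while preserving
  every cell's sign margin;
* the trend field is generated orthogonal (in sample) to the static
  spatial patterns of the landscape. Chance correlation between the trend
  field and a static pattern perturbs the covariance matrix
  antisymmetrically between the first and last epoch, rotates the leading
  eigenvectors, and leaks static structure into the fitted slopes.

Two further realism choices matter for trend identifiability: surfaces
interpolated from a fixed observation network (climate, hydrology, fiscal
statistics) carry a persistent spatial error drawn once rather than
re-randomized per epoch — re-drawing it would both be unrealistic (the same
network and method are reused every year, and terrain derivatives commonly
come from a single DEM) and masquerade as temporal change; and the
exposure surfaces carry positive baselines so that range clipping at zero
never freezes an epoch's values far from the towns. With the default
station density (60) and noise level (5% of each surface's scale), the
fitted positive-slope fraction recovers the prescribed 90% to within about
one percentage point on typical seeds, and per-cell sign agreement with
the truth map is above 99%.

What the generator does *not* emulate: real remote-sensing interpretation
error, mixed pixels, spatially autocorrelated classification noise,
non-stationary town growth, or any calibration to a particular geography.
Passing tests on this generator therefore demonstrate that the pipeline's
computations are correct and that its statistical behaviour matches the
generative model — not that any particular real landscape satisfies that
model.

## Problem sizes and runtime

The test suite exercises unit oracles on grids up to 20 × 20, property
suites on randomized small grids, and end-to-end runs on 60–80-cell
scenarios; the acceptance script and the `analysis/` drivers run the full
200 × 200, three-epoch scenario with 33-cell windows, which completes in
well under a minute on one CPU. Moving-window metrics and the Jenks
dynamic program are implemented in C++ (via Rcpp); everything else is
vectorized R over the matrix representation.

## Known limitations

* Reprojection and resampling are out of scope: all layers must already
  share one grid geometry, and the readers refuse misaligned stacks rather
  than fixing them.
* The GeoTIFF codec covers the single-band, uncompressed dialect the
  package writes (plus basic integer/float strip layouts); tiled or
  compressed files from other software are not supported — convert to
  ESRI ASCII grid in that case.
* EVI built from contribution-weighted component scores inherits the usual
  fragility of PCA-based composite indices: the effective weight a layer
  receives depends on the covariance structure, and components beyond the
  first can carry contrasts whose orientation toward "vulnerability" is
  conventional. The sign-alignment and common-\(k\) conventions above
  remove the arbitrary part, but interpretation of mid-order components
  still needs care.
* Significance testing of per-pixel trends and multiple-testing control
  across cells are deliberately absent; the trend surface is descriptive.
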