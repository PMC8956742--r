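# ecovuln

Spatial ecological vulnerability assessment from raster indicator stacks.

Regional planners and landscape ecologists often need to answer three
questions about a mountainous, forest-dominated region observed at several
points in time: *how vulnerable is each place*, *is vulnerability rising or
falling*, and *how much of it is explained by landscape pattern*. `ecovuln`
implements the standard raster workflow for all three under the
exposure–sensitivity–adaptability (VSD) framework:

- **Index construction.** Indicator surfaces are range-standardized to a
  common 0–10 scale (`standardize()`, with hierarchical scoring for
  categorical land use via `assign_categories()` and IDW spatialization of
  station data via `idw_interpolate()`), then combined by spatial principal
  component analysis (`fit_spca()`). With contribution rates
  $r_i = \lambda_i / \sum_j \lambda_j$, the ecological vulnerability index
  of a cell is

  $$EVI = \sum_{i \le k} r_i Y_i,$$

  over the first $k$ component scores $Y_i$, where $k$ is the smallest
  count reaching a 90% cumulative contribution.
- **Grading and aggregation.** EVI is standardized across epochs to
  $SVI \in [0,10]$ (`standardize_svi()`), cut into five equal-interval
  grades I–V (micro … extreme, `classify()`), and aggregated into the
  comprehensive index $CEVI = \sum_i L_i A_i / S \in [1,5]$ for the whole
  region and per town (`compute_cevi()`).
- **Change detection.** Per-pixel least-squares slopes of EVI across
  epochs (`fit_trend()`) with Jenks natural-breaks classing
  (`jenks_classify()`).
- **Landscape pattern.** FRAGSTATS-style NP, LPI, AI, DIVISION and SHDI,
  globally and in moving windows (`label_patches()`, `compute_metrics()`,
  `moving_window()`), and their contribution to vulnerability by
  leave-one-out partial regression sums of squares,
  $P_i = U - U_i$, $S_i = 100\,P_i/\sum_j P_j$
  (`partial_contributions()`).
- **Synthetic study landscapes.** A seeded generator
  (`generate_scenario()`) emits a full multi-epoch scenario — 16
  indicators, towns, zones, stations, prescribed per-pixel trends — so the
  entire pipeline runs and validates without any external rasters.

Rasters are read and written as ESRI ASCII grids or single-band GeoTIFFs;
zones as GeoJSON; stations as CSV (`read_grid()`, `read_zones()`,
`read_stations()`).

## Worked example

```r
library(ecovuln)

scn <- generate_scenario(scenario_config(seed = 42))  # 200 x 200, 3 epochs
run <- run_pipeline(scn)

run$cevi_table[, c("year", "Total")]
#>   year Total
#> 1 1996  3.29
#> 2 2007  3.26
#> 3 2018  3.25
#> 4 Mean  3.27

positive_trend_fraction(run$trend)
#> [1] 0.89805

run$landscape_global
#>   epoch np     lpi       ai  division      shdi
#> 1  1996 19 61.8825 98.34057 0.5291902 0.3999305
#> 2  2007 19 61.5100 98.27962 0.5337587 0.4158470
#> 3  2018 21 61.0425 98.25078 0.5395145 0.4308006
```

Region-wide vulnerability sits in the moderate band and declines slightly
across the three epochs, while 89.8% of cells carry a positive fitted
slope — matching the scenario's prescribed 90% of cells drifting toward
higher vulnerability (the region-wide *mean* stays level because the
recovering minority improves several times faster). The landscape stays a
forest matrix (LPI ≈ 61%, AI ≈ 98) whose patch count grows as construction
expands around the towns.

The same analysis, staged over intermediate files with tables under
`results/`, is scripted in `analysis/01_simulate.R` …
`analysis/05_contribution.R` (run them in order from the repository root).

## Package layout

- `R/` — grids and I/O, indicator standardization, SPCA, vulnerability
  indices and grading, trend, landscape metrics, contribution analysis,
  the scenario generator and the pipeline orchestrator.
- `src/` — Rcpp kernels: Jenks dynamic program, connected-component
  labeling, like-adjacency counts, moving-window metrics.
- `analysis/` — the numbered workflow drivers.
- `vignettes/ecovuln-methods.Rmd` — the methods notes: model, conventions,
  generator design, limitations.
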