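#' Configuration of a synthetic mountainous-landscape scenario
#'
#' Defines the study conditions the generator emulates: a forest-dominated
#' mosaic (91\% forest by default), eight town-centered population kernels,
#' elevation-correlated climate surfaces, a station-sampled water-quality
#' field, policy-zone masks, and a prescribed per-pixel vulnerability trend
#' (a configurable fraction of cells drifting upward across epochs). One
#' seed fixes all randomness end-to-end.
#'
#' @param rows,cols grid size in cells (default 200 x 200).
#' @param cell_size cell edge in metres (default 30).
#' @param seed integer seed fixing every random draw of the scenario.
#' @param epochs epoch labels, earliest first (default 1996, 2007, 2018).
#' @param class_props named class proportions over `forest`, `grassland`,
#'   `cultivated`, `construction`, `water`; must sum to 1.
#' @param n_towns number of towns (default 8; the zone map has one
#'   rectangular territory per town).
#' @param town_kernel_scale e-folding length of the population kernels in
#'   metres (default 2500).
#' @param town_disturbance optional vector of per-town disturbance
#'   intensities; drawn from the seed (log-uniform in \[0.5, 2.2\]) when
#'   `NULL`.
#' @param elev_smooth smoothing radius (cells) of the elevation field.
#' @param trend_positive_frac fraction of cells whose vulnerability drifts
#'   upward across epochs (default 0.9).
#' @param drift_scale magnitude scale of the per-epoch-step drift on the
#'   disturbance-core scale (default 0.5; 0 freezes the landscape).
#' @param noise_sd relative observation noise on the indicator surfaces
#'   (default 0.05 of each surface's scale; 0 for noise-free layers).
#' @param landuse_growth per-epoch-step relative growth of the
#'   construction class (default 0.25; 0 freezes land use).
#' @param n_stations number of water-quality monitoring stations
#'   (default 60).
#' @return object of class `ev_scenario_config`.
#' @export
scenario_config <- function(rows = 200, cols = 200, cell_size = 30, seed = 42,
                            epochs = c(1996, 2007, 2018),
                            class_props = c(forest = 0.91, grassland = 0.04,
                                            cultivated = 0.025,
                                            construction = 0.015, water = 0.01),
                            n_towns = 8, town_kernel_scale = 2500,
                            town_disturbance = NULL, elev_smooth = 8,
                            trend_positive_frac = 0.9, drift_scale = 0.5,
                            noise_sd = 0.05, landuse_growth = 0.25,
                            n_stations = 60) {
  if (abs(sum(class_props) - 1) > 1e-8)
    stop("class proportions must sum to 1", call. = FALSE)
  req <- c("forest", "grassland", "cultivated", "construction", "water")
  if (!all(req %in% names(class_props)))
    stop("class_props needs names: ", paste(req, collapse = ", "), call. = FALSE)
  if (rows * cols < 400L)
    stop("grid too small for a multi-class scenario", call. = FALSE)
  if (any(class_props < 0) ||
      min(class_props[req != "water"] * rows * cols) < 1)
    stop("infeasible class proportions on this grid size", call. = FALSE)
  structure(as.list(environment()), class = "ev_scenario_config")
}

# repeated box-blur of a matrix (reflecting edges), approximating a
# Gaussian smooth with radius `r` after 3 passes
smooth_field <- function(m, r, passes = 3) {
  if (r < 1) return(m)
  blur1d <- function(x) {
    n <- length(x)
    xx <- c(x[r:1], x, x[n:(n - r + 1)])
    cs <- c(0, cumsum(xx))
    (cs[(2 * r + 2):(n + 2 * r + 1)] - cs[1:n]) / (2 * r + 1)
  }
  for (p in seq_len(passes)) {
    m <- apply(m, 2L, blur1d)
    m <- t(apply(m, 1L, blur1d))
  }
  m
}

rescale01 <- function(m) (m - min(m)) / (max(m) - min(m))

# distance (map units) from every cell to the nearest of a set of cells
dist_to_cells <- function(rows, cols, cell_size, tr, tc) {
  rr <- matrix(seq_len(rows), rows, cols)
  cc <- matrix(seq_len(cols), rows, cols, byrow = TRUE)
  d2 <- matrix(Inf, rows, cols)
  for (i in seq_along(tr))
    d2 <- pmin(d2, (rr - tr[i])^2 + (cc - tc[i])^2)
  sqrt(d2) * cell_size
}

#' Generate a synthetic multi-epoch scenario
#'
#' Builds, reproducibly from the seed: a smoothed random elevation field
#' with derived slope and relief; a patchy five-class land-use map (a river
#' plus construction and cultivated land around the towns, grassland at
#' high elevation, forest elsewhere) honouring the configured proportions;
#' population and disturbance surfaces as sums of town-centered
#' exponential kernels; elevation-linked climate surfaces; policy-zone
#' score layers; a station-sampled water-quality field; and per-epoch
#' perturbations implementing the configured trend field (a prescribed
#' fraction of cells drifts toward higher vulnerability, the rest toward
#' lower).
#'
#' @param config an [scenario_config()].
#' @return list with `stacks` (one `ev_stack` of 16 raw indicator layers
#'   per epoch, with polarity metadata), `stations` (per-epoch
#'   `ev_stations` for the water-quality indicator), `zones` (`ev_zones`
#'   of town territories), `truth` (trend-sign map, drift magnitudes, town
#'   table with disturbance intensities, per-epoch class maps), and
#'   `config`.
#' @export
generate_scenario <- function(config) {
  stopifnot(inherits(config, "ev_scenario_config"))
  cf <- config
  set.seed(cf$seed)
  nr <- cf$rows; nc <- cf$cols; cs <- cf$cell_size
  n_cell <- nr * nc
  ne <- length(cf$epochs)
  template <- ev_grid(matrix(0, nr, nc), cell_size = cs,
                      origin = c(500000, 3500000), crs_tag = "EPSG:32649")

  ## --- terrain -------------------------------------------------------------
  elev <- 400 + 2700 * rescale01(smooth_field(matrix(stats::rnorm(n_cell), nr, nc),
                                              cf$elev_smooth))
  gx <- cbind(elev[, 2] - elev[, 1],
              (elev[, -(1:2), drop = FALSE] - elev[, 1:(nc - 2), drop = FALSE]) / 2,
              elev[, nc] - elev[, nc - 1]) / cs
  gy <- rbind(elev[2, ] - elev[1, ],
              (elev[-(1:2), , drop = FALSE] - elev[1:(nr - 2), , drop = FALSE]) / 2,
              elev[nr, ] - elev[nr - 1, ]) / cs
  slope <- atan(sqrt(gx^2 + gy^2)) * 180 / pi
  shift <- function(m, dr, dc) {
    r <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
    c <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
    m[r, c, drop = FALSE]
  }
  mx <- mn <- elev
  for (dr in -1:1) for (dc in -1:1) {
    s <- shift(elev, dr, dc)
    mx <- pmax(mx, s); mn <- pmin(mn, s)
  }
  relief <- mx - mn

  ## --- towns and zones -----------------------------------------------------
  tiles_c <- ceiling(sqrt(cf$n_towns))
  tiles_r <- ceiling(cf$n_towns / tiles_c)
  rb <- round(seq(0, nr, length.out = tiles_r + 1))
  cb <- round(seq(0, nc, length.out = tiles_c + 1))
  town_r <- town_c <- integer(cf$n_towns)
  zone_vals <- matrix(NA_real_, nr, nc)
  t_i <- 0L
  for (i in seq_len(tiles_r)) for (j in seq_len(tiles_c)) {
    if (t_i >= cf$n_towns) { # leftover tile joins the previous zone
      zone_vals[(rb[i] + 1):rb[i + 1], (cb[j] + 1):cb[j + 1]] <- t_i
      next
    }
    t_i <- t_i + 1L
    rs <- (rb[i] + 1):rb[i + 1]; csel <- (cb[j] + 1):cb[j + 1]
    zone_vals[rs, csel] <- t_i
    # towns sit low: the minimum-elevation cell of the tile interior
    sub <- elev[rs, csel]
    pos <- arrayInd(which.min(sub), dim(sub))
    town_r[t_i] <- rs[pos[1]]; town_c[t_i] <- csel[pos[2]]
  }
  zones <- zone_map(grid_like(template, zone_vals),
                    stats::setNames(sprintf("town%02d", seq_len(cf$n_towns)),
                                    as.character(seq_len(cf$n_towns))))
  intensity <- cf$town_disturbance
  if (is.null(intensity)) intensity <- exp(stats::runif(cf$n_towns, log(0.5), log(2.2)))
  if (length(intensity) != cf$n_towns)
    stop("town_disturbance must have one value per town", call. = FALSE)

  ## --- disturbance core and trend field ------------------------------------
  rr <- matrix(seq_len(nr), nr, nc)
  ccm <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  kern <- function(amp) {
    acc <- matrix(0, nr, nc)
    for (t in seq_len(cf$n_towns)) {
      d <- sqrt((rr - town_r[t])^2 + (ccm - town_c[t])^2) * cs
      acc <- acc + amp[t] * exp(-d / cf$town_kernel_scale)
    }
    acc
  }
  D <- kern(intensity)
  D <- 4 * D / max(D)                       # disturbance core on [0, 4]

  ## --- water system ---------------------------------------------------------
  # river: steepest-descent-biased walk across the grid
  river <- matrix(FALSE, nr, nc)
  pr <- which.min(elev[, 1]); pc <- 1L
  while (pc <= nc) {
    river[max(1, pr - 1):min(nr, pr), pc] <- TRUE
    steps <- c(-1L, 0L, 1L)
    e_next <- elev[pmin(pmax(pr + steps, 1L), nr), min(pc + 1L, nc)]
    pr <- pmin(pmax(pr + steps[which.min(e_next + stats::rnorm(3, 0, 20))], 1L), nr)
    pc <- pc + 1L
  }
  n_water_target <- round(cf$class_props["water"] * n_cell)
  if (sum(river) < n_water_target) {  # valley wetlands complete the water class
    need <- n_water_target - sum(river)
    cand <- order(elev + 3000 * river)[seq_len(need)]
    river[cand] <- TRUE
  } else if (sum(river) > n_water_target) {
    idx <- which(river)
    river[idx[seq_len(sum(river) - n_water_target)]] <- FALSE
  }
  water_dist <- dist_to_cells(nr, nc, cs, rr[river], ccm[river])
  # The trend field is prescribed as structure independent of the static
  # landscape, so it is generated orthogonal (in sample) to the static
  # spatial patterns: a smooth random field with the static fields' linear
  # span projected out. Without this, chance correlation between the trend
  # field and a static pattern rotates the leading eigenvectors between
  # epochs and leaks static structure into the fitted per-pixel trends.
  statics <- cbind(1, as.vector(D), as.vector(elev), as.vector(slope),
                   as.vector(relief), as.vector(smooth_field(D, 6)),
                   as.vector(smooth_field(elev, 6)),
                   as.vector(smooth_field(elev, 10)),
                   as.vector(water_dist), as.vector(smooth_field(water_dist, 6)))
  sgn_field <- smooth_field(matrix(stats::rnorm(n_cell), nr, nc), 4)
  sgn_field <- matrix(stats::lm.fit(statics, as.vector(sgn_field))$residuals, nr, nc)
  thr <- stats::quantile(sgn_field, 1 - cf$trend_positive_frac)
  T_sign <- ifelse(sgn_field > thr, 1, -1)  # +1 = vulnerability increasing
  # Drift magnitudes: the degrading majority drifts up with a tight
  # magnitude spread (about the scale), while the recovering minority —
  # protected cores under restoration — improves about four times as fast.
  # The tight positive spread keeps every degrading cell's drift well above
  # the regional mean drift, so per-pixel trends remain identifiable as
  # anomalies after the per-epoch centering inherent in the SPCA scores,
  # while the drift variance stays small against the static disturbance
  # pattern (limiting epoch-to-epoch rotation of the leading components).
  mag <- cf$drift_scale *
    (0.97 + 0.06 * rescale01(smooth_field(matrix(stats::rnorm(n_cell), nr, nc), 4)))
  mag[T_sign < 0] <- 4 * mag[T_sign < 0]
  drift <- T_sign * mag                     # per-epoch-step drift of the core
  delta <- seq_len(ne) - (ne + 1) / 2       # centered epoch index

  ## --- land use ------------------------------------------------------------
  urban_pot <- D + 0.6 * smooth_field(matrix(stats::rnorm(n_cell), nr, nc), 4) -
    0.002 * slope
  agri_pot <- kern(rep(1, cf$n_towns)) +
    0.8 * smooth_field(matrix(stats::rnorm(n_cell), nr, nc), 5) - 0.0005 * elev
  grass_pot <- 0.001 * elev + smooth_field(matrix(stats::rnorm(n_cell), nr, nc), 5)
  landuse_epochs <- vector("list", ne)
  for (e in seq_len(ne)) {
    lu <- matrix(1, nr, nc)                 # 1 = forest
    lu[river] <- 5                          # 5 = water
    free <- !river
    n_constr <- round(cf$class_props["construction"] * n_cell *
                        (1 + cf$landuse_growth * delta[e]))
    n_cult <- round(cf$class_props["cultivated"] * n_cell)
    n_grass <- round(cf$class_props["grassland"] * n_cell)
    ord <- order(urban_pot[free], decreasing = TRUE)
    constr_idx <- which(free)[ord[seq_len(n_constr)]]
    lu[constr_idx] <- 4
    free[constr_idx] <- FALSE
    ord <- order(agri_pot[free], decreasing = TRUE)
    cult_idx <- which(free)[ord[seq_len(n_cult)]]
    lu[cult_idx] <- 3
    free[cult_idx] <- FALSE
    ord <- order(grass_pot[free], decreasing = TRUE)
    grass_idx <- which(free)[ord[seq_len(n_grass)]]
    lu[grass_idx] <- 2
    landuse_epochs[[e]] <- lu
  }

  ## --- policy layers (pre-scored 0-10 surfaces) ----------------------------
  # graded protection intensity: remote high ground is strictly protected
  # (low vulnerability score), settled low ground hardly at all
  reserve_score <- 8 - 7 * rescale01(smooth_field(elev, 6))
  park_score <- 7 - 6 * rescale01(smooth_field(elev, 10))

  ## --- per-epoch indicator stacks ------------------------------------------
  noise <- function(scale) {
    if (cf$noise_sd == 0) matrix(0, nr, nc)
    else matrix(stats::rnorm(n_cell, 0, cf$noise_sd * scale), nr, nc)
  }
  # Interpolated single-network surfaces (climate, hydrology, fiscal) carry a
  # persistent spatial error, drawn once: the same station network and method
  # are reused every epoch, so their error does not re-randomize over time.
  temp_err <- noise(0.5); precip_err <- noise(25)
  sw_err <- noise(0.8); fiscal_err <- noise(0.5)
  meta <- data.frame(
    name = c("pop_density", "tourist_reception", "industrial_wastewater",
             "domestic_sewage", "temperature", "precipitation", "slope",
             "relief", "vegetation_coverage", "landuse", "water_distance",
             "surface_water", "water_quality", "fiscal_revenue",
             "national_park", "nature_reserve"),
    polarity = c("positive", "positive", "positive", "positive", "negative",
                 "negative", "positive", "positive", "negative", "categorical",
                 "negative", "negative", "positive", "negative", "scored",
                 "scored"))
  st_idx <- sample.int(n_cell, cf$n_stations)
  st_x <- template$origin[1] + (ccm[st_idx] - 0.5) * cs
  st_y <- template$origin[2] - (rr[st_idx] - 0.5) * cs
  stacks <- vector("list", ne)
  stations <- vector("list", ne)
  for (e in seq_len(ne)) {
    core <- D + delta[e] * drift
    g <- function(m) grid_like(template, m)
    layers <- list(
      pop_density = g(275 * (2 + core) * (1 + 0.05 * delta[e])),
      tourist_reception = g(pmax(25 * (2 + core) + noise(25), 0)),
      industrial_wastewater = g(pmax(8 * (2 + core) + noise(8), 0)),
      domestic_sewage = g(pmax(12 * (2 + core) + noise(12), 0)),
      temperature = g(24 - 0.006 * elev + temp_err),
      precipitation = g(800 + 0.25 * elev + precip_err),
      slope = g(slope),
      relief = g(relief),
      vegetation_coverage = g(pmin(pmax(0.85 - 0.12 * D - 0.05 * delta[e] * drift +
                                          noise(0.03), 0), 1)),
      landuse = g(landuse_epochs[[e]]),
      water_distance = g(water_dist),
      surface_water = g(pmax(2 + 0.004 * elev + sw_err, 0)),
      water_quality = NULL,   # filled from stations by the pipeline (IDW)
      fiscal_revenue = g(5 + 0.5 * D + fiscal_err),
      national_park = g(park_score),
      nature_reserve = g(reserve_score)
    )
    core_at <- core[st_idx]
    stations[[e]] <- station_set(data.frame(
      x = st_x, y = st_y,
      value = pmax(8 + 3 * core_at +
                     if (cf$noise_sd == 0) 0 else
                       stats::rnorm(cf$n_stations, 0, cf$noise_sd), 0)))
    layers$water_quality <- NULL
    stacks[[e]] <- indicator_stack(cf$epochs[e], layers[!vapply(layers, is.null, TRUE)],
                                   meta = meta[meta$name != "water_quality", ])
  }
  names(stacks) <- as.character(cf$epochs)
  names(stations) <- as.character(cf$epochs)

  truth <- list(
    trend_sign = grid_like(template, T_sign),
    drift_magnitude = grid_like(template, mag),
    towns = data.frame(town = zones$names, row = town_r, col = town_c,
                       x = template$origin[1] + (town_c - 0.5) * cs,
                       y = template$origin[2] - (town_r - 0.5) * cs,
                       disturbance = intensity),
    landuse = lapply(landuse_epochs, function(m) grid_like(template, m)),
    elevation = grid_like(template, elev),
    positive_fraction = mean(T_sign > 0))
  list(stacks = stacks, stations = stations, zones = zones, truth = truth,
       config = cf)
}

#' Write a scenario to disk in the pipeline's on-disk layout
#'
#' Emits one GeoTIFF per indicator per epoch (the land-use map also as an
#' ESRI ASCII grid), per-epoch station CSVs, the town territories as
#' GeoJSON, the truth bundle as JSON, and a ready-to-run `config.yaml`.
#'
#' @param scenario result of [generate_scenario()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cf <- scenario$config
  epochs <- as.character(cf$epochs)
  layer_paths <- list()
  for (e in epochs) {
    ed <- file.path(dir, e)
    dir.create(ed, showWarnings = FALSE)
    st <- scenario$stacks[[e]]
    for (nm in names(st$layers)) {
      p <- file.path(ed, paste0(nm, ".tif"))
      write_grid(st$layers[[nm]], p)
      layer_paths[[e]][[nm]] <- p
    }
    write_grid(st$layers$landuse, file.path(ed, "landuse.asc"), nodata = -9999)
    utils::write.csv(scenario$stations[[e]]$points,
                     file.path(ed, "stations_water_quality.csv"),
                     row.names = FALSE)
  }
  write_zones_geojson(scenario$zones, file.path(dir, "zones.geojson"))
  tr <- scenario$truth
  jsonlite::write_json(list(
    positive_fraction = tr$positive_fraction,
    towns = tr$towns,
    epochs = cf$epochs, seed = cf$seed), file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA)
  write_grid(tr$trend_sign, file.path(dir, "truth_trend_sign.tif"))
  meta <- scenario$stacks[[1]]$meta
  config <- list(
    epochs = as.list(stats::setNames(lapply(epochs, function(e) list(
      rasters = file.path(e, paste0(meta$name, ".tif")),
      stations = list(water_quality = file.path(e, "stations_water_quality.csv")))),
      epochs)),
    indicators = stats::setNames(as.list(meta$polarity), meta$name),
    station_polarity = list(water_quality = "positive"),
    zones = "zones.geojson",
    landuse_table = as.list(stats::setNames(unname(LANDUSE_SCORES[c("forest",
      "grassland", "cultivated", "construction", "water")]), as.character(1:5))),
    spca_threshold = 90,
    window = local({ w <- min(33, floor(min(cf$rows, cf$cols) / 3))
                     if (w %% 2 == 0) w - 1 else w }),
    stride = local({ w <- min(33, floor(min(cf$rows, cf$cols) / 3))
                     if (w %% 2 == 0) w - 1 else w }),
    idw = list(power = 2, k = 12))
  yaml::write_yaml(config, file.path(dir, "config.yaml"))
  invisible(dir)
}

# rectangular-tile zone polygons as a GeoJSON FeatureCollection
write_zones_geojson <- function(zones, path) {
  zg <- zones$zones
  cs <- zg$cell_size
  feats <- lapply(sort(as.numeric(names(zones$names))), function(code) {
    sel <- which(zg$values == code, arr.ind = TRUE)
    r0 <- min(sel[, 1]) - 1; r1 <- max(sel[, 1])
    c0 <- min(sel[, 2]) - 1; c1 <- max(sel[, 2])
    x0 <- zg$origin[1] + c0 * cs; x1 <- zg$origin[1] + c1 * cs
    y0 <- zg$origin[2] - r1 * cs; y1 <- zg$origin[2] - r0 * cs
    list(type = "Feature",
         properties = list(code = code, name = unname(zones$names[as.character(code)])),
         geometry = list(type = "Polygon", coordinates = list(list(
           c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1), c(x0, y0)))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats), path,
                       auto_unbox = TRUE, digits = NA)
}

#' Compare pipeline outputs against the scenario truth
#'
#' Reports how well the pipeline recovered the scenario's generative
#' structure: (a) the fraction of cells with a fitted positive trend slope
#' and its per-cell sign agreement with the true trend-sign map, (b) the
#' Spearman rank correlation between town-level mean CEVI and the towns'
#' configured disturbance intensity, and (c) a landscape-pattern sanity
#' check — mean aggregation index near towns versus deep forest.
#'
#' @param truth the `truth` element of [generate_scenario()].
#' @param trend an `ev_trend` fitted on the scenario EVI surfaces.
#' @param cevi_by_zone named numeric (or matrix epochs x zones) of per-town
#'   CEVI from [compute_cevi()].
#' @param ai_surface optional `ev_grid` AI moving-window surface of the
#'   last epoch.
#' @param town_radius radius (m) defining "near town" for the AI check.
#' @return list `positive_fraction`, `true_positive_fraction`,
#'   `sign_agreement`, `cevi_rank_correlation`, `ai_near_towns`,
#'   `ai_far_from_towns`.
#' @export
recovery_report <- function(truth, trend, cevi_by_zone = NULL,
                            ai_surface = NULL, town_radius = 1500) {
  slope <- if (inherits(trend, "ev_trend")) trend$slope else trend
  ts <- truth$trend_sign
  if (!same_geometry(slope, ts))
    stop("trend surface does not match the scenario geometry", call. = FALSE)
  m <- slope$mask & ts$mask
  fitted_sign <- sign(slope$values[m])
  out <- list(
    positive_fraction = mean(slope$values[m] > 0),
    true_positive_fraction = mean(ts$values[m] > 0),
    sign_agreement = mean(fitted_sign == ts$values[m]))
  if (!is.null(cevi_by_zone)) {
    cz <- if (is.matrix(cevi_by_zone)) colMeans(cevi_by_zone) else cevi_by_zone
    int <- truth$towns$disturbance[match(names(cz), truth$towns$town)]
    out$cevi_rank_correlation <-
      stats::cor(cz, int, method = "spearman", use = "complete.obs")
  }
  if (!is.null(ai_surface)) {
    d <- dist_to_cells(nrow(ts$values), ncol(ts$values), ts$cell_size,
                       truth$towns$row, truth$towns$col)
    near <- ai_surface$mask & d <= town_radius
    far <- ai_surface$mask & d > 3 * town_radius
    out$ai_near_towns <- mean(ai_surface$values[near])
    out$ai_far_from_towns <- mean(ai_surface$values[far])
  }
  out
}
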