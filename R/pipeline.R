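#' Run the full vulnerability pipeline
#'
#' Executes the stages in order: per-epoch indicator standardization
#' (range standardization, categorical assignment, IDW spatialization of
#' station indicators), spatial PCA, EVI per epoch, cross-epoch SVI,
#' five-level grading and CEVI (global and per zone), per-pixel trend with
#' natural-breaks classing, landscape-pattern metrics (global and moving
#' window), and the partial-regression contribution analysis linking the
#' two. The pipeline draws no random numbers: identical inputs give
#' identical outputs (and identical manifests when written to disk).
#'
#' @param x a scenario from [generate_scenario()], or the path to a
#'   `config.yaml` in the layout written by [write_scenario()].
#' @param out_dir optional output directory; when given, rasters (GeoTIFF),
#'   tables (CSV) and a checksum manifest are written.
#' @param spca_threshold cumulative-contribution threshold (percent) for
#'   component selection (default 90).
#' @param window,stride moving-window side and sampling stride in cells for
#'   the landscape/contribution stage (defaults 33 and 33; the window is
#'   shrunk to the largest odd size fitting the grid if needed).
#' @param idw_power,idw_k IDW parameters for station indicators.
#' @param scheme vulnerability [grading_scheme()].
#' @param landuse_layer name of the categorical land-use layer.
#' @param landuse_table category-to-score table for that layer (default
#'   [LANDUSE_SCORES] keyed `1..5`).
#' @return object of class `ev_run`; see Details.
#' @details The returned list carries: `std_stacks`, `spca`, `k`, `evi`,
#'   `svi`, `grades`, `cevi_table`, `trend`, `positive_fraction`,
#'   `landscape_global`, `metric_surfaces` (last epoch), `contribution`
#'   and `simple_fits` (per epoch), and `manifest` (when written).
#' @export
run_pipeline <- function(x, out_dir = NULL, spca_threshold = 90,
                         window = 33, stride = window,
                         idw_power = 2, idw_k = 12,
                         scheme = grading_scheme(),
                         landuse_layer = "landuse", landuse_table = NULL) {
  scn <- if (is.character(x)) load_run_config(x) else x
  if (is.character(x)) {
    cfg <- scn$cfg
    spca_threshold <- cfg$spca_threshold %||% spca_threshold
    window <- cfg$window %||% window
    stride <- cfg$stride %||% stride
    if (!is.null(cfg$idw)) { idw_power <- cfg$idw$power; idw_k <- cfg$idw$k }
    if (!is.null(cfg$landuse_table))
      landuse_table <- stats::setNames(as.numeric(unlist(cfg$landuse_table)),
                                       names(cfg$landuse_table))
  }
  stacks <- scn$stacks
  epochs <- names(stacks)
  stations <- scn$stations
  station_polarity <- scn$station_polarity %||% list()

  ## stage 1: standardization -------------------------------------------------
  std_stacks <- lapply(epochs, function(e) {
    st <- stacks[[e]]
    meta <- st$meta
    out <- list()
    for (nm in names(st$layers)) {
      pol <- meta$polarity[meta$name == nm]
      g <- st$layers[[nm]]
      out[[nm]] <- switch(pol,
        positive = standardize(g, "positive")$grid,
        negative = standardize(g, "negative")$grid,
        categorical = assign_categories(g, landuse_table)$grid,
        scored = grid_like(g, pmin(pmax(g$values, 0), 10)),
        stop("unknown polarity `", pol, "` for layer `", nm, "`", call. = FALSE))
    }
    stn <- stations[[e]]
    if (!is.null(stn)) {
      if (inherits(stn, "ev_stations")) stn <- list(water_quality = stn)
      for (nm in names(stn)) {
        surf <- idw_interpolate(stn[[nm]], st$layers[[1L]],
                                power = idw_power, k = idw_k)
        pol <- station_polarity[[nm]] %||% "positive"
        out[[nm]] <- standardize(surf, pol)$grid
      }
    }
    indicator_stack(st$epoch, out)
  })
  names(std_stacks) <- epochs

  ## stage 2: SPCA and EVI ----------------------------------------------------
  spca <- lapply(std_stacks, fit_spca)
  # cross-epoch sign alignment: eigenvector sign is arbitrary, and the
  # per-fit convention can flip between epochs when two loadings are nearly
  # tied; orient every epoch's components consistently with the first
  # epoch's so the EVI surfaces are comparable over time
  ref <- spca[[1L]]$loadings
  for (e in epochs[-1L]) {
    for (i in seq_len(ncol(ref))) {
      if (sum(spca[[e]]$loadings[, i] * ref[, i]) < 0) {
        spca[[e]]$loadings[, i] <- -spca[[e]]$loadings[, i]
        g <- spca[[e]]$scores[[i]]
        spca[[e]]$scores[[i]] <- grid_like(g, -g$values, mask = g$mask)
      }
    }
  }
  # one common k across epochs (the largest per-epoch selection), so the
  # EVI of different years combines the same number of components and
  # stays comparable for the cross-year standardization and trend fit
  k_epoch <- vapply(spca, function(p)
    select_components(100 * p$cumulative_rates, spca_threshold), 0L)
  k <- stats::setNames(rep(max(k_epoch), length(k_epoch)), names(k_epoch))
  evi <- lapply(epochs, function(e) compute_evi(spca[[e]], k[[e]]))
  names(evi) <- epochs

  ## stage 3: SVI, grading, CEVI ----------------------------------------------
  svi <- standardize_svi(evi)
  grades <- lapply(svi, classify, scheme = scheme)
  cevi_tab <- cevi_table(grades, scn$zones)

  ## stage 4: trend -----------------------------------------------------------
  trend <- fit_trend(evi)
  trend <- jenks_classify(trend)
  pos_frac <- positive_trend_fraction(trend)

  ## stage 5: landscape metrics and contribution ------------------------------
  win <- min(window, min(dim(std_stacks[[1]]$layers[[1]]$values)))
  if (win %% 2 == 0) win <- win - 1L
  lu <- lapply(epochs, function(e) stacks[[e]]$layers[[landuse_layer]])
  names(lu) <- epochs
  landscape_global <- do.call(rbind, lapply(epochs, function(e)
    data.frame(epoch = e, t(compute_metrics(label_patches(lu[[e]]))))))
  designs <- lapply(epochs, function(e)
    window_design(lu[[e]], evi[[e]], win, stride))
  names(designs) <- epochs
  contribution <- lapply(designs, partial_contributions)
  simple_fits <- lapply(designs, simple_regressions)
  metric_surfaces <- moving_window(lu[[length(lu)]], win, stride)

  run <- structure(list(
    std_stacks = std_stacks, spca = spca, k = k, evi = evi, svi = svi,
    grades = grades, cevi_table = cevi_tab, trend = trend,
    positive_fraction = pos_frac, landscape_global = landscape_global,
    designs = designs, contribution = contribution, simple_fits = simple_fits,
    metric_surfaces = metric_surfaces, zones = scn$zones,
    params = list(spca_threshold = spca_threshold, window = win,
                  stride = stride, idw_power = idw_power, idw_k = idw_k)),
    class = "ev_run")
  if (!is.null(out_dir)) run$manifest <- write_run(run, out_dir)
  run
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# load the on-disk layout written by write_scenario() into the in-memory
# shape run_pipeline() consumes
load_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(path)
  pol <- unlist(cfg$indicators)
  meta <- data.frame(name = names(pol), polarity = unname(pol))
  stacks <- list(); stations <- list()
  for (e in names(cfg$epochs)) {
    ep <- cfg$epochs[[e]]
    layers <- list()
    for (p in ep$rasters) {
      nm <- tools::file_path_sans_ext(basename(p))
      layers[[nm]] <- read_grid(file.path(base, p))
    }
    stacks[[e]] <- indicator_stack(e, layers,
                                   meta = meta[meta$name %in% names(layers), ])
    stations[[e]] <- lapply(ep$stations, function(p)
      read_stations(file.path(base, p)))
  }
  zones <- NULL
  if (!is.null(cfg$zones))
    zones <- read_zones(file.path(base, cfg$zones), stacks[[1]]$layers[[1]])
  list(stacks = stacks, stations = stations, zones = zones,
       station_polarity = cfg$station_polarity, cfg = cfg)
}

# write rasters, tables and a checksum manifest for a finished run
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  put_grid <- function(g, name) {
    p <- file.path(out_dir, paste0(name, ".tif"))
    write_grid(g, p); paths <<- c(paths, p)
  }
  put_csv <- function(df, name) {
    p <- file.path(out_dir, paste0(name, ".csv"))
    utils::write.csv(df, p, row.names = FALSE); paths <<- c(paths, p)
  }
  for (e in names(run$evi)) {
    put_grid(run$evi[[e]], paste0("evi_", e))
    put_grid(run$svi[[e]], paste0("svi_", e))
    put_grid(run$grades[[e]]$classes, paste0("grade_", e))
    put_csv(spca_table(run$spca[[e]]), paste0("spca_", e))
    put_csv(data.frame(indicator = rownames(run$spca[[e]]$loadings),
                       run$spca[[e]]$loadings[, seq_len(run$k[[e]]), drop = FALSE],
                       check.names = FALSE), paste0("loadings_", e))
    put_csv(run$contribution[[e]]$table, paste0("contribution_", e))
    put_csv(run$simple_fits[[e]], paste0("simple_regressions_", e))
  }
  put_grid(run$trend$slope, "trend_slope")
  put_grid(run$trend$classes, "trend_classes")
  put_csv(data.frame(break_value = run$trend$breaks), "trend_breaks")
  for (nm in names(run$metric_surfaces))
    put_grid(run$metric_surfaces[[nm]], paste0("metric_", nm))
  put_csv(run$cevi_table, "cevi")
  put_csv(run$landscape_global, "landscape_global")
  shares <- do.call(rbind, lapply(names(run$grades), function(e)
    data.frame(epoch = e, level = c("I", "II", "III", "IV", "V"),
               share_pct = 100 * unname(run$grades[[e]]$proportions))))
  put_csv(shares, "grade_shares")
  manifest <- data.frame(file = basename(paths),
                         md5 = unname(tools::md5sum(paths)))
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}
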