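#' Single-band raster grid
#'
#' The basic spatial container of the pipeline: a rectangular grid of cell
#' values with a validity mask and minimal georeferencing. Row 1 is the
#' northernmost row; cell (r, c) covers the half-open square
#' \eqn{[x, x + cell) \times (y - cell, y]} measured from the upper-left
#' corner `origin`. Invalid (nodata) cells are held as `NA` in `values` and
#' `FALSE` in `mask`; every statistic in the package ignores them.
#'
#' @param values numeric matrix of cell values (row 1 = north).
#' @param cell_size cell edge length in metres (default 30).
#' @param origin numeric `c(x, y)` map coordinates of the upper-left corner.
#' @param crs_tag opaque CRS string carried through I/O, never interpreted.
#' @param mask optional logical matrix marking valid cells; defaults to
#'   `!is.na(values)`. Cells invalid in `mask` are set to `NA` in `values`.
#' @return an object of class `ev_grid`.
#' @export
ev_grid <- function(values, cell_size = 30, origin = c(0, 0), crs_tag = "",
                    mask = NULL) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(mask)) mask <- !is.na(values)
  if (!is.logical(mask)) mask <- as.logical(mask) & !is.na(mask)
  dim(mask) <- dim(values)
  if (!identical(dim(mask), dim(values)))
    stop("`mask` and `values` must have identical shape", call. = FALSE)
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("`cell_size` must be a single positive number", call. = FALSE)
  mask <- mask & !is.na(values) & is.finite(values)
  values[!mask] <- NA_real_
  structure(
    list(values = values, mask = mask, cell_size = as.numeric(cell_size),
         origin = as.numeric(origin[1:2]), crs_tag = as.character(crs_tag)),
    class = "ev_grid"
  )
}

#' @export
print.ev_grid <- function(x, ...) {
  v <- x$values[x$mask]
  cat(sprintf("<ev_grid> %d x %d cells, %g m; %d valid (%.1f%%)\n",
              nrow(x$values), ncol(x$values), x$cell_size,
              length(v), 100 * length(v) / length(x$values)))
  if (length(v))
    cat(sprintf("  range [%g, %g], origin (%g, %g)\n",
                min(v), max(v), x$origin[1], x$origin[2]))
  invisible(x)
}

is_ev_grid <- function(x) inherits(x, "ev_grid")

#' Number of valid cells of a grid
#' @param grid an `ev_grid`.
#' @return integer count of unmasked cells.
#' @export
n_valid <- function(grid) sum(grid$mask)

#' Valid cell values of a grid as a vector
#' @param grid an `ev_grid`.
#' @return numeric vector of the values at valid cells (column-major order).
#' @export
grid_values <- function(grid) grid$values[grid$mask]

#' Replace a grid's values keeping its geometry
#'
#' @param grid template `ev_grid`.
#' @param values matrix (or vector recycled to the grid shape) of new values.
#' @param mask optional new validity mask; defaults to the template's mask
#'   intersected with non-`NA` values.
#' @return an `ev_grid` with the template's geometry.
#' @export
grid_like <- function(grid, values, mask = NULL) {
  if (!is.matrix(values)) values <- matrix(values, nrow(grid$values), ncol(grid$values))
  if (is.null(mask)) mask <- grid$mask & !is.na(values)
  ev_grid(values, grid$cell_size, grid$origin, grid$crs_tag, mask = mask)
}

same_geometry <- function(a, b, tol = 1e-6) {
  identical(dim(a$values), dim(b$values)) &&
    abs(a$cell_size - b$cell_size) <= tol * a$cell_size &&
    all(abs(a$origin - b$origin) <= tol * a$cell_size)
}

#' Map coordinates of all cell centers
#' @param grid an `ev_grid`.
#' @return list with matrices `x` and `y` of cell-center coordinates.
#' @export
cell_centers <- function(grid) {
  nr <- nrow(grid$values); nc <- ncol(grid$values); cs <- grid$cell_size
  x <- matrix(grid$origin[1] + (seq_len(nc) - 0.5) * cs, nr, nc, byrow = TRUE)
  y <- matrix(grid$origin[2] - (seq_len(nr) - 0.5) * cs, nr, nc)
  list(x = x, y = y)
}

# ---------------------------------------------------------------------------
# Indicator stacks

#' Aligned multi-indicator raster stack for one epoch
#'
#' @param epoch epoch label (e.g. a year).
#' @param layers named list of `ev_grid` layers, one per indicator.
#' @param meta optional data.frame with columns `name` and
#'   `polarity` (one of `"positive"`, `"negative"`, `"categorical"`); rows are
#'   matched to layers by `name`.
#' @return object of class `ev_stack` with the common validity mask in
#'   `$common_mask`.
#' @export
indicator_stack <- function(epoch, layers, meta = NULL) {
  if (length(layers) < 1L) stop("need at least one layer", call. = FALSE)
  nm <- names(layers)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm))
    stop("layers must have unique non-empty names", call. = FALSE)
  if (!is.null(meta)) {
    if (!all(c("name", "polarity") %in% names(meta)))
      stop("meta needs columns `name` and `polarity`", call. = FALSE)
    missing <- setdiff(nm, meta$name)
    if (length(missing))
      stop("meta missing indicators: ", paste(missing, collapse = ", "), call. = FALSE)
    meta <- meta[match(nm, meta$name), , drop = FALSE]
  }
  x <- structure(list(epoch = epoch, layers = layers, meta = meta,
                      common_mask = NULL), class = "ev_stack")
  assert_aligned(x)
}

#' @export
print.ev_stack <- function(x, ...) {
  cat(sprintf("<ev_stack> epoch %s: %d layers [%s]\n", format(x$epoch),
              length(x$layers), paste(names(x$layers), collapse = ", ")))
  invisible(x)
}

#' Validate that all layers of a stack share one geometry
#'
#' Checks shape, cell size and origin of every layer against the first and
#' records the common validity mask (the cellwise intersection of all layer
#' masks) in `$common_mask`. All multi-layer statistics in the package use
#' that intersection mask only.
#'
#' @param stack an `ev_stack`.
#' @return the validated stack, invisibly if already validated.
#' @export
assert_aligned <- function(stack) {
  stopifnot(inherits(stack, "ev_stack"))
  ref <- stack$layers[[1L]]
  for (nm in names(stack$layers)) {
    g <- stack$layers[[nm]]
    if (!is_ev_grid(g)) stop("layer `", nm, "` is not an ev_grid", call. = FALSE)
    if (!identical(dim(g$values), dim(ref$values)))
      stop("alignment error: layer `", nm, "` has shape ",
           paste(dim(g$values), collapse = "x"), ", expected ",
           paste(dim(ref$values), collapse = "x"), call. = FALSE)
    if (abs(g$cell_size - ref$cell_size) > 1e-9 * ref$cell_size)
      stop("alignment error: layer `", nm, "` cell_size mismatch", call. = FALSE)
    if (any(abs(g$origin - ref$origin) > 1e-6 * ref$cell_size))
      stop("alignment error: layer `", nm, "` origin mismatch", call. = FALSE)
  }
  m <- Reduce(`&`, lapply(stack$layers, `[[`, "mask"))
  stack$common_mask <- m
  stack
}

# ---------------------------------------------------------------------------
# Areas and zones

#' Per-class areas of a categorical grid
#'
#' @param grid an `ev_grid` holding integer category codes.
#' @return named numeric vector mapping each code to its area in square
#'   metres (cell count times `cell_size^2`); names sorted by code.
#' @export
class_areas <- function(grid) {
  stopifnot(is_ev_grid(grid))
  v <- grid_values(grid)
  if (!length(v)) stop("grid has no valid cells", call. = FALSE)
  tab <- table(v)
  a <- as.numeric(tab) * grid$cell_size^2
  names(a) <- names(tab)
  a
}

#' Zone map: integer zone codes plus labels
#'
#' @param zones an `ev_grid` of integer zone codes.
#' @param names named character vector mapping code (as name) to zone label;
#'   must cover every code present.
#' @return object of class `ev_zones`.
#' @export
zone_map <- function(zones, names) {
  stopifnot(is_ev_grid(zones))
  codes <- sort(unique(grid_values(zones)))
  miss <- setdiff(as.character(codes), base::names(names))
  if (length(miss))
    stop("zone labels missing for codes: ", paste(miss, collapse = ", "),
         call. = FALSE)
  structure(list(zones = zones, names = names), class = "ev_zones")
}

# even-odd (crossing number) point-in-polygon, vectorized over points
points_in_ring <- function(px, py, rx, ry) {
  n <- length(rx)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    cross <- ((ry[i] > py) != (ry[j] > py)) &
      (px < (rx[j] - rx[i]) * (py - ry[i]) / (ry[j] - ry[i]) + rx[i])
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Read zone polygons from GeoJSON and rasterize onto a template grid
#'
#' Polygons (or MultiPolygons) from a GeoJSON FeatureCollection are burned
#' onto the template geometry by the cell-center rule: a cell belongs to the
#' zone whose polygon contains its center (even-odd rule, so interior rings
#' punch holes). Later features overwrite earlier ones where they overlap.
#' The zone code is the feature property `code` if present, else the 1-based
#' feature index; the label is the property `name` if present.
#'
#' @param path GeoJSON file.
#' @param template `ev_grid` defining the output geometry.
#' @return an `ev_zones` object; cells in no polygon are masked.
#' @export
read_zones <- function(path, template) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- if (identical(gj$type, "FeatureCollection")) gj$features else list(gj)
  if (!length(feats)) stop("no features in ", path, call. = FALSE)
  ctr <- cell_centers(template)
  px <- as.vector(ctr$x); py <- as.vector(ctr$y)
  codes <- rep(NA_real_, length(px))
  labels <- character(0)
  for (k in seq_along(feats)) {
    f <- feats[[k]]
    code <- if (!is.null(f$properties$code)) as.numeric(f$properties$code) else k
    lab <- if (!is.null(f$properties$name)) as.character(f$properties$name) else paste0("zone", k)
    geom <- f$geometry
    polys <- switch(geom$type,
      Polygon = list(geom$coordinates),
      MultiPolygon = geom$coordinates,
      stop("unsupported geometry type: ", geom$type, call. = FALSE))
    inside <- logical(length(px))
    for (poly in polys) {
      for (ring in poly) {
        rx <- vapply(ring, function(p) as.numeric(p[[1]]), 0)
        ry <- vapply(ring, function(p) as.numeric(p[[2]]), 0)
        # drop duplicated closing vertex
        if (rx[1] == rx[length(rx)] && ry[1] == ry[length(ry)]) {
          rx <- rx[-length(rx)]; ry <- ry[-length(ry)]
        }
        inside <- xor(inside, points_in_ring(px, py, rx, ry))
      }
    }
    codes[inside] <- code
    labels[as.character(code)] <- lab
  }
  zg <- grid_like(template,
                  matrix(codes, nrow(template$values), ncol(template$values)),
                  mask = template$mask & !is.na(codes))
  zone_map(zg, labels)
}
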