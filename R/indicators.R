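#' Default land-use vulnerability assignment
#'
#' Hierarchical scores on the common 0-10 vulnerability scale for the five
#' land-use categories: forest and water score low (well-buffered systems),
#' construction land scores high.
#' @export
LANDUSE_SCORES <- c(forest = 2, grassland = 4, cultivated = 6,
                    construction = 8, water = 2)

#' Range-standardize an indicator surface to the 0-10 vulnerability scale
#'
#' Positive-polarity indicators (larger raw value means more vulnerable) map
#' through \eqn{Y = 10 (X - X_{min}) / (X_{max} - X_{min})}; negative-polarity
#' indicators through \eqn{Y = 10 (X_{max} - X) / (X_{max} - X_{min})}. After
#' standardization a larger value always means a more vulnerable cell.
#'
#' @param grid numeric `ev_grid` of raw indicator values.
#' @param polarity `"positive"` or `"negative"`.
#' @param x_min,x_max optional extreme overrides (e.g. pooled across epochs
#'   for comparability); by default the extremes of the grid's valid cells.
#' @return object of class `ev_std`: fields `grid` (values in \[0, 10\]),
#'   `source_name`, `polarity`, `x_min`, `x_max`.
#' @export
standardize <- function(grid, polarity = c("positive", "negative"),
                        x_min = NULL, x_max = NULL) {
  stopifnot(is_ev_grid(grid))
  polarity <- match.arg(polarity)
  v <- grid_values(grid)
  if (!length(v)) stop("grid has no valid cells", call. = FALSE)
  if (is.null(x_min)) x_min <- min(v)
  if (is.null(x_max)) x_max <- max(v)
  if (x_max <= x_min)
    stop("degenerate range: x_max (", x_max, ") must exceed x_min (", x_min, ")",
         call. = FALSE)
  y <- if (polarity == "positive") {
    10 * (grid$values - x_min) / (x_max - x_min)
  } else {
    10 * (x_max - grid$values) / (x_max - x_min)
  }
  out <- grid_like(grid, pmin(pmax(y, 0), 10), mask = grid$mask)
  structure(list(grid = out, source_name = attr(grid, "name"),
                 polarity = polarity, x_min = x_min, x_max = x_max),
            class = "ev_std")
}

#' Score a categorical surface by table lookup
#'
#' Qualitative indicators (land-use class above all) are standardized by
#' hierarchical assignment: every category code receives a fixed score on
#' the 0-10 vulnerability scale.
#'
#' @param grid `ev_grid` of category codes.
#' @param table named numeric vector mapping code (as name) to score;
#'   defaults to [LANDUSE_SCORES] keyed by the codes `1..5` in the order
#'   forest, grassland, cultivated, construction, water.
#' @return an `ev_std` with `polarity = "categorical"`.
#' @export
assign_categories <- function(grid, table = NULL) {
  stopifnot(is_ev_grid(grid))
  if (is.null(table)) {
    table <- LANDUSE_SCORES
    names(table) <- as.character(seq_along(LANDUSE_SCORES))
  }
  codes <- unique(grid_values(grid))
  unknown <- setdiff(as.character(codes), names(table))
  if (length(unknown))
    stop("codes with no score in the assignment table: ",
         paste(sort(unknown), collapse = ", "), call. = FALSE)
  y <- matrix(table[as.character(grid$values)],
              nrow(grid$values), ncol(grid$values))
  out <- grid_like(grid, y, mask = grid$mask)
  structure(list(grid = out, source_name = attr(grid, "name"),
                 polarity = "categorical", x_min = NA_real_, x_max = NA_real_),
            class = "ev_std")
}

#' Monitoring stations for interpolation
#'
#' @param points data.frame with numeric columns `x`, `y`, `value` in map
#'   coordinates.
#' @return object of class `ev_stations`.
#' @export
station_set <- function(points) {
  points <- as.data.frame(points)
  if (!all(c("x", "y", "value") %in% names(points)))
    stop("stations need columns x, y, value", call. = FALSE)
  if (nrow(points) < 1L) stop("need at least one station", call. = FALSE)
  if (!all(is.finite(points$x)) || !all(is.finite(points$y)))
    stop("station coordinates must be finite", call. = FALSE)
  key <- paste(points$x, points$y)
  if (anyDuplicated(key)) {
    dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
    if (length(unique(points$value[dup])) > 1 &&
        any(tapply(points$value, key, function(v) length(unique(v))) > 1))
      stop("stations at identical coordinates with different values", call. = FALSE)
    points <- points[!duplicated(key), , drop = FALSE]
  }
  structure(list(points = points[, c("x", "y", "value")]), class = "ev_stations")
}

#' Read stations from CSV
#' @param path CSV file with header columns `x,y,value`.
#' @return an `ev_stations`.
#' @export
read_stations <- function(path) {
  station_set(utils::read.csv(path))
}

#' Inverse-distance-weighted interpolation of stations onto a grid
#'
#' Each cell center receives \eqn{\sum w_j v_j / \sum w_j} with
#' \eqn{w_j = d_j^{-p}} over its `k` nearest stations; a cell coinciding
#' with a station takes that station's value exactly. Ties in the
#' nearest-neighbour selection are broken by station input order.
#'
#' @param stations an `ev_stations`.
#' @param template `ev_grid` defining the output geometry and mask.
#' @param power distance-decay exponent \eqn{p > 0} (default 2).
#' @param k number of nearest stations used per cell, or `Inf` for all
#'   (default 12).
#' @return `ev_grid` of interpolated values on the template geometry.
#' @export
idw_interpolate <- function(stations, template, power = 2, k = 12) {
  stopifnot(inherits(stations, "ev_stations"), is_ev_grid(template))
  if (power <= 0) stop("power must be > 0", call. = FALSE)
  pts <- stations$points
  ns <- nrow(pts)
  k <- min(k, ns)
  ctr <- cell_centers(template)
  px <- as.vector(ctr$x); py <- as.vector(ctr$y)
  # squared distances: cells x stations
  d2 <- outer(px, pts$x, `-`)^2 + outer(py, pts$y, `-`)^2
  if (k < ns) {
    # keep the k nearest per cell (order() is stable, so input order breaks ties)
    keep <- t(apply(d2, 1L, function(d) {
      sel <- logical(ns); sel[order(d)[seq_len(k)]] <- TRUE; sel
    }))
    d2[!keep] <- NA
  }
  w <- d2^(-power / 2)
  hit <- d2 == 0
  est <- numeric(length(px))
  any_hit <- rowSums(hit, na.rm = TRUE) > 0
  if (any(any_hit)) {
    idx <- apply(hit[any_hit, , drop = FALSE], 1L, which.max)
    est[any_hit] <- pts$value[idx]
  }
  vmat <- matrix(pts$value, length(px), ns, byrow = TRUE)
  est[!any_hit] <- rowSums(w * vmat, na.rm = TRUE)[!any_hit] /
    rowSums(w, na.rm = TRUE)[!any_hit]
  grid_like(template, matrix(est, nrow(template$values), ncol(template$values)),
            mask = template$mask)
}
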