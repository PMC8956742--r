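#' Ecological vulnerability index from component scores
#'
#' The EVI of a cell is the contribution-rate-weighted sum of its first `k`
#' principal-component scores, \eqn{EVI = \sum_{i \le k} r_i Y_i}, with the
#' rates exactly as returned by [contribution_rates()] (not renormalized
#' over the selected components).
#'
#' @param pca an `ev_spca`.
#' @param k number of components to combine (e.g. from
#'   [select_components()]).
#' @return `ev_grid` of EVI values on the stack geometry.
#' @export
compute_evi <- function(pca, k) {
  stopifnot(inherits(pca, "ev_spca"))
  if (k < 1L || k > pca$n_indicators)
    stop("k must lie in 1..", pca$n_indicators, call. = FALSE)
  acc <- 0
  for (i in seq_len(k))
    acc <- acc + pca$contribution_rates[i] * pca$scores[[i]]$values
  grid_like(pca$scores[[1L]], acc, mask = pca$scores[[1L]]$mask)
}

#' Cross-epoch standardization of EVI surfaces
#'
#' Rescales every epoch's EVI to the common 0-10 scale
#' \eqn{SVI = 10 (EVI - EVI_{min}) / (EVI_{max} - EVI_{min})} with the
#' extremes pooled over all epochs and valid cells, so vulnerability levels
#' are comparable across years.
#'
#' @param evi_by_year named list of `ev_grid` EVI surfaces sharing one
#'   geometry.
#' @return named list of `ev_grid` SVI surfaces in \[0, 10\].
#' @export
standardize_svi <- function(evi_by_year) {
  if (!length(evi_by_year)) stop("need at least one epoch", call. = FALSE)
  ref <- evi_by_year[[1L]]
  for (g in evi_by_year)
    if (!same_geometry(ref, g)) stop("EVI surfaces must share one geometry", call. = FALSE)
  pooled <- unlist(lapply(evi_by_year, grid_values))
  lo <- min(pooled); hi <- max(pooled)
  if (hi <= lo) stop("degenerate range: pooled EVI is constant", call. = FALSE)
  lapply(evi_by_year, function(g)
    grid_like(g, pmin(pmax(10 * (g$values - lo) / (hi - lo), 0), 10),
              mask = g$mask))
}

#' Five-level vulnerability grading scheme
#'
#' Equal-interval grading of the 0-10 SVI scale into the levels micro (I),
#' mild (II), moderate (III), severe (IV) and extreme (V) vulnerability.
#' Intervals are lower-closed: I = \[0, 2), II = \[2, 4), III = \[4, 6),
#' IV = \[6, 8), V = \[8, 10\].
#'
#' @param breaks four strictly increasing interior boundaries
#'   (default `c(2, 4, 6, 8)`).
#' @param labels level names.
#' @return object of class `ev_scheme`.
#' @export
grading_scheme <- function(breaks = c(2, 4, 6, 8),
                           labels = c("micro", "mild", "moderate",
                                      "severe", "extreme")) {
  if (length(breaks) != 4L || is.unsorted(breaks, strictly = TRUE))
    stop("need 4 strictly increasing breaks", call. = FALSE)
  if (length(labels) != 5L) stop("need 5 labels", call. = FALSE)
  structure(list(breaks = as.numeric(breaks), labels = labels,
                 grades = 1:5), class = "ev_scheme")
}

#' Classify an SVI surface into the five vulnerability grades
#'
#' @param svi `ev_grid` with valid values in \[0, 10\].
#' @param scheme an [grading_scheme()].
#' @return object of class `ev_vulngrade`: `classes` (`ev_grid` of codes
#'   1-5), `area_by_class` (m^2 per grade, all five grades reported),
#'   `proportions` (shares of the valid area), `cevi` (the overall
#'   area-weighted mean grade), `scheme`.
#' @export
classify <- function(svi, scheme = grading_scheme()) {
  stopifnot(is_ev_grid(svi), inherits(scheme, "ev_scheme"))
  v <- grid_values(svi)
  if (!length(v)) stop("no valid cells", call. = FALSE)
  if (min(v) < 0 || max(v) > 10)
    stop("SVI values outside [0, 10]: range [", min(v), ", ", max(v), "]",
         call. = FALSE)
  cls <- matrix(NA_real_, nrow(svi$values), ncol(svi$values))
  cls[svi$mask] <- findInterval(grid_values(svi), scheme$breaks) + 1
  cg <- grid_like(svi, cls, mask = svi$mask)
  counts <- tabulate(cls[svi$mask], nbins = 5L)
  areas <- counts * svi$cell_size^2
  names(areas) <- as.character(1:5)
  props <- areas / sum(areas)
  cevi <- sum(scheme$grades * props)
  structure(list(classes = cg, area_by_class = areas, proportions = props,
                 cevi = cevi, scheme = scheme), class = "ev_vulngrade")
}

#' @export
print.ev_vulngrade <- function(x, ...) {
  cat("<ev_vulngrade>\n")
  print(data.frame(level = c("I", "II", "III", "IV", "V"),
                   label = x$scheme$labels,
                   area_m2 = unname(x$area_by_class),
                   share_pct = round(100 * unname(x$proportions), 2)))
  cat(sprintf("CEVI = %.2f\n", x$cevi))
  invisible(x)
}

#' Comprehensive ecological vulnerability index
#'
#' The CEVI of a region is the area-weighted mean grade
#' \eqn{CEVI = \sum_i L_i A_i / S} over the five vulnerability levels
#' (grade values \eqn{L_i = 1..5}), a scalar in \[1, 5\]. With a zone map it
#' is evaluated per zone over the zone's cells; empty zones are dropped
#' with a warning.
#'
#' @param grade an `ev_vulngrade` (or an `ev_grid` of class codes 1-5).
#' @param zones optional `ev_zones`.
#' @return a scalar, or a named numeric vector of per-zone CEVI values.
#' @export
compute_cevi <- function(grade, zones = NULL) {
  cg <- if (inherits(grade, "ev_vulngrade")) grade$classes else grade
  stopifnot(is_ev_grid(cg))
  if (is.null(zones)) {
    v <- grid_values(cg)
    if (!length(v)) stop("no valid cells", call. = FALSE)
    return(mean(v))  # equal cell areas: area weighting reduces to the cell mean
  }
  stopifnot(inherits(zones, "ev_zones"))
  if (!same_geometry(cg, zones$zones))
    stop("zone map and class grid must share one geometry", call. = FALSE)
  m <- cg$mask & zones$zones$mask
  z <- zones$zones$values[m]
  g <- cg$values[m]
  all_codes <- sort(as.numeric(names(zones$names)))
  out <- vapply(all_codes, function(code) {
    sel <- z == code
    if (!any(sel)) return(NA_real_)
    mean(g[sel])
  }, 0)
  names(out) <- zones$names[as.character(all_codes)]
  if (anyNA(out)) {
    warning("empty zone(s) omitted: ",
            paste(names(out)[is.na(out)], collapse = ", "), call. = FALSE)
    out <- out[!is.na(out)]
  }
  out
}

#' Multi-year mean CEVI
#'
#' Arithmetic mean of per-epoch CEVI values; exports round it to two
#' decimals (half-up).
#'
#' @param values_by_year numeric vector of per-epoch CEVI values.
#' @return the mean.
#' @export
mean_cevi <- function(values_by_year) {
  if (!length(values_by_year)) stop("no values", call. = FALSE)
  mean(values_by_year)
}

# round half-up at `digits`, the convention of the exported CEVI tables
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' CEVI table over zones and epochs
#'
#' Builds the standard zones-by-years CEVI summary: one row per epoch plus
#' a `Mean` row, one column per zone plus a `Total` column for the whole
#' region, rounded to two decimals (half-up).
#'
#' @param grades_by_year named list of `ev_vulngrade`, one per epoch.
#' @param zones optional `ev_zones`.
#' @return data.frame.
#' @export
cevi_table <- function(grades_by_year, zones = NULL) {
  rows <- lapply(grades_by_year, function(gr) {
    tot <- gr$cevi
    if (is.null(zones)) c(Total = tot)
    else c(compute_cevi(gr, zones), Total = tot)
  })
  tab <- do.call(rbind, rows)
  tab <- rbind(tab, Mean = colMeans(tab))
  out <- data.frame(year = rownames(tab), round_half_up(as.data.frame(tab), 2),
                    row.names = NULL, check.names = FALSE)
  out
}
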