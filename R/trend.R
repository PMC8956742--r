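#' Per-pixel least-squares trend of EVI across epochs
#'
#' Fits, at every cell valid in all epochs, an ordinary least-squares line
#' of EVI against the 1-based epoch index \eqn{i = 1..n} and returns its
#' slope
#' \deqn{K = \frac{n \sum i \, EVI_i - (\sum i)(\sum EVI_i)}
#'              {n \sum i^2 - (\sum i)^2}.}
#' Positive `K` means vulnerability is increasing over the study period,
#' negative means it is decreasing.
#'
#' @param evi_by_year ordered list of `ev_grid` EVI surfaces (epoch order),
#'   sharing one geometry.
#' @return object of class `ev_trend` with fields `slope` (`ev_grid`),
#'   `n_years`; `classes` and `breaks` are filled by [jenks_classify()].
#' @export
fit_trend <- function(evi_by_year) {
  n <- length(evi_by_year)
  if (n < 2L) stop("need at least two epochs", call. = FALSE)
  ref <- evi_by_year[[1L]]
  for (g in evi_by_year)
    if (!same_geometry(ref, g)) stop("EVI surfaces must share one geometry", call. = FALSE)
  m <- Reduce(`&`, lapply(evi_by_year, `[[`, "mask"))
  Y <- vapply(evi_by_year, function(g) g$values[m], numeric(sum(m)))
  K <- ols_slopes(Y)
  vals <- matrix(NA_real_, nrow(ref$values), ncol(ref$values))
  vals[m] <- K
  structure(list(slope = grid_like(ref, vals, mask = m), n_years = n,
                 classes = NULL, breaks = NULL), class = "ev_trend")
}

#' Jenks natural-breaks values for a numeric vector
#'
#' Optimal 1-D classification (Fisher's method): break positions minimize
#' the total within-class sum of squared deviations, computed by exact
#' dynamic programming over the sorted distinct values with their
#' multiplicities as weights. Among equal-cost partitions the one with the
#' smallest first break is returned. For more than `max_exact` distinct
#' values the breaks are fitted on a deterministic regular subsample of the
#' sorted values (every element at `max_exact` evenly spaced ranks), then
#' applied to all values.
#'
#' @param values numeric vector.
#' @param n_classes number of classes (default 5).
#' @param max_exact largest number of distinct values solved exactly
#'   (default 10000).
#' @return numeric vector of `n_classes - 1` upper boundaries (the largest
#'   value of each class but the last).
#' @export
jenks_breaks <- function(values, n_classes = 5, max_exact = 10000) {
  v <- values[is.finite(values)]
  tab <- table(v)
  ux <- as.numeric(names(tab))
  w <- as.numeric(tab)
  if (length(ux) < n_classes)
    stop("need at least ", n_classes, " distinct values, got ", length(ux),
         call. = FALSE)
  if (length(ux) > max_exact) {
    idx <- unique(round(seq(1L, length(ux), length.out = max_exact)))
    ux <- ux[idx]; w <- w[idx]
  }
  idx <- jenks_dp(ux, w, as.integer(n_classes))
  ux[idx]
}

#' Classify a grid by Jenks natural breaks
#'
#' @param values an `ev_grid` (typically the trend slope surface) or an
#'   `ev_trend`, in which case its slope surface is classified and the
#'   result attached.
#' @param n_classes number of classes (default 5; class codes are ordered
#'   by value, 1 = lowest).
#' @param max_exact see [jenks_breaks()].
#' @return for a grid: list with `classes` (`ev_grid` of codes) and
#'   `breaks`; for an `ev_trend`: the trend object with `classes` and
#'   `breaks` filled in.
#' @export
jenks_classify <- function(values, n_classes = 5, max_exact = 10000) {
  if (inherits(values, "ev_trend")) {
    r <- jenks_classify(values$slope, n_classes, max_exact)
    values$classes <- r$classes
    values$breaks <- r$breaks
    return(values)
  }
  stopifnot(is_ev_grid(values))
  br <- jenks_breaks(grid_values(values), n_classes, max_exact)
  cls <- matrix(NA_real_, nrow(values$values), ncol(values$values))
  # classes are (-Inf, b1], (b1, b2], ..., (b_{k-1}, Inf)
  cls[values$mask] <- findInterval(grid_values(values), br, left.open = TRUE) + 1
  list(classes = grid_like(values, cls, mask = values$mask), breaks = br)
}

#' Share of cells with increasing vulnerability
#'
#' @param trend an `ev_trend` (or slope `ev_grid`).
#' @param threshold slope above which a cell counts as increasing
#'   (default 0).
#' @return fraction of valid cells with slope > `threshold`.
#' @export
positive_trend_fraction <- function(trend, threshold = 0) {
  g <- if (inherits(trend, "ev_trend")) trend$slope else trend
  v <- grid_values(g)
  if (!length(v)) stop("no valid cells", call. = FALSE)
  mean(v > threshold)
}
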