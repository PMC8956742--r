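#' Delineate patches of a categorical landscape
#'
#' A patch is a maximal connected region of same-class valid cells under
#' the chosen neighbourhood rule. Patch ids are assigned in reading order
#' (first cell touched row by row), so labeling is deterministic.
#'
#' @param grid `ev_grid` of class codes.
#' @param connectivity 8 (queen, the default) or 4 (rook).
#' @return object of class `ev_patches`: `labels` (`ev_grid` of patch
#'   ids), `patch_table` (data.frame `id`, `class`, `cells`, `area_m2`),
#'   `connectivity`, and the source `grid`.
#' @export
label_patches <- function(grid, connectivity = 8) {
  stopifnot(is_ev_grid(grid), connectivity %in% c(4, 8))
  if (!n_valid(grid)) stop("grid has no valid cells", call. = FALSE)
  res <- label_patches_cpp(grid$values, grid$mask, as.integer(connectivity))
  lab <- res$labels
  storage.mode(lab) <- "double"
  structure(list(
    labels = grid_like(grid, lab, mask = grid$mask),
    patch_table = data.frame(id = seq_along(res$patch_class),
                             class = res$patch_class,
                             cells = res$patch_cells,
                             area_m2 = res$patch_cells * grid$cell_size^2),
    connectivity = connectivity,
    grid = grid), class = "ev_patches")
}

#' Landscape-level pattern metrics
#'
#' The five landscape-level metrics used throughout the pipeline, in their
#' FRAGSTATS definitions:
#' \describe{
#'   \item{NP}{number of patches.}
#'   \item{LPI}{largest patch index, \eqn{100 \max_i a_i / A} (percent of
#'     landscape).}
#'   \item{AI}{aggregation index,
#'     \eqn{100 \sum_c P_c \, g_{cc} / \max g_{cc}}, with \eqn{g_{cc}} the
#'     single-count like-adjacency count of class c and \eqn{\max g_{cc}}
#'     its maximum attainable value for the class's cell count
#'     (largest-integer-square construction); classes of a single cell
#'     contribute zero.}
#'   \item{DIVISION}{landscape division, \eqn{1 - \sum_i (a_i/A)^2} over
#'     patches.}
#'   \item{SHDI}{Shannon diversity, \eqn{-\sum_c p_c \ln p_c} over class
#'     area proportions (nats).}
#' }
#'
#' @param patches an `ev_patches` from [label_patches()] (or an `ev_grid`,
#'   labelled first with 8-connectivity).
#' @return named numeric vector `np`, `lpi`, `ai`, `division`, `shdi`.
#' @export
compute_metrics <- function(patches) {
  if (is_ev_grid(patches)) patches <- label_patches(patches)
  stopifnot(inherits(patches, "ev_patches"))
  g <- patches$grid
  metrics_cpp(g$values, g$mask, as.integer(patches$connectivity))
}

#' Moving-window landscape metric surfaces
#'
#' Slides an odd-sided square window over the landscape and evaluates the
#' five landscape metrics of [compute_metrics()] on the window contents at
#' every position; the output cell at the window center holds the value.
#' Positions where the window would leave the grid are masked, not padded
#' (padding would distort the adjacency counts). A `stride` larger than 1
#' evaluates only every `stride`-th center in each direction, masking the
#' rest.
#'
#' @param grid `ev_grid` of class codes.
#' @param window odd window side length in cells (>= 3).
#' @param stride center spacing in cells (default 1).
#' @param connectivity patch rule, 8 (default) or 4.
#' @return named list of five `ev_grid` metric surfaces.
#' @export
moving_window <- function(grid, window, stride = 1, connectivity = 8) {
  stopifnot(is_ev_grid(grid))
  if (window %% 2 == 0) stop("window must be odd", call. = FALSE)
  if (window < 3 || window > min(dim(grid$values)))
    stop("window must lie in [3, min(grid extent)]", call. = FALSE)
  res <- moving_window_cpp(grid$values, grid$mask, as.integer(window),
                           as.integer(stride), as.integer(connectivity))
  lapply(res, function(m) grid_like(grid, m, mask = grid$mask & !is.na(m)))
}

#' Window-mean surface of a numeric grid
#'
#' Mean of the valid cells inside the same windows as [moving_window()];
#' used to pair a window's landscape metrics with its mean vulnerability.
#'
#' @inheritParams moving_window
#' @param grid numeric `ev_grid`.
#' @return `ev_grid` of window means, masked off the stride lattice.
#' @export
window_mean <- function(grid, window, stride = 1) {
  stopifnot(is_ev_grid(grid))
  if (window %% 2 == 0) stop("window must be odd", call. = FALSE)
  m <- window_mean_cpp(grid$values, grid$mask, as.integer(window),
                       as.integer(stride))
  grid_like(grid, m, mask = grid$mask & !is.na(m))
}
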