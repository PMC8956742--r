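#' Regression design linking landscape pattern to vulnerability
#'
#' @param y numeric response vector (vulnerability, e.g. window-mean EVI).
#' @param X numeric matrix or data.frame of predictor samples (one column
#'   per landscape metric).
#' @param unit optional sample-unit identifiers (e.g. window centers).
#' @return object of class `ev_design`.
#' @export
regression_design <- function(y, X, unit = NULL) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("X", seq_len(ncol(X)))
  if (length(y) != nrow(X)) stop("y and X disagree on sample count", call. = FALSE)
  keep <- is.finite(y) & apply(X, 1L, function(r) all(is.finite(r)))
  y <- y[keep]; X <- X[keep, , drop = FALSE]
  if (!is.null(unit)) unit <- unit[keep]
  if (nrow(X) < ncol(X) + 2L)
    stop("need at least k + 2 samples for k predictors", call. = FALSE)
  structure(list(y = as.numeric(y), X = X, unit = unit), class = "ev_design")
}

#' Build a regression design from moving-window surfaces
#'
#' Samples the moving-window landscape-metric surfaces of a land-use map
#' and pairs each window with the mean EVI of the same window, producing
#' the design for [partial_contributions()] and [simple_regressions()].
#'
#' @param landuse `ev_grid` of land-use class codes.
#' @param evi `ev_grid` of EVI (or SVI) values on the same geometry.
#' @param window odd window side in cells.
#' @param stride spacing between sampled window centers (default: one
#'   window, i.e. non-overlapping samples).
#' @param connectivity patch rule for the metrics.
#' @return an `ev_design` with columns `np`, `lpi`, `division`, `ai`,
#'   `shdi`.
#' @export
window_design <- function(landuse, evi, window, stride = window,
                          connectivity = 8) {
  stopifnot(same_geometry(landuse, evi))
  mets <- moving_window(landuse, window, stride, connectivity)
  ybar <- window_mean(evi, window, stride)
  ok <- ybar$mask & Reduce(`&`, lapply(mets, `[[`, "mask"))
  idx <- which(ok)
  X <- vapply(mets[c("np", "lpi", "division", "ai", "shdi")],
              function(g) g$values[idx], numeric(length(idx)))
  if (is.null(dim(X))) X <- matrix(X, nrow = length(idx),
                                   dimnames = list(NULL, names(mets)))
  regression_design(ybar$values[idx], X, unit = idx)
}

#' Full-model least squares fit and regression sum of squares
#'
#' Ordinary least squares of the response on all predictors plus an
#' intercept; `U` is the regression (model) sum of squares
#' \eqn{\sum (\hat y - \bar y)^2}.
#'
#' @param design an `ev_design`.
#' @return list with `coefficients`, `U`, `fitted`, `r_squared`.
#' @export
fit_ols <- function(design) {
  stopifnot(inherits(design, "ev_design"))
  df <- data.frame(y = design$y, design$X, check.names = FALSE)
  qrX <- qr(cbind(1, design$X))
  if (qrX$rank < ncol(design$X) + 1L)
    stop("singular design: predictors are exactly collinear", call. = FALSE)
  fit <- stats::lm(y ~ ., data = df)
  U <- sum((stats::fitted(fit) - mean(design$y))^2)
  tss <- sum((design$y - mean(design$y))^2)
  list(coefficients = stats::coef(fit), U = U, fitted = stats::fitted(fit),
       r_squared = if (tss > 0) U / tss else 0)
}

#' Partial-regression contribution of each predictor
#'
#' For each predictor \eqn{X_i} the full model is refit without it
#' (keeping the intercept); the partial regression sum of squares is the
#' drop in the regression sum of squares, \eqn{P_i = U - U_i}, and the
#' contribution rate is its share
#' \eqn{S_i = 100 \, P_i / \sum_j P_j} (percent).
#'
#' @param design an `ev_design` with at least two predictors.
#' @return object of class `ev_contrib`: data.frame `table` with columns
#'   `predictor`, `U_reduced`, `P`, `S_pct`, plus `U` and the full-model
#'   `coefficients`.
#' @export
partial_contributions <- function(design) {
  stopifnot(inherits(design, "ev_design"))
  k <- ncol(design$X)
  if (k < 2L) stop("need at least two predictors", call. = FALSE)
  full <- fit_ols(design)
  Ui <- vapply(seq_len(k), function(i) {
    red <- design
    red$X <- design$X[, -i, drop = FALSE]
    out <- tryCatch(fit_ols(red), error = function(e)
      stop("reduced model without `", colnames(design$X)[i], "` is singular",
           call. = FALSE))
    out$U
  }, 0)
  P <- full$U - Ui
  P[P < 0 & P > -1e-10 * max(1, full$U)] <- 0  # clip tiny negative round-off
  S <- 100 * P / sum(P)
  structure(list(
    table = data.frame(predictor = colnames(design$X), U_reduced = Ui,
                       P = P, S_pct = S, row.names = NULL),
    U = full$U, coefficients = full$coefficients), class = "ev_contrib")
}

#' @export
print.ev_contrib <- function(x, ...) {
  cat(sprintf("<ev_contrib> full-model regression SS U = %.5f\n", x$U))
  tab <- x$table
  tab$P <- round(tab$P, 5); tab$S_pct <- round(tab$S_pct, 2)
  print(tab)
  invisible(x)
}

#' Univariate regressions of vulnerability on each landscape metric
#'
#' One ordinary least-squares line per predictor, with the Pearson
#' correlation — the scatter-plot companion of the multiple-regression
#' contribution analysis. Zero-variance predictors are skipped with a
#' warning.
#'
#' @param design an `ev_design` with at least 3 samples.
#' @return data.frame with columns `predictor`, `slope`, `intercept`, `r`.
#' @export
simple_regressions <- function(design) {
  stopifnot(inherits(design, "ev_design"))
  if (length(design$y) < 3L) stop("need at least 3 samples", call. = FALSE)
  rows <- lapply(colnames(design$X), function(nm) {
    x <- design$X[, nm]
    if (stats::sd(x) == 0) {
      warning("predictor `", nm, "` has zero variance; skipped", call. = FALSE)
      return(NULL)
    }
    b <- stats::cov(x, design$y) / stats::var(x)
    a <- mean(design$y) - b * mean(x)
    data.frame(predictor = nm, slope = b, intercept = a,
               r = stats::cor(x, design$y))
  })
  do.call(rbind, rows)
}
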