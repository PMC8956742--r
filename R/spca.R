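#' Spatial principal component analysis of a standardized indicator stack
#'
#' Treats every valid cell of the common mask as one observation and every
#' layer as one variable, decomposes the covariance matrix of that
#' observation-by-indicator table, and writes the component scores (the
#' mean-centered data projected on the eigenvectors) back onto the stack
#' geometry. The layers are expected on a common 0-10 scale already (see
#' [standardize()]), so the covariance — not correlation — matrix is
#' decomposed and no further rescaling is applied.
#'
#' Eigenvector sign is fixed so that each loading vector's
#' largest-magnitude entry is positive; eigenvalue ties are left in the
#' solver's stable order.
#'
#' @param stack an `ev_stack` whose layers are `ev_std` objects or plain
#'   `ev_grid`s on a common scale.
#' @return object of class `ev_spca`: `eigenvalues` (descending),
#'   `loadings` (indicator x component matrix), `contribution_rates`
#'   (\eqn{r_i = \lambda_i / \sum \lambda}), `cumulative_rates`, `scores`
#'   (list of per-component `ev_grid`s), `center` (per-indicator means),
#'   `n_indicators`.
#' @export
fit_spca <- function(stack) {
  stopifnot(inherits(stack, "ev_stack"))
  stack <- assert_aligned(stack)
  grids <- lapply(stack$layers, function(l) if (inherits(l, "ev_std")) l$grid else l)
  p <- length(grids)
  if (p < 2L) stop("need at least two layers", call. = FALSE)
  m <- stack$common_mask
  n <- sum(m)
  if (n < p)
    stop("fewer valid common cells (", n, ") than indicators (", p, ")",
         call. = FALSE)
  X <- vapply(grids, function(g) g$values[m], numeric(n))
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0))
    warning("constant layer(s): ", paste(colnames(X)[sds == 0], collapse = ", "),
            "; they carry zero variance", call. = FALSE)
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr)
  S <- stats::cov(X)
  eg <- eigen(S, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  V <- eg$vectors
  # deterministic sign: largest-|loading| entry of each component positive
  for (j in seq_len(p)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  dimnames(V) <- list(names(grids), paste0("PC", seq_len(p)))
  scores <- Xc %*% V
  ref <- grids[[1L]]
  score_grids <- lapply(seq_len(p), function(j) {
    vals <- matrix(NA_real_, nrow(ref$values), ncol(ref$values))
    vals[m] <- scores[, j]
    grid_like(ref, vals, mask = m)
  })
  names(score_grids) <- colnames(V)
  r <- contribution_rates(lam)
  structure(list(eigenvalues = lam, loadings = V, contribution_rates = r,
                 cumulative_rates = cumsum(r), scores = score_grids,
                 center = ctr, n_indicators = p), class = "ev_spca")
}

#' @export
print.ev_spca <- function(x, ...) {
  cat(sprintf("<ev_spca> %d indicators\n", x$n_indicators))
  print(data.frame(eigenvalue = round(x$eigenvalues, 4),
                   contribution_pct = round(100 * x$contribution_rates, 2),
                   cumulative_pct = round(100 * x$cumulative_rates, 2)))
  invisible(x)
}

#' Component contribution rates from eigenvalues
#'
#' \eqn{r_i = \lambda_i / \sum_j \lambda_j}; the rates sum to one.
#'
#' @param eigenvalues non-negative eigenvalues.
#' @return numeric vector of rates.
#' @export
contribution_rates <- function(eigenvalues) {
  if (!length(eigenvalues)) stop("no eigenvalues", call. = FALSE)
  if (any(eigenvalues < 0)) stop("eigenvalues must be non-negative", call. = FALSE)
  tot <- sum(eigenvalues)
  if (tot <= 0) stop("all eigenvalues are zero", call. = FALSE)
  eigenvalues / tot
}

#' Number of components needed to reach a cumulative-contribution threshold
#'
#' Returns the smallest `k` whose cumulative contribution rate reaches the
#' threshold (default 90\%) — the component-selection rule of the pipeline.
#' If the threshold is never reached, all components are kept with a
#' warning.
#'
#' @param cumulative_pct non-decreasing cumulative contribution rates in
#'   percent.
#' @param threshold_pct selection threshold in percent (default 90).
#' @return integer `k`.
#' @export
select_components <- function(cumulative_pct, threshold_pct = 90) {
  if (!length(cumulative_pct)) stop("empty cumulative rates", call. = FALSE)
  if (is.unsorted(cumulative_pct + 1e-12))
    stop("cumulative rates must be non-decreasing", call. = FALSE)
  k <- which(cumulative_pct >= threshold_pct)
  if (!length(k)) {
    warning("cumulative contribution never reaches ", threshold_pct,
            "%; keeping all ", length(cumulative_pct), " components",
            call. = FALSE)
    return(length(cumulative_pct))
  }
  k[1L]
}

#' Export the eigenvalue/contribution bookkeeping as a data.frame
#'
#' One row per component: eigenvalue, contribution rate and cumulative
#' contribution rate in percent — the layout of a standard SPCA summary
#' table.
#'
#' @param pca an `ev_spca`.
#' @return data.frame with columns `component`, `eigenvalue`,
#'   `contribution_pct`, `cumulative_pct`.
#' @export
spca_table <- function(pca) {
  stopifnot(inherits(pca, "ev_spca"))
  data.frame(component = names(pca$scores),
             eigenvalue = pca$eigenvalues,
             contribution_pct = 100 * pca$contribution_rates,
             cumulative_pct = 100 * pca$cumulative_rates,
             row.names = NULL)
}
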