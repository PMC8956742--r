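make_stack <- function(mats, cell_size = 30) {
  layers <- lapply(mats, ev_grid, cell_size = cell_size)
  names(layers) <- paste0("L", seq_along(layers))
  indicator_stack(2000, layers)
}

test_that("two proportional layers give a rank-1 decomposition", {
  set.seed(1)
  a <- matrix(rnorm(64), 8, 8)
  p <- fit_spca(make_stack(list(a, 3 * a)))
  expect_equal(unname(p$contribution_rates), c(1, 0), tolerance = 1e-12)
})

test_that("scores of distinct components are uncorrelated", {
  set.seed(2)
  p <- fit_spca(make_stack(lapply(1:4, function(i) matrix(rnorm(100), 10, 10))))
  S <- vapply(p$scores, grid_values, numeric(100))
  cv <- cov(S)
  expect_lt(max(abs(cv[upper.tri(cv)])), 1e-10)
})

test_that("3-layer eigenvalues match the characteristic-polynomial roots", {
  set.seed(3)
  mats <- lapply(1:3, function(i) matrix(rnorm(144), 12, 12))
  mats[[2]] <- mats[[2]] + 0.5 * mats[[1]]
  st <- make_stack(mats)
  p <- fit_spca(st)
  X <- vapply(st$layers, grid_values, numeric(144))
  C <- cov(X)
  # roots of det(C - lambda I) via the cubic's coefficients
  c0 <- -det(C)
  c1 <- det(C[1:2, 1:2]) + det(C[c(1, 3), c(1, 3)]) + det(C[2:3, 2:3])
  c2 <- -sum(diag(C))
  lam <- sort(Re(polyroot(c(c0, c1, c2, 1))), decreasing = TRUE)
  expect_equal(unname(p$eigenvalues), lam, tolerance = 1e-8)
})

test_that("loadings and scores agree with an SVD-based reference", {
  set.seed(4)
  mats <- lapply(1:5, function(i) matrix(rnorm(81), 9, 9))
  st <- make_stack(mats)
  p <- fit_spca(st)
  X <- vapply(st$layers, grid_values, numeric(81))
  ref <- prcomp(X, center = TRUE, scale. = FALSE)
  expect_equal(unname(p$eigenvalues), unname(ref$sdev^2), tolerance = 1e-10)
  for (j in 1:5) {
    v <- ref$rotation[, j]
    i <- which.max(abs(v))
    if (v[i] < 0) v <- -v  # same sign convention
    expect_equal(unname(p$loadings[, j]), unname(v), tolerance = 1e-8)
    s <- ref$x[, j] * sign(ref$rotation[i, j])
    expect_equal(grid_values(p$scores[[j]]), unname(s), tolerance = 1e-8)
  }
})

test_that("the eigenvalue sum conserves total variance", {
  set.seed(5)
  st <- make_stack(lapply(1:6, function(i) matrix(rnorm(64) * i, 8, 8)))
  p <- fit_spca(st)
  tot <- sum(vapply(st$layers, function(g) var(grid_values(g)), 0))
  expect_equal(sum(p$eigenvalues), tot, tolerance = 1e-8)
})

test_that("layer order does not change the decomposition", {
  set.seed(6)
  mats <- lapply(1:4, function(i) matrix(rnorm(49), 7, 7))
  st1 <- make_stack(mats)
  st2 <- make_stack(mats[c(3, 1, 4, 2)])
  p1 <- fit_spca(st1); p2 <- fit_spca(st2)
  expect_equal(p1$eigenvalues, p2$eigenvalues, tolerance = 1e-10)
  perm <- match(paste0("L", c(3, 1, 4, 2)), paste0("L", 1:4))
  expect_equal(unname(p1$loadings[perm, ]), unname(p2$loadings),
               tolerance = 1e-8)
})

test_that("retaining all components reconstructs the input", {
  set.seed(7)
  st <- make_stack(lapply(1:3, function(i) matrix(rnorm(36), 6, 6)))
  p <- fit_spca(st)
  X <- vapply(st$layers, grid_values, numeric(36))
  S <- vapply(p$scores, grid_values, numeric(36))
  rec <- S %*% t(p$loadings) + matrix(p$center, 36, 3, byrow = TRUE)
  expect_equal(unname(rec), unname(X), tolerance = 1e-6)
})

test_that("constant layers warn and degenerate stacks error", {
  a <- rand_grid(5, 5, seed = 8, origin = c(0, 0))
  flat <- ev_grid(matrix(2, 5, 5))
  expect_warning(fit_spca(indicator_stack(1, list(a = a, b = flat))),
                 "constant layer")
  tiny <- indicator_stack(1, list(
    a = ev_grid(matrix(c(1, 2, NA, NA), 2, 2)),
    b = ev_grid(matrix(c(2, 1, NA, NA), 2, 2)),
    c = ev_grid(matrix(c(5, 3, NA, NA), 2, 2))))
  expect_error(fit_spca(tiny), "fewer valid common cells")
})

test_that("contribution rates normalize the eigenvalues", {
  expect_equal(contribution_rates(c(2, 1, 1)), c(0.5, 0.25, 0.25))
  expect_equal(contribution_rates(5.3), 1)
  expect_error(contribution_rates(c(0, 0)), "zero")
  expect_error(contribution_rates(c(1, -0.1)), "non-negative")
})

test_that("published eigenvalues and contribution rates are mutually consistent", {
  # first-year table: eigenvalue ratio must match the printed rate ratio
  # up to the table's rounding
  expect_lt(abs(1.681 / 0.567 - 47.17 / 15.90), 0.01)
  r <- contribution_rates(c(1.681, 0.567, 0.429, 0.227, 0.207, 0.112))
  expect_equal(r[1] / r[2], 1.681 / 0.567, tolerance = 1e-12)
})

test_that("component selection implements the cumulative-threshold rule", {
  printed <- cumsum(c(47.17, 15.90, 12.04, 6.36, 5.80, 3.13))
  expect_equal(select_components(printed, 90), 6)
  expect_equal(select_components(cumsum(c(95, 5)), 90), 1)
  expect_equal(select_components(cumsum(rep(6.25, 16)), 90), 15)
  expect_warning(k <- select_components(c(20, 40), 90), "never reaches")
  expect_equal(k, 2)
  expect_error(select_components(numeric(0)), "empty")
})
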