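fake_pca <- function(score_mats, rates, cell_size = 30) {
  scores <- lapply(score_mats, ev_grid, cell_size = cell_size)
  names(scores) <- paste0("PC", seq_along(scores))
  structure(list(eigenvalues = rates, contribution_rates = rates,
                 cumulative_rates = cumsum(rates), scores = scores,
                 loadings = diag(length(scores)),
                 n_indicators = length(scores)), class = "ev_spca")
}

test_that("EVI is the contribution-weighted sum of component scores", {
  set.seed(1)
  mats <- lapply(1:4, function(i) matrix(rnorm(25), 5, 5))
  r <- c(0.5, 0.25, 0.15, 0.1)
  p <- fake_pca(mats, r)
  expect_equal(compute_evi(p, 1)$values, 0.5 * mats[[1]], tolerance = 1e-15)
  manual <- r[1] * mats[[1]] + r[2] * mats[[2]] + r[3] * mats[[3]]
  expect_equal(compute_evi(p, 3)$values, manual, tolerance = 1e-12)
  zero <- fake_pca(lapply(1:2, function(i) matrix(0, 3, 3)), c(0.7, 0.3))
  expect_equal(compute_evi(zero, 2)$values, matrix(0, 3, 3))
  expect_error(compute_evi(p, 5), "1..4")
  expect_error(compute_evi(p, 0), "1..4")
})

test_that("cross-year SVI attains 0 and 10 at the pooled extremes", {
  e1 <- ev_grid(matrix(c(1, 2, 3, 4), 2, 2))
  e2 <- ev_grid(matrix(c(5, 6, 7, 9), 2, 2))
  svi <- standardize_svi(list(`1996` = e1, `2007` = e2))
  expect_equal(svi$`1996`$values[1, 1], 0)   # pooled minimum
  expect_equal(svi$`2007`$values[2, 2], 10)  # pooled maximum
  expect_equal(min(unlist(lapply(svi, grid_values))), 0)
  expect_equal(max(unlist(lapply(svi, grid_values))), 10)
  # a single linear ramp is rescaled affinely
  ramp <- ev_grid(matrix(seq(0, 3, length.out = 16), 4, 4))
  s <- standardize_svi(list(a = ramp))$a
  expect_equal(s$values, ramp$values * 10 / 3, tolerance = 1e-12)
  expect_error(standardize_svi(list(a = ev_grid(matrix(2, 3, 3)))), "degenerate")
})

test_that("SVI preserves cross-epoch ordering of EVI", {
  set.seed(3)
  e1 <- rand_grid(6, 6, seed = 3)
  e2 <- grid_like(e1, e1$values + 5)  # disjoint ranges
  svi <- standardize_svi(list(a = e1, b = e2))
  ord_evi <- order(c(grid_values(e1), grid_values(e2)))
  ord_svi <- order(c(grid_values(svi$a), grid_values(svi$b)))
  expect_equal(ord_svi, ord_evi)
})

test_that("grading uses lower-closed equal intervals on the 0-10 scale", {
  svi <- ev_grid(matrix(c(1, 8, 4, 0, 2, 3.999, 6, 7.999, 10), 3, 3))
  vg <- classify(svi)
  expect_equal(vg$classes$values[1, 1], 1)  # 1.0 -> I
  expect_equal(vg$classes$values[2, 1], 5)  # 8.0 -> V (lower-closed)
  expect_equal(vg$classes$values[3, 1], 3)  # 4.0 -> III (lower-closed)
  expect_equal(vg$classes$values[1, 2], 1)  # 0 -> I
  expect_equal(vg$classes$values[3, 2], 2)  # 3.999 -> II
  expect_equal(vg$classes$values[3, 3], 5)  # 10 stays in the top class
  expect_error(classify(ev_grid(matrix(c(-1, 5, 5, 5), 2, 2))), "outside")
  expect_error(classify(ev_grid(matrix(c(11, 5, 5, 5), 2, 2))), "outside")
})

test_that("grade areas partition the landscape and proportions sum to one", {
  set.seed(4)
  svi <- ev_grid(matrix(runif(400, 0, 10), 20, 20), cell_size = 30)
  vg <- classify(svi)
  expect_equal(sum(vg$area_by_class), n_valid(svi) * 900)
  expect_equal(sum(vg$proportions), 1, tolerance = 1e-12)
})

test_that("CEVI is the area-weighted mean grade", {
  all3 <- ev_grid(matrix(5, 6, 6))  # svi 5 -> class III everywhere
  expect_equal(classify(all3)$cevi, 3)
  half <- ev_grid(matrix(rep(c(1, 9), each = 18), 6, 6))  # half I, half V
  expect_equal(classify(half)$cevi, 3)
  set.seed(5)
  svi <- ev_grid(matrix(runif(144, 0, 10), 12, 12))
  vg <- classify(svi)
  expect_equal(vg$cevi, mean(grid_values(vg$classes)))
  expect_equal(compute_cevi(vg), vg$cevi)
  expect_true(vg$cevi >= 1 && vg$cevi <= 5)
})

test_that("CEVI is monotone in any cell's grade", {
  set.seed(6)
  svi <- ev_grid(matrix(runif(64, 0, 9.4), 8, 8))
  vg <- classify(svi)
  bumped <- svi
  bumped$values[3, 3] <- bumped$values[3, 3] + 0.6  # can only raise the class
  expect_gte(classify(bumped)$cevi, vg$cevi)
})

test_that("zonal CEVI averages within zones and warns on empty ones", {
  cls <- ev_grid(matrix(c(1, 1, 5, 5), 2, 2))
  zg <- ev_grid(matrix(c(1, 1, 2, 2), 2, 2))
  zones <- zone_map(zg, c(`1` = "west", `2` = "east", `3` = "ghost"))
  expect_warning(z <- compute_cevi(cls, zones), "ghost")
  expect_equal(z, c(west = 1, east = 5))
})

test_that("grading is invariant under positive affine transforms of EVI", {
  set.seed(7)
  e1 <- rand_grid(7, 7, seed = 7)
  e2 <- rand_grid(7, 7, seed = 8)
  base <- lapply(standardize_svi(list(a = e1, b = e2)), classify)
  tr <- lapply(list(a = e1, b = e2),
               function(g) ev_grid(3.7 * g$values + 11, cell_size = 30))
  trans <- lapply(standardize_svi(tr), classify)
  expect_equal(base$a$classes$values, trans$a$classes$values)
  expect_equal(base$b$classes$values, trans$b$classes$values)
})

test_that("multi-year means reproduce the published town table", {
  expect_equal(round(mean_cevi(c(4.41, 4.17, 3.83)), 2), 4.14)  # Yangri
  expect_equal(round(mean_cevi(c(2.77, 2.71, 2.51)), 2), 2.66)  # whole region
  expect_equal(mean_cevi(c(2.4, 2.4, 2.4)), 2.4)
  expect_error(mean_cevi(numeric(0)), "no values")
})
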