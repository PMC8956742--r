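test_that("ASCII and GeoTIFF round-trips preserve values, mask and geometry", {
  g <- rand_grid(5, 5, seed = 3, origin = c(1234.5, 98765), na_frac = 0.12)
  g$crs_tag <- "EPSG:32649"
  for (fmt in c("ascii", "geotiff")) {
    p <- tempfile(fileext = if (fmt == "ascii") ".asc" else ".tif")
    write_grid(g, p, format = fmt)
    g2 <- read_grid(p, format = fmt)
    expect_identical(g2$mask, g$mask)
    expect_equal(g2$values, g$values, tolerance = 1e-12)
    expect_equal(g2$cell_size, g$cell_size)
    expect_equal(g2$origin, g$origin)
    unlink(p)
  }
})

test_that("integer grids round-trip bit-exactly", {
  g <- rand_cat_grid(6, 7, codes = c(1, 2, 5, 9), seed = 2)
  p <- tempfile(fileext = ".tif")
  write_grid(g, p)
  expect_identical(read_grid(p)$values, g$values)
  unlink(p)
})

test_that("the two dialects encode the same grid identically", {
  g <- rand_grid(7, 4, seed = 9, na_frac = 0.2)
  pa <- tempfile(fileext = ".asc"); pt <- tempfile(fileext = ".tif")
  write_grid(g, pa); write_grid(g, pt)
  ga <- read_grid(pa); gt <- read_grid(pt)
  expect_equal(ga$values, gt$values, tolerance = 1e-12)
  expect_identical(ga$mask, gt$mask)
  expect_equal(ga$origin, gt$origin)
  unlink(c(pa, pt))
})

test_that("an all-nodata file reads as empty and downstream ops refuse it", {
  g <- ev_grid(matrix(NA_real_, 4, 4))
  p <- tempfile(fileext = ".asc")
  write_grid(g, p)
  g2 <- read_grid(p)
  expect_equal(n_valid(g2), 0)
  expect_error(standardize(g2, "positive"), "no valid cells")
  expect_error(class_areas(g2), "no valid cells")
  unlink(p)
})

test_that("missing nodata declaration warns and keeps all cells valid", {
  p <- tempfile(fileext = ".asc")
  writeLines(c("ncols 2", "nrows 2", "xllcorner 0", "yllcorner 0",
               "cellsize 30", "1 2", "3 4"), p)
  expect_warning(g <- read_grid(p), "NODATA")
  expect_equal(n_valid(g), 4)
  unlink(p)
})

test_that("alignment validation accepts matching layers and names offenders", {
  a <- rand_grid(6, 6, seed = 1)
  b <- rand_grid(6, 6, seed = 2)
  st <- indicator_stack(2000, list(a = a, b = b))
  expect_s3_class(st, "ev_stack")

  shifted <- ev_grid(b$values, cell_size = 30, origin = c(15, 1000))
  expect_error(indicator_stack(2000, list(a = a, b = shifted)),
               "alignment error: layer `b` origin")
  small <- ev_grid(b$values[1:5, ], cell_size = 30, origin = c(0, 1000))
  expect_error(indicator_stack(2000, list(a = a, b = small)),
               "alignment error: layer `b` has shape")
})

test_that("the common mask is the cellwise intersection of layer masks", {
  a <- rand_grid(10, 10, seed = 4, na_frac = 0.3)
  b <- rand_grid(10, 10, seed = 5, na_frac = 0.3)
  st <- indicator_stack(2000, list(a = a, b = b))
  expect_identical(st$common_mask, a$mask & b$mask)
})

test_that("class areas follow direct cell counting", {
  u <- ev_grid(matrix(7, 10, 10), cell_size = 30)
  expect_equal(class_areas(u), c(`7` = 90000))

  half <- ev_grid(matrix(rep(c(1, 2), each = 50), 10, 10), cell_size = 30)
  a <- class_areas(half)
  expect_equal(unname(a["1"]), unname(a["2"]))

  g <- rand_cat_grid(15, 13, codes = 1:5, seed = 8, cell_size = 10)
  a <- class_areas(g)
  counts <- table(grid_values(g))
  expect_equal(unname(a[names(counts)]), as.numeric(counts) * 100)
  expect_equal(sum(a), n_valid(g) * 100)
})

test_that("class areas are invariant under cell permutation and conserve total area", {
  g <- rand_cat_grid(9, 9, codes = 1:3, seed = 11)
  set.seed(1)
  perm <- ev_grid(matrix(sample(as.vector(g$values)), 9, 9), cell_size = 30)
  expect_equal(class_areas(g), class_areas(perm))
})

test_that("GeoJSON zones rasterize by the cell-center rule", {
  tpl <- ev_grid(matrix(0, 10, 10), cell_size = 10, origin = c(0, 100))
  gj <- list(type = "FeatureCollection", features = list(
    list(type = "Feature", properties = list(code = 1, name = "west"),
         geometry = list(type = "Polygon", coordinates = list(list(
           c(0, 0), c(50, 0), c(50, 100), c(0, 100), c(0, 0))))),
    list(type = "Feature", properties = list(code = 2, name = "east"),
         geometry = list(type = "Polygon", coordinates = list(list(
           c(50, 0), c(100, 0), c(100, 100), c(50, 100), c(50, 0)))))))
  p <- tempfile(fileext = ".geojson")
  jsonlite::write_json(gj, p, auto_unbox = TRUE, digits = NA)
  z <- read_zones(p, tpl)
  expect_setequal(unique(grid_values(z$zones)), c(1, 2))
  expect_true(all(z$zones$values[, 1:5] == 1))
  expect_true(all(z$zones$values[, 6:10] == 2))
  expect_equal(unname(z$names[c("1", "2")]), c("west", "east"))
  unlink(p)
})
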