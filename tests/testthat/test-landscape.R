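test_that("a uniform landscape is one maximally aggregated patch", {
  g <- ev_grid(matrix(3, 9, 9), cell_size = 30)
  p <- label_patches(g)
  expect_equal(nrow(p$patch_table), 1)
  m <- compute_metrics(p)
  expect_equal(unname(m), c(1, 100, 100, 0, 0),
               tolerance = 1e-12)
})

test_that("diagonal contact merges under queen but not rook connectivity", {
  g <- ev_grid(matrix(c(1, 2, 2, 1), 2, 2))
  expect_equal(nrow(label_patches(g, 8)$patch_table), 2)
  expect_equal(nrow(label_patches(g, 4)$patch_table), 4)
})

test_that("labeling matches independent flood-fill and EBImage references", {
  set.seed(1)
  for (conn in c(4, 8)) {
    g <- rand_cat_grid(15, 15, codes = 1:3, seed = conn)
    got <- label_patches(g, conn)$labels$values
    ref <- flood_fill_labels(g$values, g$mask, conn)
    expect_true(same_partition(got, ref))
  }
  skip_if_not_installed("EBImage")
  g <- rand_cat_grid(20, 20, codes = 1:2, seed = 5)
  got <- label_patches(g, 4)$labels$values
  # EBImage::bwlabel is 4-connected; label each class separately
  ref <- matrix(0, 20, 20)
  for (cl in 1:2) {
    lab <- EBImage::bwlabel(g$values == cl)
    ref[lab > 0] <- lab[lab > 0] + max(ref)
  }
  expect_true(same_partition(got, ref))
})

test_that("metrics follow their closed forms on designed landscapes", {
  # two classes of equal area
  g <- ev_grid(matrix(rep(c(1, 2), each = 32), 8, 8))
  m <- compute_metrics(label_patches(g))
  expect_equal(unname(m["shdi"]), log(2), tolerance = 1e-12)
  expect_equal(unname(m["np"]), 2)
  expect_equal(unname(m["lpi"]), 50)
  expect_equal(unname(m["division"]), 0.5)

  # n single-cell patches of n distinct classes (checkerboard of 4 on 2x2)
  g4 <- ev_grid(matrix(1:4, 2, 2))
  m4 <- compute_metrics(label_patches(g4, 4))
  expect_equal(unname(m4["np"]), 4)
  expect_equal(unname(m4["division"]), 1 - 1 / 4, tolerance = 1e-12)
  expect_equal(unname(m4["ai"]), 0)
  expect_equal(unname(m4["shdi"]), log(4), tolerance = 1e-12)
})

test_that("moving windows reproduce cropped-grid metrics", {
  set.seed(2)
  g <- rand_cat_grid(15, 15, codes = 1:3, seed = 7)
  mw <- moving_window(g, window = 5, stride = 1)
  for (center in list(c(3, 3), c(8, 11), c(13, 7))) {
    r <- center[1]; c <- center[2]
    crop <- ev_grid(g$values[(r - 2):(r + 2), (c - 2):(c + 2)],
                    cell_size = g$cell_size)
    ref <- compute_metrics(label_patches(crop, 8))
    for (nm in names(mw))
      expect_equal(mw[[nm]]$values[r, c], unname(ref[nm]), tolerance = 1e-12)
  }
  # full-extent window equals the global metrics
  g2 <- rand_cat_grid(9, 9, codes = 1:2, seed = 8)
  mw2 <- moving_window(g2, window = 9)
  glob <- compute_metrics(label_patches(g2))
  for (nm in names(mw2))
    expect_equal(mw2[[nm]]$values[5, 5], unname(glob[nm]), tolerance = 1e-12)
  # uniform landscape gives constant surfaces
  u <- ev_grid(matrix(1, 9, 9))
  mwu <- moving_window(u, window = 3)
  expect_true(all(grid_values(mwu$np) == 1))
  expect_true(all(grid_values(mwu$ai) == 100))
  expect_error(moving_window(g, window = 4), "odd")
})

test_that("window edges are masked, not padded", {
  g <- rand_cat_grid(9, 9, codes = 1:2, seed = 9)
  mw <- moving_window(g, window = 5)
  expect_false(any(mw$np$mask[1:2, ]))
  expect_false(any(mw$np$mask[, 8:9]))
  expect_true(all(mw$np$mask[3:7, 3:7]))
})

test_that("queen patches are never more numerous than rook patches", {
  for (seed in 1:4) {
    g <- rand_cat_grid(12, 12, codes = 1:3, seed = seed)
    expect_lte(nrow(label_patches(g, 8)$patch_table),
               nrow(label_patches(g, 4)$patch_table))
  }
})

test_that("AI and SHDI are invariant under class relabeling; DIVISION is bounded", {
  set.seed(3)
  g <- rand_cat_grid(12, 12, codes = 1:4, seed = 10)
  relab <- ev_grid(matrix(c(9, 2, 7, 4)[g$values], 12, 12), cell_size = 30)
  m1 <- compute_metrics(label_patches(g))
  m2 <- compute_metrics(label_patches(relab))
  expect_equal(m1["ai"], m2["ai"], tolerance = 1e-12)
  expect_equal(m1["shdi"], m2["shdi"], tolerance = 1e-12)
  expect_lte(unname(m1["division"]), 1 - 1 / unname(m1["np"]))
})

test_that("patch table areas use the cell size and cover the landscape", {
  g <- rand_cat_grid(10, 10, codes = 1:2, seed = 11, cell_size = 20)
  p <- label_patches(g)
  expect_equal(sum(p$patch_table$area_m2), 100 * 400)
  expect_equal(sum(p$patch_table$cells), 100)
  # every valid cell belongs to exactly one patch
  expect_false(anyNA(p$labels$values[g$mask]))
})
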