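# Look-up-table construction, persistence and exhaustive matching.

test_that("the production grid exceeds the 300,000-profile scale", {
  g <- default_grid()
  expect_identical(length(axis_values(g, "diameter_um")), 85L)
  expect_identical(length(axis_values(g, "nc_ratio")), 81L)
  expect_identical(length(axis_values(g, "ri_cytosol")), 8L)
  expect_identical(length(axis_values(g, "ri_nucleus")), 10L)
  expect_identical(grid_cardinality(g), 85L * 81L * 8L * 10L)
  expect_gte(grid_cardinality(g), 300000L)
})

test_that("LUT profiles are the forward-model profiles, unit-normalized", {
  g1 <- grid_spec(c(10, 10, 1), c(0.9, 0.9, 1), c(1.36, 1.36, 1),
                  c(1.40, 1.40, 1))
  lut1 <- build_lut(g1)
  expect_identical(nrow(lut1$profiles), 1L)
  direct <- compute_lsp(cell_model(10, 0.9, 1.36, 1.40))
  expect_equal(lut1$profiles[1, ], direct$intensities, tolerance = 1e-12)
  expect_equal(max(lut1$profiles[1, ]), 1)
})

test_that("building the same grid twice is deterministic", {
  g <- grid_spec(c(9, 10, 0.5), c(0.9, 0.9, 1), c(1.36, 1.36, 1),
                 c(1.40, 1.41, 0.01))
  expect_identical(build_lut(g)$profiles, build_lut(g)$profiles)
})

test_that("a LUT survives a save/load round trip bit-for-bit", {
  lut <- tiny_lut()
  path <- withr::local_tempfile(fileext = ".rds")
  write_lut(lut, path)
  back <- read_lut(path)
  expect_identical(back$profiles, lut$profiles)
  expect_identical(back$params, lut$params)
  expect_identical(unclass(back$grid), unclass(lut$grid))
})

test_that("matching equals an independent exhaustive scan", {
  lut <- tiny_lut()
  set.seed(21)
  for (i in 1:20) {
    cell <- cell_model(runif(1, 9, 11), runif(1, 0.86, 0.92),
                       runif(1, 1.35, 1.37), runif(1, 1.39, 1.41))
    x <- compute_lsp(cell)
    expect_identical(match_lsp(x, lut)$index, brute_force_match(x, lut)$index)
  }
})

test_that("a profile copied from the table matches itself at distance 0", {
  lut <- tiny_lut()
  i <- 137L
  x <- lsp(setup_angles(lut$setup), lut$profiles[i, ], normalized = TRUE)
  m <- match_lsp(x, lut)
  expect_identical(m$index, i)
  expect_lt(abs(m$distance), 1e-12)
})

test_that("an off-grid profile matches a neighbouring grid point", {
  lut <- tiny_lut()
  truth <- cell_model(10.1, 0.87, 1.362, 1.396)
  m <- match_lsp(compute_lsp(truth), lut)
  expect_lte(abs(m$cell$diameter_um - truth$diameter_um), 0.25)
  expect_lte(abs(m$cell$nc_ratio - truth$nc_ratio), 0.02)
  expect_lte(abs(m$cell$ri_cytosol - truth$ri_cytosol), 0.01)
  expect_lte(abs(m$cell$ri_nucleus - truth$ri_nucleus), 0.01)
})

test_that("matching is invariant under positive rescaling of the profile", {
  lut <- tiny_lut()
  x <- compute_lsp(cell_model(10.6, 0.91, 1.36, 1.40))
  scaled <- lsp(x$angles_deg, 739.2 * x$intensities)
  expect_identical(match_lsp(scaled, lut)$index, match_lsp(x, lut)$index)
  expect_equal(match_lsp(scaled, lut)$distance, match_lsp(x, lut)$distance,
               tolerance = 1e-12)
})

test_that("exact distance ties break to the smallest diameter then N/C", {
  # entries with equal core and shell index produce identical profiles for
  # every N/C value, a controlled source of exact ties
  g <- grid_spec(c(9, 9.5, 0.5), c(0.8, 0.9, 0.05), c(1.38, 1.38, 1),
                 c(1.38, 1.38, 1))
  lut <- build_lut(g)
  x <- compute_lsp(cell_model(9, ri_cytosol = 1.38))
  m <- match_lsp(x, lut)
  expect_equal(m$cell$diameter_um, 9)
  expect_equal(m$cell$nc_ratio, 0.8)
})

test_that("degenerate queries are refused", {
  lut <- tiny_lut()
  bad <- lsp(setup_angles(lut$setup), rep(1, 281))
  bad$intensities[5] <- NaN
  expect_error(match_lsp(bad, lut), "non-finite")
  short <- lsp(seq(2, 30, 1), rep(1, 29))
  expect_error(match_lsp(short, lut), "grid")
})
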