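# Two-stage inversion: coarse match plus bounded local refinement.

test_that("refinement never increases the match distance", {
  lut <- tiny_lut()
  set.seed(31)
  for (i in 1:5) {
    truth <- cell_model(runif(1, 9.2, 10.8), runif(1, 0.87, 0.91),
                        runif(1, 1.352, 1.368), runif(1, 1.392, 1.408))
    x <- compute_lsp(truth)
    r <- invert_lsp(x, lut)
    expect_lte(r$distance, r$coarse_distance + 1e-14)
  }
})

test_that("an already exact seed is returned unchanged", {
  truth <- cell_model(10, 0.9, 1.36, 1.40)
  x <- compute_lsp(truth)
  fit <- refine(x, truth)
  expect_equal(fit$cell$diameter_um, 10, tolerance = 1e-6)
  expect_equal(fit$cell$nc_ratio, 0.9, tolerance = 1e-6)
  expect_equal(fit$reported$diameter_um, 10)
  expect_equal(fit$reported$nc_ratio, 0.9)
  expect_lte(fit$distance, fit$seed_distance + 1e-14)
})

test_that("refined parameters stay within one grid step of the seed", {
  lut <- tiny_lut()
  truth <- cell_model(10.1, 0.87, 1.362, 1.396)
  x <- compute_lsp(truth)
  m <- match_lsp(x, lut)
  fit <- refine(x, m$cell, box_steps = c(diameter_um = 0.25,
                                         nc_ratio = 0.02,
                                         ri_cytosol = 0.01,
                                         ri_nucleus = 0.01))
  expect_lte(abs(fit$cell$diameter_um - m$cell$diameter_um), 0.25 + 1e-9)
  expect_lte(abs(fit$cell$nc_ratio - m$cell$nc_ratio), 0.02 + 1e-9)
  expect_lte(abs(fit$cell$ri_cytosol - m$cell$ri_cytosol), 0.01 + 1e-9)
  expect_lte(abs(fit$cell$ri_nucleus - m$cell$ri_nucleus), 0.01 + 1e-9)
})

test_that("noiseless profiles are recovered at the reporting precision", {
  lut <- tiny_lut()
  set.seed(8)
  for (i in 1:8) {
    truth <- cell_model(runif(1, 9.2, 10.8), runif(1, 0.87, 0.91),
                        runif(1, 1.352, 1.368), runif(1, 1.392, 1.408))
    r <- invert_lsp(compute_lsp(truth), lut)
    expect_lte(abs(r$reported$diameter_um - truth$diameter_um), 0.01)
    expect_lte(abs(r$reported$nc_ratio - truth$nc_ratio), 0.005)
    expect_lte(abs(r$reported$ri_cytosol - truth$ri_cytosol), 0.01)
    expect_lte(abs(r$reported$ri_nucleus - truth$ri_nucleus), 0.01)
  }
})

test_that("one percent multiplicative noise still recovers the grid entry", {
  lut <- tiny_lut()
  i <- 212L
  set.seed(55)
  noisy <- lut$profiles[i, ] * pmax(1 + 0.01 * rnorm(281), 0.01)
  m <- match_lsp(lsp(setup_angles(lut$setup), noisy), lut)
  expect_identical(m$index, i)
})

test_that("a homogeneous scatterer is reported as homogeneous", {
  # N/C has no meaning without a core/shell contrast; the inversion must
  # collapse such fits to N/C = 1 with a single index
  g <- grid_spec(c(7, 8.5, 0.25), c(0.9, 1.0, 0.02), c(1.38, 1.42, 0.01),
                 c(1.38, 1.42, 0.01))
  lut <- build_lut(g)
  truth <- cell_model(7.64, ri_cytosol = 1.40)
  r <- invert_lsp(compute_lsp(truth), lut)
  expect_true(r$homogeneous)
  expect_equal(r$reported$nc_ratio, 1)
  expect_equal(r$reported$ri_cytosol, r$reported$ri_nucleus)
  expect_lte(abs(r$reported$diameter_um - 7.64), 0.01)
  expect_lte(abs(r$reported$ri_nucleus - 1.40), 0.01)
})

test_that("inversion is deterministic", {
  lut <- tiny_lut()
  x <- compute_lsp(cell_model(10.37, 0.885, 1.363, 1.402))
  r1 <- invert_lsp(x, lut)
  r2 <- invert_lsp(x, lut)
  expect_identical(r1$reported, r2$reported)
  expect_identical(r1$distance, r2$distance)
})

test_that("inverting a profile set yields one feature row per profile", {
  lut <- tiny_lut()
  cells <- list(a = compute_lsp(cell_model(9.8, 0.9, 1.36, 1.40)),
                b = compute_lsp(cell_model(10.4, 0.88, 1.36, 1.40)))
  fx <- invert_population(cells, lut)
  expect_identical(nrow(fx), 2L)
  expect_identical(fx$cell_id, c("a", "b"))
  expect_true(all(fx$distance < 1e-8))
})
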