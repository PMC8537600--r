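# Synthetic population generator: distributional fidelity and determinism.

test_that("draws are seeded, reproducible and seed-sensitive", {
  a <- sample_population(c(T = 50, CTC = 50), seed = 10)
  b <- sample_population(c(T = 50, CTC = 50), seed = 10)
  c <- sample_population(c(T = 50, CTC = 50), seed = 11)
  expect_identical(a, b)
  expect_false(identical(a$diameter_um, c$diameter_um))
})

test_that("large samples converge to the class parameters", {
  params <- class_parameters()
  pop <- sample_population(c(RBC = 10000, T = 10000, B = 10000, M = 10000,
                             CTC = 10000), seed = 123)
  for (cl in params$class) {
    p <- params[params$class == cl, ]
    d <- pop$diameter_um[pop$label == cl]
    se <- p$d_sd_um / sqrt(length(d))
    expect_lte(abs(mean(d) - p$d_mean_um), 3 * se)
    expect_lte(abs(sd(d) - p$d_sd_um) / p$d_sd_um, 0.05)
    nc <- pop$nc_ratio[pop$label == cl]
    expect_true(all(nc > 0 & nc <= 1))
    ric <- pop$ri_cytosol[pop$label == cl]
    expect_lte(abs(mean(ric) - p$ri_cytosol), 3 * 0.005 / sqrt(length(ric)) + 1e-4)
  }
  # anucleate class has no nucleus index
  expect_true(all(is.na(pop$ri_nucleus[pop$label == "RBC"])))
  expect_true(all(!is.na(pop$ri_nucleus[pop$label != "RBC"])))
})

test_that("empty requests and missing classes are handled", {
  expect_identical(nrow(sample_population(c(T = 0), seed = 1)), 0L)
  expect_error(sample_population(c(Macro = 5), seed = 1), "Macro")
  extra <- data.frame(class = "Macro", d_mean_um = 12, d_sd_um = 1,
                      ri_cytosol = 1.36, ri_nucleus = 1.39,
                      nc_ratio = 0.7)
  pop <- sample_population(c(Macro = 5),
                           params = class_parameters(extra = extra),
                           seed = 1)
  expect_identical(nrow(pop), 5L)
})

test_that("scenario fractions are normalized and match their sources", {
  f <- scenario_fractions("adenocarcinoma-like")
  expect_equal(sum(f), 1)
  expect_equal(100 * f[["M"]], 0.12, tolerance = 0.005)
  f0 <- scenario_fractions("training-sample-t0")
  expect_equal(sum(f0), 1)
  expect_equal(100 * f0[["B"]], 47.14, tolerance = 0.01)
  pop <- sample_scenario("training-sample-t0", 200, seed = 6)
  expect_identical(nrow(pop), 200L)
  expect_true(all(pop$label %in% c("T", "B", "M", "CTC")))
})

test_that("profile synthesis is one profile per record and seeded", {
  pop <- sample_population(c(T = 3, CTC = 2), seed = 2)
  lsps <- population_to_lsps(pop)
  expect_length(lsps, 5L)
  expect_true(all(vapply(lsps, function(x) length(x$angles_deg) == 281L,
                         logical(1))))
  # noiseless synthesis is deterministic; noisy synthesis is seeded
  expect_identical(population_to_lsps(pop), population_to_lsps(pop))
  n1 <- population_to_lsps(pop, noise_level = 0.05, seed = 3)
  n2 <- population_to_lsps(pop, noise_level = 0.05, seed = 3)
  expect_identical(n1, n2)
  expect_false(identical(n1[[1]]$intensities,
                         population_to_lsps(pop)[[1]]$intensities))
})

test_that("the culture time-course table is available as percentages", {
  tab <- table2_percentages()
  expect_identical(nrow(tab), 3L)
  expect_equal(rowSums(tab[, -1]), rep(100, 3), tolerance = 0.02)
  expect_equal(tab$CTC, c(25.71, 88.02, 100.00))
})
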