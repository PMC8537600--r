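# Forward model: coated-sphere (Aden-Kerker) series and its limits.

test_that("amplitudes match the independent reference implementation", {
  ref <- read.csv(test_path("mie-reference.csv"))
  key <- paste(ref$x_core, ref$x_shell, ref$m_core, ref$m_shell)
  for (k in unique(key)) {
    sub <- ref[key == k, ]
    res <- lspcyto:::mie_coated_cpp(sub$x_core[1], sub$x_shell[1],
                                    sub$m_core[1], sub$m_shell[1],
                                    cos(sub$angle_deg * pi / 180))
    s1 <- complex(real = sub$re_s1, imaginary = sub$im_s1)
    s2 <- complex(real = sub$re_s2, imaginary = sub$im_s2)
    expect_lt(max(Mod(res$S1 - s1) / Mod(s1)), 1e-6)
    expect_lt(max(Mod(res$S2 - s2) / Mod(s2)), 1e-6)
  }
})

test_that("degenerate coated spheres reduce to the homogeneous series", {
  setup <- optical_setup()
  # equal core and shell indices
  coated <- compute_lsp(cell_model(10, 0.9, 1.36, 1.36), setup,
                        normalize = FALSE)
  homog <- compute_lsp(cell_model(10, ri_cytosol = 1.36), setup,
                       normalize = FALSE)
  expect_lt(max(abs(coated$intensities - homog$intensities) /
                  homog$intensities), 1e-9)
  # core filling the whole sphere: profile is that of a sphere of RI_N
  full <- compute_lsp(cell_model(12, 1, 1.36, 1.40), setup,
                      normalize = FALSE)
  homog_n <- compute_lsp(cell_model(12, ri_cytosol = 1.40), setup,
                         normalize = FALSE)
  expect_lt(max(abs(full$intensities - homog_n$intensities) /
                  homog_n$intensities), 1e-9)
})

test_that("small-particle limit follows the Rayleigh dipole shape", {
  setup <- optical_setup()
  # x ~ 0.06 for this diameter at 632.8 nm in water-like medium
  d <- 0.06 * setup$wavelength_nm * 1e-3 / (pi * setup$medium_ri)
  prof <- compute_lsp(cell_model(d, ri_cytosol = 1.40), setup)
  expect_lt(max(abs(prof$intensities - rayleigh_shape(prof$angles_deg))),
            0.01)
})

test_that("an RBC-sized homogeneous sphere scatters mostly forward", {
  amp <- coated_sphere_amplitudes(cell_model(7.64, ri_cytosol = 1.40))
  expect_true(all(is.finite(Mod(amp$S1)), is.finite(Mod(amp$S2))))
  expect_gt(Mod(amp$S1[1]), Mod(amp$S1[length(amp$S1)]))
})

test_that("profiles live on the 281-point grid, positive and normalized", {
  prof <- compute_lsp(cell_model(18.44, 0.920, 1.36, 1.40))
  expect_length(prof$angles_deg, 281L)
  expect_true(all(prof$intensities > 0))
  expect_equal(max(prof$intensities), 1)
  raw <- compute_lsp(cell_model(18.44, 0.920, 1.36, 1.40),
                     normalize = FALSE)
  expect_false(isTRUE(all.equal(max(raw$intensities), 1)))
})

test_that("profiles vary continuously with diameter", {
  set.seed(99)
  for (i in 1:100) {
    cell <- random_nucleated_cell()
    a <- compute_lsp(cell)
    cell2 <- cell_model(cell$diameter_um + 0.01, cell$nc_ratio,
                        cell$ri_cytosol, cell$ri_nucleus)
    b <- compute_lsp(cell2)
    expect_true(all(is.finite(b$intensities)))
    expect_lt(max(abs(a$intensities - b$intensities)), 0.5)
  }
})

test_that("invalid models and out-of-range size parameters are rejected", {
  expect_error(cell_model(10, nc_ratio = 1.2, ri_cytosol = 1.36),
               "nc_ratio")
  expect_error(cell_model(10, nc_ratio = 0, ri_cytosol = 1.36), "nc_ratio")
  expect_error(cell_model(-1, ri_cytosol = 1.36), "diameter")
  expect_error(cell_model(10, ri_cytosol = 1.25), "1.30")
  expect_error(cell_model(10, nc_ratio = 0.9, ri_cytosol = 1.36),
               "homogeneous")
  # series refused beyond the validated size-parameter range, naming x
  expect_error(coated_sphere_amplitudes(
    cell_model(50, ri_cytosol = 1.36), optical_setup()), "size parameter")
})
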