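#' Mie size parameter of a cell model
#'
#' x = pi * D * n_medium / lambda, with the wavelength taken in the same
#' length unit as the diameter.
#'
#' @param cell A [cell_model()].
#' @param setup An [optical_setup()].
#' @return Dimensionless size parameter of the outer sphere.
#' @export
size_parameter <- function(cell, setup) {
  pi * cell$diameter_um * setup$medium_ri / (setup$wavelength_nm * 1e-3)
}

# (x_core, x_shell, m_core, m_shell) row for the compiled series.
# Homogeneous cells (absent RI_N, N/C = 1, or RI_N = RI_C) collapse to the
# plain Mie sphere: equal indices make the core/shell interface vanish
# exactly in the series.
mie_params <- function(cell, setup) {
  x <- size_parameter(cell, setup)
  if (is_homogeneous(cell)) {
    m <- if (!is.null(cell$ri_nucleus) && cell$nc_ratio == 1)
      cell$ri_nucleus else cell$ri_cytosol
    m <- m / setup$medium_ri
    c(x_core = x, x_shell = x, m_core = m, m_shell = m)
  } else {
    c(x_core = cell$nc_ratio * x, x_shell = x,
      m_core = cell$ri_nucleus / setup$medium_ri,
      m_shell = cell$ri_cytosol / setup$medium_ri)
  }
}

#' Scattering amplitudes of a coated-sphere cell model
#'
#' Computes the complex amplitude functions S1 and S2 of the concentric
#' two-layer sphere (Aden-Kerker series) on the angular grid of `setup`.
#' The series is truncated at `n_max = x + 4.05 x^(1/3) + 2` (Wiscombe).
#' For a homogeneous model the result is the ordinary Mie series.
#'
#' @inheritParams size_parameter
#' @return A list with `angles_deg`, complex vectors `S1` and `S2`, and
#'   `n_terms`, the series truncation order.
#' @examples
#' amp <- coated_sphere_amplitudes(cell_model(7.64, ri_cytosol = 1.40),
#'                                 optical_setup())
#' Mod(amp$S1[1]) > Mod(amp$S1[length(amp$S1)])  # forward dominance
#' @export
coated_sphere_amplitudes <- function(cell, setup = optical_setup()) {
  stopifnot(inherits(cell, "cell_model"), inherits(setup, "optical_setup"))
  x <- size_parameter(cell, setup)
  if (x > 300)
    stop("size parameter x = ", format(x),
         " exceeds 300: series truncation not validated there")
  p <- mie_params(cell, setup)
  ang <- setup_angles(setup)
  res <- mie_coated_cpp(p[["x_core"]], p[["x_shell"]], p[["m_core"]],
                        p[["m_shell"]], cos(ang * pi / 180))
  list(angles_deg = ang, S1 = res$S1, S2 = res$S2, n_terms = res$n_terms)
}

#' Light-scattering profile of a cell model
#'
#' The unpolarized intensity convention is used:
#' I(theta) = (|S1|^2 + |S2|^2) / 2 (the S11 Mueller-matrix element).
#'
#' @inheritParams size_parameter
#' @param normalize Scale the profile to unit maximum (default `TRUE`).
#' @return An [lsp()] on the setup's angular grid.
#' @examples
#' prof <- compute_lsp(cell_model(18.44, 0.920, 1.36, 1.40), optical_setup())
#' length(prof$angles_deg)  # 281 on the default grid
#' @export
compute_lsp <- function(cell, setup = optical_setup(), normalize = TRUE) {
  amp <- coated_sphere_amplitudes(cell, setup)
  s11 <- 0.5 * (Mod(amp$S1)^2 + Mod(amp$S2)^2)
  if (normalize) s11 <- s11 / max(s11)
  lsp(amp$angles_deg, s11, normalized = normalize)
}
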