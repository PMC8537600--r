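#' Two-compartment optical cell model
#'
#' A cell is represented as a concentric two-layer sphere: a nucleus core of
#' diameter `nc_ratio * diameter_um` and refractive index `ri_nucleus`,
#' inside a cytosol shell of outer diameter `diameter_um` and refractive
#' index `ri_cytosol`.  Omitting `ri_nucleus` declares a homogeneous sphere
#' (e.g. a red blood cell treated as an equivalent homogeneous sphere), in
#' which case `nc_ratio` must be 1 and `ri_cytosol` is the single index.
#'
#' @param diameter_um Cell diameter D in micrometres (> 0).
#' @param nc_ratio Nucleus-to-cell *diameter* ratio N/C in (0, 1].
#' @param ri_cytosol Refractive index of the cytosol shell, in [1.30, 1.60].
#' @param ri_nucleus Refractive index of the nucleus core, in [1.30, 1.60],
#'   or `NULL` for a homogeneous sphere.
#' @param label Optional cell-class tag (e.g. `"CTC"`).
#' @return An object of class `cell_model`.
#' @examples
#' ctc <- cell_model(18.44, nc_ratio = 0.920, ri_cytosol = 1.36,
#'                   ri_nucleus = 1.40, label = "CTC")
#' rbc <- cell_model(7.64, ri_cytosol = 1.40)  # homogeneous
#' @export
cell_model <- function(diameter_um, nc_ratio = 1, ri_cytosol,
                       ri_nucleus = NULL, label = NULL) {
  stopifnot(is.numeric(diameter_um), length(diameter_um) == 1L)
  if (!is.finite(diameter_um) || diameter_um <= 0)
    stop("diameter_um must be a positive number, got ", diameter_um)
  if (!is.finite(nc_ratio) || nc_ratio <= 0 || nc_ratio > 1)
    stop("nc_ratio must lie in (0, 1], got ", nc_ratio)
  check_ri <- function(x, what) {
    if (!is.finite(x) || x < 1.30 || x > 1.60)
      stop(what, " must lie in [1.30, 1.60], got ", x)
  }
  check_ri(ri_cytosol, "ri_cytosol")
  if (is.null(ri_nucleus) || (length(ri_nucleus) == 1L && is.na(ri_nucleus))) {
    if (nc_ratio != 1)
      stop("a homogeneous model (no ri_nucleus) requires nc_ratio = 1")
    ri_nucleus <- NULL
  } else {
    check_ri(ri_nucleus, "ri_nucleus")
  }
  structure(
    list(diameter_um = diameter_um, nc_ratio = nc_ratio,
         ri_cytosol = ri_cytosol, ri_nucleus = ri_nucleus,
         label = label),
    class = "cell_model")
}

#' @export
print.cell_model <- function(x, ...) {
  cat("<cell_model>", if (!is.null(x$label)) paste0("[", x$label, "]"), "\n")
  cat(sprintf("  D = %.3f um, N/C = %.4f, RI_C = %.4f, RI_N = %s\n",
              x$diameter_um, x$nc_ratio, x$ri_cytosol,
              if (is.null(x$ri_nucleus)) "- (homogeneous)"
              else sprintf("%.4f", x$ri_nucleus)))
  invisible(x)
}

is_homogeneous <- function(cell) {
  is.null(cell$ri_nucleus) || cell$nc_ratio == 1 ||
    cell$ri_nucleus == cell$ri_cytosol
}

#' Optical measurement setup
#'
#' Wavelength, suspension-medium refractive index and the fixed angular
#' acquisition grid.  The default grid runs from 2 to 30 degrees in steps
#' of 0.1 degrees (281 points).
#'
#' @param wavelength_nm Laser wavelength in nanometres (default 632.8, HeNe).
#' @param medium_ri Refractive index of the suspension medium; default 1.334
#'   (PBS with 0.4 wt% PEO, optically close to water).
#' @param angle_min_deg,angle_max_deg,angle_step_deg Angular grid bounds and
#'   resolution in degrees.
#' @return An object of class `optical_setup`.
#' @export
optical_setup <- function(wavelength_nm = 632.8, medium_ri = 1.334,
                          angle_min_deg = 2, angle_max_deg = 30,
                          angle_step_deg = 0.1) {
  if (!is.finite(wavelength_nm) || wavelength_nm <= 0)
    stop("wavelength_nm must be > 0")
  if (!is.finite(medium_ri) || medium_ri < 1)
    stop("medium_ri must be >= 1")
  if (angle_min_deg >= angle_max_deg || angle_step_deg <= 0)
    stop("need angle_min_deg < angle_max_deg and angle_step_deg > 0")
  n <- round((angle_max_deg - angle_min_deg) / angle_step_deg) + 1L
  structure(
    list(wavelength_nm = wavelength_nm, medium_ri = medium_ri,
         angle_min_deg = angle_min_deg, angle_max_deg = angle_max_deg,
         angle_step_deg = angle_step_deg, n_angles = as.integer(n)),
    class = "optical_setup")
}

#' @export
print.optical_setup <- function(x, ...) {
  cat(sprintf(
    "<optical_setup> lambda = %.1f nm, n_medium = %.4f, %g..%g deg x %g (%d pts)\n",
    x$wavelength_nm, x$medium_ri, x$angle_min_deg, x$angle_max_deg,
    x$angle_step_deg, x$n_angles))
  invisible(x)
}

#' Angular grid of an optical setup
#' @param setup An [optical_setup()].
#' @return Numeric vector of scattering angles in degrees.
#' @export
setup_angles <- function(setup) {
  seq(setup$angle_min_deg, by = setup$angle_step_deg,
      length.out = setup$n_angles)
}

#' Light-scattering profile container
#'
#' @param angles_deg Strictly increasing scattering angles in degrees.
#' @param intensities Non-negative scattered intensities, same length.
#' @param normalized Logical; `TRUE` if intensities are scaled to unit max.
#' @return An object of class `lsp`.
#' @export
lsp <- function(angles_deg, intensities, normalized = FALSE) {
  if (length(angles_deg) != length(intensities))
    stop("angles_deg and intensities must have equal length")
  if (any(!is.finite(angles_deg)) || any(diff(angles_deg) <= 0))
    stop("angles_deg must be finite and strictly increasing")
  if (any(!is.finite(intensities)) || any(intensities < 0))
    stop("intensities must be finite and non-negative")
  structure(list(angles_deg = as.numeric(angles_deg),
                 intensities = as.numeric(intensities),
                 normalized = isTRUE(normalized)),
            class = "lsp")
}

#' @export
print.lsp <- function(x, ...) {
  cat(sprintf("<lsp> %d angles in [%g, %g] deg, %s\n",
              length(x$angles_deg), min(x$angles_deg), max(x$angles_deg),
              if (x$normalized) "unit-max normalized" else "raw intensity"))
  invisible(x)
}

#' @export
as.data.frame.lsp <- function(x, ...) {
  data.frame(angle_deg = x$angles_deg, intensity = x$intensities)
}

#' Interpolate a profile onto the angular grid of a setup
#'
#' Off-grid experimental angles are linearly interpolated onto the fixed
#' acquisition grid; the profile must cover the full grid range.
#'
#' @param x An [lsp()].
#' @param setup An [optical_setup()].
#' @return An [lsp()] on `setup_angles(setup)`.
#' @export
resample_lsp <- function(x, setup) {
  grid <- setup_angles(setup)
  if (min(x$angles_deg) > grid[1] + 1e-9 ||
      max(x$angles_deg) < grid[length(grid)] - 1e-9)
    stop("profile covers [", min(x$angles_deg), ", ", max(x$angles_deg),
         "] deg but the setup grid needs [", grid[1], ", ",
         grid[length(grid)], "]")
  yi <- approx(x$angles_deg, x$intensities, xout = grid, rule = 2)$y
  lsp(grid, pmax(yi, 0), normalized = FALSE)
}
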