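#' Detector geometry for 2D diffraction patterns
#'
#' Maps radial pixel distance from the beam centre to scattering angle.
#' The mapping is linear in radius (small-angle thin-lens approximation):
#' `angle_deg = r_px / px_per_deg`.  It must be monotone and cover the
#' full angular range of the optical setup.
#'
#' @param width_px,height_px Image dimensions in pixels.
#' @param center_xy Beam-centre pixel coordinates `c(x, y)`; defaults to the
#'   image centre.
#' @param px_per_deg Pixels per degree of scattering angle.
#' @return An object of class `detector_geometry`.
#' @export
detector_geometry <- function(width_px = 512L, height_px = 512L,
                              center_xy = c((width_px + 1) / 2,
                                            (height_px + 1) / 2),
                              px_per_deg = 8.4) {
  stopifnot(width_px >= 8, height_px >= 8, px_per_deg > 0,
            length(center_xy) == 2L)
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 center_xy = as.numeric(center_xy),
                 px_per_deg = px_per_deg),
            class = "detector_geometry")
}

# radius (px) of every pixel from the beam centre; matrix is row = y, col = x
pixel_radius <- function(geom) {
  xs <- seq_len(geom$width_px) - geom$center_xy[1]
  ys <- seq_len(geom$height_px) - geom$center_xy[2]
  sqrt(outer(ys^2, xs^2, `+`))
}

check_coverage <- function(geom, setup) {
  if (geom$center_xy[1] < 1 || geom$center_xy[1] > geom$width_px ||
      geom$center_xy[2] < 1 || geom$center_xy[2] > geom$height_px)
    stop("beam centre lies outside the image")
  # radius available in every azimuthal direction
  r_avail <- min(geom$center_xy[1] - 1, geom$width_px - geom$center_xy[1],
                 geom$center_xy[2] - 1, geom$height_px - geom$center_xy[2])
  if (r_avail / geom$px_per_deg < setup$angle_max_deg)
    stop("detector covers only ", format(r_avail / geom$px_per_deg),
         " deg; the setup needs ", setup$angle_max_deg, " deg")
  invisible(TRUE)
}

#' Render a radially symmetric diffraction pattern from a profile
#'
#' Each pixel receives the profile value at the grid angle nearest to its
#' mapped angle (piecewise-constant in angle), so azimuthal averaging
#' recovers the profile exactly in the noiseless case.  Pixels outside the
#' angular range are zero.  Optional multiplicative noise
#' `I * (1 + noise_level * Z)`, `Z ~ N(0,1)`, is seeded and truncated at
#' one percent of the local intensity.
#'
#' @param x An [lsp()].
#' @param geom A [detector_geometry()].
#' @param noise_level Fractional noise standard deviation (>= 0).
#' @param seed Optional integer seed for the noise draw.
#' @param setup Optical setup defining the angular grid.
#' @return Numeric matrix `height_px` x `width_px`.
#' @export
render_pattern <- function(x, geom = detector_geometry(), noise_level = 0,
                           seed = NULL, setup = optical_setup()) {
  stopifnot(inherits(x, "lsp"), inherits(geom, "detector_geometry"),
            noise_level >= 0)
  check_coverage(geom, setup)
  grid <- x$angles_deg
  step <- grid[2] - grid[1]
  ang <- pixel_radius(geom) / geom$px_per_deg
  idx <- round((ang - grid[1]) / step) + 1
  inside <- idx >= 1 & idx <= length(grid) &
    ang >= grid[1] - step / 2 & ang <= grid[length(grid)] + step / 2
  img <- matrix(0, geom$height_px, geom$width_px)
  img[inside] <- x$intensities[idx[inside]]
  if (noise_level > 0) {
    if (!is.null(seed)) set.seed(seed)
    fac <- pmax(1 + noise_level * rnorm(sum(inside)), 0.01)
    img[inside] <- img[inside] * fac
  }
  img
}

#' Azimuthally average a diffraction pattern into a profile
#'
#' Bins pixel intensities by the grid angle nearest to their mapped
#' scattering angle and averages within each bin.  More than 10% empty
#' bins is an error (insufficient angular coverage); isolated empty bins
#' are filled by linear interpolation.
#'
#' @param image Numeric matrix of non-negative pixel intensities.
#' @param geom A [detector_geometry()].
#' @param setup An [optical_setup()] defining the output angular grid.
#' @return An [lsp()] on the setup grid.
#' @export
image_to_lsp <- function(image, geom = detector_geometry(),
                         setup = optical_setup()) {
  stopifnot(is.matrix(image))
  if (any(!is.finite(image)) || any(image < 0))
    stop("image must be finite and non-negative")
  if (nrow(image) != geom$height_px || ncol(image) != geom$width_px)
    stop("image dimensions do not match the detector geometry")
  check_coverage(geom, setup)
  grid <- setup_angles(setup)
  step <- setup$angle_step_deg
  ang <- pixel_radius(geom) / geom$px_per_deg
  idx <- round((ang - grid[1]) / step) + 1
  inside <- idx >= 1 & idx <= length(grid)
  sums <- rep(0, length(grid)); cnts <- rep(0L, length(grid))
  tab <- tapply(image[inside], idx[inside], sum)
  ii <- as.integer(names(tab))
  sums[ii] <- as.numeric(tab)
  cnt_tab <- table(idx[inside])
  cnts[as.integer(names(cnt_tab))] <- as.integer(cnt_tab)
  empty <- cnts == 0L
  if (mean(empty) > 0.10)
    stop(sprintf("%.1f%% of angular bins receive no pixel (max 10%%)",
                 100 * mean(empty)))
  y <- ifelse(empty, NA_real_, sums / pmax(cnts, 1L))
  if (any(empty))
    y[empty] <- approx(grid[!empty], y[!empty], xout = grid[empty],
                       rule = 2)$y
  lsp(grid, pmax(y, 0), normalized = FALSE)
}
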