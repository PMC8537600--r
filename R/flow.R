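#' Geometry and fluid constants of the viscoelastic alignment channel
#'
#' Defaults are the constants of the round first channel used for 3D
#' centreline focusing: inner radius R = 25 um, length L = 0.35 m, fluid
#' relaxation time 0.197 ms (0.4 wt% PEO in PBS) and mean flow velocity
#' 1496 um/s.
#'
#' @param inner_radius_um Channel inner radius R in micrometres.
#' @param channel_length_m Channel length L in metres.
#' @param relaxation_time_ms Fluid relaxation time in milliseconds.
#' @param mean_velocity_um_s Mean fluid velocity in micrometres per second.
#' @return An object of class `flow_cell_geometry`.
#' @export
flow_cell_geometry <- function(inner_radius_um = 25,
                               channel_length_m = 0.35,
                               relaxation_time_ms = 0.197,
                               mean_velocity_um_s = 1496) {
  vals <- c(inner_radius_um, channel_length_m, relaxation_time_ms,
            mean_velocity_um_s)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all flow-cell parameters must be strictly positive")
  structure(list(inner_radius_um = inner_radius_um,
                 channel_length_m = channel_length_m,
                 relaxation_time_ms = relaxation_time_ms,
                 mean_velocity_um_s = mean_velocity_um_s),
            class = "flow_cell_geometry")
}

#' Weissenberg number of the alignment channel
#'
#' Wi = 2 lambda Ubar / (2R), i.e. the fluid relaxation time times the
#' characteristic shear rate Ubar / R.  Units are normalized internally
#' (ms to s); the result is dimensionless.
#'
#' @param geom A [flow_cell_geometry()].
#' @return Dimensionless Weissenberg number.
#' @examples
#' weissenberg(flow_cell_geometry())  # ~0.0118
#' @export
weissenberg <- function(geom) {
  stopifnot(inherits(geom, "flow_cell_geometry"))
  lambda_s <- geom$relaxation_time_ms * 1e-3
  2 * lambda_s * geom$mean_velocity_um_s / (2 * geom$inner_radius_um)
}

#' Centreline alignment criterion for a cell in the viscoelastic channel
#'
#' The alignment parameter is theta = 3 Wi beta^2 L / (2R) with
#' beta = r1 / R the cell-to-channel radius ratio; the cell is predicted to
#' focus onto the centreline when theta exceeds -ln(3.5 beta).  All
#' intermediate quantities are returned for audit.
#'
#' @param geom A [flow_cell_geometry()].
#' @param cell_radius_um Cell radius r1 in micrometres, 0 < r1 < R.
#' @return An object of class `alignment_result` with fields `weissenberg`,
#'   `beta`, `theta`, `threshold` and logical `aligned`.
#' @examples
#' alignment_check(flow_cell_geometry(), cell_radius_um = 3.3)
#' @export
alignment_check <- function(geom, cell_radius_um) {
  stopifnot(inherits(geom, "flow_cell_geometry"))
  if (!is.finite(cell_radius_um) || cell_radius_um <= 0)
    stop("cell_radius_um must be > 0")
  if (cell_radius_um >= geom$inner_radius_um)
    stop("cell radius ", cell_radius_um,
         " um does not fit the channel (R = ", geom$inner_radius_um, " um)")
  wi <- weissenberg(geom)
  beta <- cell_radius_um / geom$inner_radius_um
  length_um <- geom$channel_length_m * 1e6
  theta <- 3 * wi * beta^2 * length_um / (2 * geom$inner_radius_um)
  threshold <- -log(3.5 * beta)
  structure(list(weissenberg = wi, beta = beta, theta = theta,
                 threshold = threshold, aligned = theta > threshold),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf(
    "<alignment_result> Wi = %.4g, beta = %.3f, theta = %.4g %s %.4g -> %s\n",
    x$weissenberg, x$beta, x$theta, if (x$aligned) ">" else "<=",
    x$threshold, if (x$aligned) "aligned" else "not aligned"))
  invisible(x)
}
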