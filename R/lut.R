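#' Four-axis parameter grid for the look-up table
#'
#' Each axis is given as `c(min, max, step)`.  Axis order: diameter (um),
#' N/C diameter ratio, cytosol RI, nucleus RI.
#'
#' @param diameter_um,nc_ratio,ri_cytosol,ri_nucleus Numeric triples
#'   `c(min, max, step)`.
#' @return An object of class `grid_spec`.
#' @seealso [default_grid()] for the full-scale production grid.
#' @export
grid_spec <- function(diameter_um, nc_ratio, ri_cytosol, ri_nucleus) {
  axes <- list(diameter_um = diameter_um, nc_ratio = nc_ratio,
               ri_cytosol = ri_cytosol, ri_nucleus = ri_nucleus)
  for (nm in names(axes)) {
    a <- axes[[nm]]
    if (length(a) != 3L || !all(is.finite(a)))
      stop(nm, " must be c(min, max, step)")
    if (a[1] > a[2] || a[3] <= 0)
      stop(nm, ": need min <= max and step > 0")
  }
  structure(axes, class = "grid_spec")
}

#' Default look-up-table grid
#'
#' Spans all the cell classes handled by the classifier with margin:
#' D 4.00-25.00 um step 0.25, N/C 0.60-1.00 step 0.005, RI_C 1.34-1.41
#' step 0.01, RI_N 1.36-1.45 step 0.01 - 550,800 grid points in total,
#' comfortably above the 300,000-profile scale the method was built at.
#' @return A [grid_spec()].
#' @export
default_grid <- function() {
  grid_spec(diameter_um = c(4.00, 25.00, 0.25),
            nc_ratio = c(0.60, 1.00, 0.005),
            ri_cytosol = c(1.34, 1.41, 0.01),
            ri_nucleus = c(1.36, 1.45, 0.01))
}

#' @export
print.grid_spec <- function(x, ...) {
  cat("<grid_spec>", format(grid_cardinality(x), big.mark = ","),
      "points\n")
  for (nm in names(unclass(x)))
    cat(sprintf("  %-11s %g .. %g step %g (%d)\n", nm, x[[nm]][1],
                x[[nm]][2], x[[nm]][3], length(axis_values(x, nm))))
  invisible(x)
}

#' Grid values along one axis
#' @param grid A [grid_spec()].
#' @param axis Axis name.
#' @return Numeric vector of axis values.
#' @export
axis_values <- function(grid, axis) {
  a <- grid[[axis]]
  n <- floor(round((a[2] - a[1]) / a[3], 9)) + 1L
  a[1] + a[3] * (seq_len(n) - 1L)
}

#' Number of grid points in a grid specification
#' @param grid A [grid_spec()].
#' @return Integer product of the per-axis point counts.
#' @export
grid_cardinality <- function(grid) {
  as.integer(prod(vapply(names(unclass(grid)),
                         function(nm) length(axis_values(grid, nm)),
                         integer(1))))
}

grid_table <- function(grid) {
  expand.grid(diameter_um = axis_values(grid, "diameter_um"),
              nc_ratio = axis_values(grid, "nc_ratio"),
              ri_cytosol = axis_values(grid, "ri_cytosol"),
              ri_nucleus = axis_values(grid, "ri_nucleus"),
              KEEP.OUT.ATTRS = FALSE)
}

#' Build a look-up table of theoretical scattering profiles
#'
#' Computes one unit-max-normalized coated-sphere profile per grid point on
#' the angular grid of `setup`.  Deterministic: depends only on the grid
#' and the optical setup.
#'
#' @param grid A [grid_spec()].
#' @param setup An [optical_setup()].
#' @return An object of class `lut` with elements `grid`, `setup`,
#'   `params` (one row per entry) and `profiles`
#'   (entries x angles matrix, each row unit-max normalized).
#' @export
build_lut <- function(grid, setup = optical_setup()) {
  stopifnot(inherits(grid, "grid_spec"), inherits(setup, "optical_setup"))
  tab <- grid_table(grid)
  lam_um <- setup$wavelength_nm * 1e-3
  x <- pi * tab$diameter_um * setup$medium_ri / lam_um
  pm <- cbind(x_core = tab$nc_ratio * x, x_shell = x,
              m_core = tab$ri_nucleus / setup$medium_ri,
              m_shell = tab$ri_cytosol / setup$medium_ri)
  ang <- setup_angles(setup)
  profiles <- mie_s11_batch_cpp(pm, cos(ang * pi / 180), TRUE)
  structure(list(grid = grid, setup = setup, params = tab,
                 profiles = profiles, version = "1",
                 cache = new.env(parent = emptyenv())),
            class = "lut")
}

#' @export
print.lut <- function(x, ...) {
  cat("<lut>", format(nrow(x$profiles), big.mark = ","), "profiles x",
      ncol(x$profiles), "angles\n")
  print(x$grid)
  invisible(x)
}

#' Persist / load a look-up table
#'
#' The table round-trips bit-identically through R native serialization.
#'
#' @param lut A `lut` object.
#' @param path File path.
#' @return `read_lut` returns the `lut`; `write_lut` returns `path`
#'   invisibly.
#' @export
write_lut <- function(lut, path) {
  stopifnot(inherits(lut, "lut"))
  keep <- lut
  keep$cache <- NULL
  saveRDS(keep, path)
  invisible(path)
}

#' @rdname write_lut
#' @export
read_lut <- function(path) {
  lut <- readRDS(path)
  if (!inherits(lut, "lut")) stop(path, " does not contain a look-up table")
  lut$cache <- new.env(parent = emptyenv())
  lut
}

# log10 profile matrix and its row norms, cached per LUT
lut_log_matrix <- function(lut) {
  cache <- lut$cache
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  if (is.null(cache$logp)) {
    cache$logp <- log10(pmax(lut$profiles, 1e-12))
    cache$norms <- sqrt(rowSums(cache$logp^2))
  }
  list(logp = cache$logp, norms = cache$norms)
}

# log10 feature vector of a profile after unit-max normalization
log_feature <- function(intensities) {
  v <- intensities / max(intensities)
  log10(pmax(v, 1e-12))
}

#' Distance between two scattering profiles
#'
#' Cosine distance between log10-intensity vectors after unit-max
#' normalization of each profile.  Invariant under positive rescaling of
#' either profile (absolute intensity depends on laser power and exposure).
#'
#' @param a,b [lsp()] objects or numeric intensity vectors on a common
#'   angular grid.
#' @return Non-negative distance (0 for identical shapes).
#' @export
profile_distance <- function(a, b) {
  ia <- if (inherits(a, "lsp")) a$intensities else a
  ib <- if (inherits(b, "lsp")) b$intensities else b
  if (length(ia) != length(ib)) stop("profiles are on different grids")
  va <- log_feature(ia); vb <- log_feature(ib)
  1 - sum(va * vb) / (sqrt(sum(va^2)) * sqrt(sum(vb^2)))
}

#' Match a measured profile against a look-up table
#'
#' Returns the grid entry minimizing the profile distance.  Distance ties
#' (equal within 1e-9, far below any physically meaningful profile
#' difference but above floating-point summation noise) are broken
#' deterministically by smallest diameter, then smallest N/C ratio, then
#' smallest cytosol and nucleus RI.
#'
#' @param x An [lsp()] on the LUT's angular grid (see [resample_lsp()]).
#' @param lut A `lut` from [build_lut()].
#' @param k Number of top candidates to return (default 1).
#' @return A list with `cell` (the best-match [cell_model()]), `distance`,
#'   `index`, and when `k > 1` a data frame `candidates` of the `k` best
#'   entries.
#' @export
match_lsp <- function(x, lut, k = 1L) {
  stopifnot(inherits(x, "lsp"), inherits(lut, "lut"))
  if (nrow(lut$profiles) == 0L) stop("empty look-up table")
  if (any(!is.finite(x$intensities)))
    stop("profile contains non-finite intensities")
  if (length(x$intensities) != ncol(lut$profiles))
    stop("profile has ", length(x$intensities), " points but the LUT grid has ",
         ncol(lut$profiles))
  lm <- lut_log_matrix(lut)
  q <- log_feature(x$intensities)
  d <- 1 - as.numeric(lm$logp %*% q) / (lm$norms * sqrt(sum(q^2)))
  # identical profiles can differ in the last bits of the BLAS reduction;
  # snap the leading tie group before applying the deterministic keys
  ds <- d
  ds[ds <= min(ds) + 1e-9] <- min(ds)
  ord <- order(ds, lut$params$diameter_um, lut$params$nc_ratio,
               lut$params$ri_cytosol, lut$params$ri_nucleus)
  best <- ord[1]
  p <- lut$params[best, ]
  out <- list(cell = cell_model(p$diameter_um, p$nc_ratio, p$ri_cytosol,
                                p$ri_nucleus),
              distance = d[best], index = best)
  if (k > 1L) {
    top <- ord[seq_len(min(k, length(ord)))]
    out$candidates <- cbind(lut$params[top, , drop = FALSE],
                            distance = d[top], index = top)
    rownames(out$candidates) <- NULL
  }
  out
}
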