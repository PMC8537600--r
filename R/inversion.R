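# Parameter recovery from a measured profile: coarse LUT match, then a
# bounded local search of the same profile distance around the match.

# reporting resolutions of the recovered parameters
REPORT_RES <- c(diameter_um = 0.01, nc_ratio = 0.005,
                ri_cytosol = 0.01, ri_nucleus = 0.01)

# physical validity box used to clip local-search iterates
PARAM_LO <- c(diameter_um = 0.2, nc_ratio = 0.05,
              ri_cytosol = 1.30, ri_nucleus = 1.30)
PARAM_HI <- c(diameter_um = 60, nc_ratio = 1.00,
              ri_cytosol = 1.60, ri_nucleus = 1.60)

param_vec <- function(cell) {
  c(diameter_um = cell$diameter_um, nc_ratio = cell$nc_ratio,
    ri_cytosol = cell$ri_cytosol,
    ri_nucleus = if (is.null(cell$ri_nucleus)) cell$ri_cytosol
                 else cell$ri_nucleus)
}

# objective: distance between the measured profile and the forward model
make_objective <- function(x, setup) {
  mu <- cos(setup_angles(setup) * pi / 180)
  lam_um <- setup$wavelength_nm * 1e-3
  q <- log_feature(x$intensities)
  qn <- sqrt(sum(q^2))
  function(p) {
    xs <- pi * p[["diameter_um"]] * setup$medium_ri / lam_um
    pm <- matrix(c(p[["nc_ratio"]] * xs, xs,
                   p[["ri_nucleus"]] / setup$medium_ri,
                   p[["ri_cytosol"]] / setup$medium_ri), nrow = 1)
    v <- log10(pmax(mie_s11_batch_cpp(pm, mu, TRUE)[1, ], 1e-12))
    1 - sum(v * q) / (sqrt(sum(v^2)) * qn)
  }
}

# compass (pattern) search of f over `free` axes inside [lo, hi],
# step halving down to `final_step`; monotone non-increasing in f
compass_search <- function(f, p0, free, lo, hi, step0, final_step,
                           max_eval = 4000) {
  p <- p0
  fp <- f(p)
  s <- step0
  nev <- 1L
  while (any(s[free] > final_step[free] * 0.999) && nev < max_eval) {
    improved <- FALSE
    for (ax in free) {
      for (dir in c(1, -1)) {
        cand <- p
        cand[ax] <- min(max(p[ax] + dir * s[ax], lo[ax]), hi[ax])
        if (cand[ax] == p[ax]) next
        fc <- f(cand)
        nev <- nev + 1L
        if (fc < fp) {
          p <- cand; fp <- fc; improved <- TRUE
        }
      }
    }
    if (!improved) s <- s / 2
  }
  list(par = p, value = fp, evals = nev)
}

#' Locally refine a coarse look-up-table match
#'
#' Minimizes the same scale-invariant profile distance used for matching,
#' within plus or minus one grid step per axis around the coarse match,
#' with box-constrained quasi-Newton iterations (L-BFGS-B; a derivative-free
#' compass search with step halving is the fallback if the quasi-Newton path
#' fails).  The refined distance never exceeds the seed's.  Parameters are
#' additionally reported at the instrument resolutions: 0.01 um for D, 0.01
#' for both refractive indices and 0.005 for the N/C ratio.
#'
#' @param x The measured [lsp()].
#' @param seed_model Coarse-match [cell_model()] (the search centre).
#' @param setup An [optical_setup()].
#' @param box_steps Named per-axis half-widths of the search box; defaults
#'   to one step of [default_grid()] per axis.
#' @param homogeneous If `TRUE`, fit a homogeneous sphere: only diameter
#'   and a single refractive index are free (N/C fixed at 1).
#' @return A list with `cell` (refined continuous parameters), `reported`
#'   (precision-rounded parameters), `distance` and `seed_distance`.
#' @export
refine <- function(x, seed_model, setup = optical_setup(),
                   box_steps = c(diameter_um = 0.25, nc_ratio = 0.005,
                                 ri_cytosol = 0.01, ri_nucleus = 0.01),
                   homogeneous = FALSE) {
  stopifnot(inherits(x, "lsp"), inherits(seed_model, "cell_model"))
  f <- make_objective(x, setup)
  p0 <- param_vec(seed_model)
  axes <- names(REPORT_RES)
  if (homogeneous) {
    p0["nc_ratio"] <- 1
    p0["ri_cytosol"] <- p0["ri_nucleus"]
    free <- c("diameter_um", "ri_nucleus")
  } else {
    free <- axes
  }
  box <- REPORT_RES * 0 + box_steps[axes]
  lo <- pmax(p0 - box, PARAM_LO)
  hi <- pmin(p0 + box, PARAM_HI)
  ob <- function(pf) {
    p <- p0
    p[free] <- pf
    if (homogeneous) p["ri_cytosol"] <- p["ri_nucleus"]
    f(p)
  }
  fit <- tryCatch(
    optim(p0[free], ob, method = "L-BFGS-B", lower = lo[free],
          upper = hi[free],
          control = list(maxit = 200, factr = 10,
                         parscale = pmax(box[free] / 5, REPORT_RES[free] / 5))),
    error = function(e) NULL)
  if (is.null(fit)) {
    cs <- compass_search(f, p0, free, lo, hi,
                         step0 = pmax(box / 2, REPORT_RES / 4),
                         final_step = REPORT_RES / 8)
    fit <- list(par = cs$par[free], value = cs$value, counts = cs$evals)
  }
  pf <- pmin(pmax(fit$par, lo[free]), hi[free])
  p <- p0
  p[free] <- pf
  res <- list(par = p, value = ob(pf), evals = sum(fit$counts))
  if (res$value > f(p0)) { # never worse than the seed
    res$par <- p0
    res$value <- f(p0)
    p <- p0
  }
  if (homogeneous) p["ri_cytosol"] <- p["ri_nucleus"]
  rep_p <- round(p / REPORT_RES) * REPORT_RES
  rep_p["nc_ratio"] <- min(rep_p["nc_ratio"], 1)
  cell <- cell_model(p[["diameter_um"]], p[["nc_ratio"]],
                     p[["ri_cytosol"]], p[["ri_nucleus"]])
  list(cell = cell, reported = as.list(rep_p), distance = res$value,
       seed_distance = f(param_vec(seed_model)), evals = res$evals,
       homogeneous = homogeneous)
}

#' Invert a light-scattering profile to biophysical cell properties
#'
#' Two-stage inversion: exhaustive match against the look-up table, then
#' bounded local refinement of the best candidates.  When a refinement ends
#' on its box boundary with a clearly non-zero residual the search box is
#' re-centred on the current best fit and refinement repeats (at most
#' `max_hops` times), letting the fit walk along the valley of the profile
#' distance when the coarse match lands a few grid steps away from the
#' optimum.  Degenerate matches are
#' canonicalized before refinement: when the matched core and shell indices
#' coincide the N/C ratio has no effect on the profile, and when the
#' matched N/C ratio is 1 the cytosol index has none; either way the cell
#' is reported as a homogeneous sphere (N/C = 1, a single RI).
#'
#' @param x An [lsp()] on the LUT's angular grid.
#' @param lut A `lut` from [build_lut()].
#' @param setup Optical setup; defaults to the one the LUT was built with.
#' @param do_refine Refine the coarse match (default `TRUE`).
#' @param top_k Number of coarse candidates refined (best final distance
#'   wins); multi-start protects against coarse matches in a neighbouring
#'   local basin of the oscillatory profile distance.
#' @param max_hops Maximum number of box re-centrings per candidate.
#' @param hop_tol Residual distance below which a fit is accepted without
#'   further re-centring.
#' @param retry_k,retry_tol If the best residual distance still exceeds
#'   `retry_tol` (implausible for a profile the forward model can represent
#'   exactly), the inversion is repeated once with `retry_k` coarse
#'   candidates.  Set `retry_k = top_k` to disable the escalation (e.g.
#'   for noisy profiles, whose residuals are legitimately large).
#' @return An object of class `inversion_result`: `coarse`, `cell`
#'   (refined), `reported` (precision-rounded named list), `distance`,
#'   `coarse_distance`, `homogeneous`.
#' @export
invert_lsp <- function(x, lut, setup = lut$setup, do_refine = TRUE,
                       top_k = 10L, max_hops = 8L, hop_tol = 1e-10,
                       retry_k = 25L, retry_tol = 1e-9) {
  res <- invert_once(x, lut, setup, do_refine, top_k, max_hops, hop_tol)
  if (do_refine && retry_k > top_k && res$distance > retry_tol) {
    res2 <- invert_once(x, lut, setup, do_refine, retry_k, max_hops,
                        hop_tol)
    if (res2$distance < res$distance) res <- res2
  }
  res
}

invert_once <- function(x, lut, setup, do_refine, top_k, max_hops,
                        hop_tol) {
  mm <- match_lsp(x, lut, k = max(top_k, 1L))
  cand <- if (!is.null(mm$candidates)) mm$candidates
          else cbind(as.data.frame(t(param_vec(mm$cell))),
                     distance = mm$distance)
  # per-axis grid steps define the refinement box
  steps <- c(diameter_um = lut$grid$diameter_um[3],
             nc_ratio = lut$grid$nc_ratio[3],
             ri_cytosol = lut$grid$ri_cytosol[3],
             ri_nucleus = lut$grid$ri_nucleus[3])
  seeds <- list()
  add_seed <- function(d, nc, ric, rin, hom) {
    key <- paste(signif(c(d, nc, ric, rin), 10), hom, collapse = "|")
    if (is.null(seeds[[key]]))
      seeds[[key]] <<- list(cell = cell_model(d, nc, ric, rin), hom = hom)
  }
  for (i in seq_len(nrow(cand))) {
    r <- cand[i, ]
    add_seed(r$diameter_um, r$nc_ratio, r$ri_cytosol, r$ri_nucleus, FALSE)
    # homogeneous reading of the same candidate: a cell whose core and
    # shell indices coincide (or whose core fills the sphere) produces the
    # profile of a plain sphere, so the simpler model is always tried too
    add_seed(r$diameter_um, 1, r$ri_nucleus, r$ri_nucleus, TRUE)
  }
  if (!do_refine) {
    p <- param_vec(mm$cell)
    rep_p <- round(p / REPORT_RES) * REPORT_RES
    return(structure(list(coarse = mm$cell, cell = mm$cell,
                          reported = as.list(rep_p),
                          distance = mm$distance,
                          coarse_distance = mm$distance,
                          homogeneous = FALSE),
                     class = "inversion_result"))
  }
  fits <- lapply(seeds, function(s) {
    fit <- refine(x, s$cell, setup, box_steps = steps,
                  homogeneous = s$hom)
    for (hop in seq_len(max_hops)) {
      if (fit$distance < hop_tol) break
      nxt <- refine(x, fit$cell, setup, box_steps = steps,
                    homogeneous = s$hom)
      if (nxt$distance >= fit$distance - 1e-14) break
      fit <- nxt
    }
    fit
  })
  dist <- pmax(vapply(fits, `[[`, numeric(1), "distance"), 0)
  hom <- vapply(fits, `[[`, logical(1), "homogeneous")
  # prefer the simpler homogeneous reading on numerical near-ties: for a
  # homogeneous scatterer the four-parameter fit reaches the same residual
  # with arbitrary N/C and shell index, which carries no information
  near <- dist <= min(dist) + 1e-9
  best <- which(near)[order(!hom[near], dist[near])][1]
  fit <- fits[[best]]
  structure(list(coarse = mm$cell, cell = fit$cell,
                 reported = fit$reported, distance = fit$distance,
                 coarse_distance = mm$distance,
                 homogeneous = fit$homogeneous),
            class = "inversion_result")
}

#' @export
print.inversion_result <- function(x, ...) {
  r <- x$reported
  cat(sprintf(
    "<inversion_result> D = %.2f um, N/C = %.3f, RI_C = %.2f, RI_N = %.2f\n",
    r$diameter_um, r$nc_ratio, r$ri_cytosol, r$ri_nucleus))
  cat(sprintf("  distance %.3e (coarse %.3e)%s\n", x$distance,
              x$coarse_distance,
              if (x$homogeneous) ", homogeneous" else ""))
  invisible(x)
}

#' Invert a set of profiles into a feature table
#'
#' @param lsps A list of [lsp()] objects (optionally named by cell id).
#' @param lut A `lut`.
#' @param ... Passed to [invert_lsp()].
#' @return A data frame with columns `cell_id`, `diameter_um`,
#'   `ri_cytosol`, `ri_nucleus`, `nc_ratio`, `distance` (reported,
#'   precision-rounded values).
#' @export
invert_population <- function(lsps, lut, ...) {
  ids <- names(lsps)
  if (is.null(ids)) ids <- as.character(seq_along(lsps))
  rows <- lapply(seq_along(lsps), function(i) {
    r <- invert_lsp(lsps[[i]], lut, ...)
    data.frame(cell_id = ids[i],
               diameter_um = r$reported$diameter_um,
               ri_cytosol = r$reported$ri_cytosol,
               ri_nucleus = r$reported$ri_nucleus,
               nc_ratio = r$reported$nc_ratio,
               distance = r$distance)
  })
  do.call(rbind, rows)
}
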