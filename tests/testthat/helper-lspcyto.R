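# Shared fixtures, built in code.  Expensive objects are memoised in a
# helper environment so each is built at most once per test run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# small LUT spanning the mid-size nucleated-cell region; 324 entries
tiny_lut <- function() {
  memo("tiny_lut", function() {
    build_lut(grid_spec(c(9, 11, 0.25), c(0.86, 0.92, 0.02),
                        c(1.35, 1.37, 0.01), c(1.39, 1.41, 0.01)))
  })
}

# unpolarized dipole (Rayleigh) angular shape, unit maximum
rayleigh_shape <- function(angles_deg) {
  s <- (1 + cos(angles_deg * pi / 180)^2) / 2
  s / max(s)
}

# independent linear-scan argmin over a LUT, sharing only the public
# profile_distance definition with the implementation under test
brute_force_match <- function(x, lut) {
  d <- vapply(seq_len(nrow(lut$profiles)), function(i)
    profile_distance(x$intensities, lut$profiles[i, ]), numeric(1))
  ord <- order(d, lut$params$diameter_um, lut$params$nc_ratio,
               lut$params$ri_cytosol, lut$params$ri_nucleus)
  list(index = ord[1], distance = d[ord[1]])
}

random_nucleated_cell <- function() {
  cell_model(runif(1, 6.6, 21.9), runif(1, 0.784, 0.975),
             runif(1, 1.355, 1.365), runif(1, 1.375, 1.425))
}
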