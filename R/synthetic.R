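# Class-conditional synthetic cell populations with the distributional
# structure of the five reference classes (diameter mean +/- SD, point
# refractive indices and N/C ratio), plus the packaged per-sample count
# tables.

#' Reference biophysical parameters of the built-in cell classes
#'
#' Diameter mean and SD, point values for the compartment refractive
#' indices and the N/C diameter ratio for the five built-in classes (CTC,
#' RBC, T- and B-lymphocytes, monocytes).  RBC are anucleate and carry no
#' nucleus index.  Granulocytes (`Macro`) have no built-in parameters and
#' must be supplied via `extra` when a scenario needs them.
#'
#' Only the diameter has a reported population SD; the refractive-index and
#' N/C jitter default to half the instrument reporting precision (0.005 and
#' 0.0025) and can be overridden.
#'
#' @param ri_sd Class-conditional SD of both refractive indices.
#' @param nc_sd Class-conditional SD of the N/C ratio.
#' @param extra Optional data frame of additional classes with the same
#'   columns as the built-in table.
#' @return Data frame with one row per class.
#' @export
class_parameters <- function(ri_sd = 0.005, nc_sd = 0.0025, extra = NULL) {
  path <- system.file("extdata", "table1_class_parameters.csv",
                      package = "lspcyto", mustWork = TRUE)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(extra)) tab <- rbind(tab, extra[, names(tab)])
  tab$ri_sd <- ri_sd
  tab$nc_sd <- nc_sd
  tab
}

rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(rep(mean, n))
  x <- rnorm(n, mean, sd)
  bad <- which(x <= lower | x > upper)
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= lower | x[bad] > upper]
  }
  x
}

#' Draw a synthetic class-conditional cell population
#'
#' Per class: D ~ Normal(mean, SD) truncated to positive values,
#' RI ~ Normal(point, `ri_sd`) kept within [1.30, 1.60], and
#' N/C ~ Normal(point, `nc_sd`) truncated to (0, 1].  Draws are seeded and
#' bit-reproducible.
#'
#' @param n Named integer vector of cells per class, e.g.
#'   `c(T = 200, CTC = 50)`.
#' @param params Class parameter table from [class_parameters()].
#' @param seed Integer seed.
#' @param sample_id Sample tag written into every record.
#' @return Feature record data frame with columns `sample_id`, `cell_id`,
#'   `diameter_um`, `ri_cytosol`, `ri_nucleus` (`NA` for anucleate
#'   classes), `nc_ratio`, `label`.
#' @export
sample_population <- function(n, params = class_parameters(), seed = 1L,
                              sample_id = "synthetic") {
  stopifnot(!is.null(names(n)), all(n >= 0))
  missing_cls <- setdiff(names(n)[n > 0], params$class)
  if (length(missing_cls))
    stop("no class parameters for: ", paste(missing_cls, collapse = ", "),
         " (supply them via class_parameters(extra = ...))")
  set.seed(seed)
  rows <- lapply(names(n)[n > 0], function(cl) {
    p <- params[params$class == cl, ]
    k <- n[[cl]]
    data.frame(
      sample_id = sample_id,
      cell_id = NA_integer_,
      diameter_um = rtrunc_norm(k, p$d_mean_um, p$d_sd_um, lower = 0),
      ri_cytosol = rtrunc_norm(k, p$ri_cytosol, p$ri_sd, 1.30, 1.60),
      ri_nucleus = if (is.na(p$ri_nucleus)) rep(NA_real_, k)
                   else rtrunc_norm(k, p$ri_nucleus, p$ri_sd, 1.30, 1.60),
      nc_ratio = rtrunc_norm(k, p$nc_ratio, p$nc_sd, 0, 1),
      label = rep(cl, k))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(sample_id = character(), cell_id = integer(),
                      diameter_um = numeric(), ri_cytosol = numeric(),
                      ri_nucleus = numeric(), nc_ratio = numeric(),
                      label = character())
  else out$cell_id <- seq_len(nrow(out))
  out
}

#' Class mixture fractions of the named scenarios
#'
#' `"adenocarcinoma-like"` uses the mean per-sample percentages of the
#' seven adenocarcinoma samples of the packaged nine-sample count table;
#' `"training-sample-t0"`, `"-t1"`, `"-t2"` use the packaged culture
#' time-course percentages; `"balanced"` gives the five built-in classes
#' equal weight.
#'
#' @param scenario Scenario name.
#' @return Named fractions summing to 1.
#' @export
scenario_fractions <- function(scenario = c("adenocarcinoma-like",
                                            "training-sample-t0",
                                            "training-sample-t1",
                                            "training-sample-t2",
                                            "balanced")) {
  scenario <- match.arg(scenario)
  if (scenario == "balanced") {
    f <- setNames(rep(1 / 5, 5), c("RBC", "T", "B", "M", "CTC"))
  } else if (scenario == "adenocarcinoma-like") {
    reports <- lapply(3:9, function(s)
      enumerate_sample(counts_to_records(table3_counts(), s)))
    f <- aggregate_reports(reports) / 100
  } else {
    step <- as.integer(sub("training-sample-t", "", scenario)) + 1L
    tab <- table2_percentages()
    f <- unlist(tab[tab$time_step == step, CELL_CLASSES]) / 100
    names(f) <- CELL_CLASSES
  }
  f / sum(f)
}

#' Draw a mixed population for a named scenario
#'
#' Class counts are a seeded multinomial draw from the scenario fractions.
#'
#' @param scenario Scenario name (see [scenario_fractions()]).
#' @param n_total Total number of cells.
#' @param params Class parameter table.
#' @param seed Integer seed.
#' @return Feature records as in [sample_population()].
#' @export
sample_scenario <- function(scenario, n_total, params = class_parameters(),
                            seed = 1L) {
  f <- scenario_fractions(scenario)
  f <- f[f > 0]
  set.seed(seed)
  counts <- as.integer(stats::rmultinom(1, n_total, f))
  sample_population(setNames(counts, names(f)), params = params,
                    seed = seed + 1L, sample_id = scenario)
}

#' Forward-simulate profiles for a feature table
#'
#' One coated-sphere profile per record (anucleate records become
#' homogeneous spheres), with optional seeded multiplicative intensity
#' noise `I * (1 + noise_level * Z)`.
#'
#' @param records Feature records (see [sample_population()]).
#' @param setup An [optical_setup()].
#' @param noise_level Fractional noise SD (0 = noiseless).
#' @param seed Seed for the noise draw.
#' @return Named list of [lsp()] objects (names = `cell_id`).
#' @export
population_to_lsps <- function(records, setup = optical_setup(),
                               noise_level = 0, seed = 1L) {
  if (nrow(records) == 0L) return(list())
  lam_um <- setup$wavelength_nm * 1e-3
  x <- pi * records$diameter_um * setup$medium_ri / lam_um
  anuc <- is.na(records$ri_nucleus)
  m_core <- ifelse(anuc, records$ri_cytosol, records$ri_nucleus) /
    setup$medium_ri
  pm <- cbind(x_core = ifelse(anuc, x, records$nc_ratio * x), x_shell = x,
              m_core = m_core,
              m_shell = records$ri_cytosol / setup$medium_ri)
  ang <- setup_angles(setup)
  prof <- mie_s11_batch_cpp(pm, cos(ang * pi / 180), TRUE)
  if (noise_level > 0) {
    set.seed(seed)
    fac <- matrix(pmax(1 + noise_level * rnorm(length(prof)), 0.01),
                  nrow(prof), ncol(prof))
    prof <- prof * fac
  }
  out <- lapply(seq_len(nrow(prof)), function(i)
    lsp(ang, prof[i, ], normalized = noise_level == 0))
  names(out) <- as.character(records$cell_id)
  out
}

#' Packaged per-sample cell-type counts of the nine measured samples
#'
#' The printed class counts of the nine patient samples, shipped verbatim
#' as a fixture.
#'
#' @return Data frame with a `class` column (RBC, T, B, M, Macro, CTC) and
#'   columns `sample_1` .. `sample_9`.
#' @export
table3_counts <- function() {
  path <- system.file("extdata", "table3_counts.csv", package = "lspcyto",
                      mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}

#' Packaged culture time-course composition percentages
#'
#' @return Data frame with `time_step` and one percentage column per class.
#' @export
table2_percentages <- function() {
  path <- system.file("extdata", "table2_timecourse.csv",
                      package = "lspcyto", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}
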