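# End-to-end composition: (image ->) profile -> inversion -> classification
# -> per-sample enumeration, driven by one configuration object.

#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end run with documented defaults.
#' All randomness in a run flows from the single `seed`.
#'
#' @param setup An [optical_setup()].
#' @param grid [grid_spec()] for the look-up table.
#' @param flow A [flow_cell_geometry()].
#' @param algorithm Classifier algorithm name.
#' @param noise_level Multiplicative intensity noise applied when the
#'   pipeline simulates profiles.
#' @param top_k Coarse candidates refined per inversion.
#' @param seed Master seed.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(setup = optical_setup(), grid = default_grid(),
                            flow = flow_cell_geometry(),
                            algorithm = "quadratic-svm", noise_level = 0,
                            top_k = 3L, seed = 1L) {
  structure(list(setup = setup, grid = grid, flow = flow,
                 algorithm = algorithm, noise_level = noise_level,
                 top_k = as.integer(top_k), seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration as JSON
#'
#' The representation round-trips losslessly.
#'
#' @param config A [pipeline_config()].
#' @param path File path.
#' @return `read_config` returns the [pipeline_config()].
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  body <- list(setup = unclass(config$setup),
               grid = unclass(config$grid),
               flow = unclass(config$flow),
               algorithm = config$algorithm,
               noise_level = config$noise_level,
               top_k = config$top_k, seed = config$seed)
  jsonlite::write_json(body, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  b <- jsonlite::read_json(path, simplifyVector = TRUE)
  pipeline_config(
    setup = do.call(optical_setup, b$setup[setdiff(names(b$setup),
                                                   "n_angles")]),
    grid = do.call(grid_spec, lapply(b$grid, as.numeric)),
    flow = do.call(flow_cell_geometry, b$flow),
    algorithm = b$algorithm, noise_level = b$noise_level,
    top_k = b$top_k, seed = b$seed)
}

stage <- function(name, expr, verbose = FALSE) {
  if (verbose) message("[", name, "] ...")
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full measurement pipeline on a set of profiles
#'
#' Inverts each profile against the look-up table, classifies the recovered
#' features, and enumerates the class composition of the sample.  Inputs
#' may be [lsp()] objects, paths to LSP CSV files, or 2D image matrices
#' (converted with [image_to_lsp()]).
#'
#' @param input List of [lsp()] objects, character vector of LSP CSV paths,
#'   or list of image matrices.
#' @param config A [pipeline_config()].
#' @param lut Prebuilt `lut`; when `NULL` one is built from `config$grid`.
#' @param classifier Trained [train_cell_classifier()]; when `NULL` one is
#'   trained on synthetic populations of the built-in classes
#'   (200 cells/class, seeded from `config$seed`).
#' @param geom [detector_geometry()] used when `input` contains images.
#' @param sample_id Sample tag for the report.
#' @param verbose Emit per-stage messages.
#' @return A list with `features` (recovered + classified records),
#'   `report` (a `sample_report`) and `config`.
#' @export
run_pipeline <- function(input, config = pipeline_config(), lut = NULL,
                         classifier = NULL, geom = detector_geometry(),
                         sample_id = "sample_1", verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  lsps <- stage("ingest", {
    if (is.character(input)) {
      lapply(input, function(p) resample_lsp(read_lsp(p), config$setup))
    } else if (length(input) && is.matrix(input[[1]])) {
      lapply(input, image_to_lsp, geom = geom, setup = config$setup)
    } else input
  }, verbose)
  if (!length(lsps)) stop("stage 'ingest' failed: no input profiles")
  if (is.null(names(lsps))) names(lsps) <- as.character(seq_along(lsps))
  lut <- stage("look-up table", {
    if (is.null(lut)) build_lut(config$grid, config$setup) else lut
  }, verbose)
  classifier <- stage("train", {
    if (is.null(classifier)) {
      train <- sample_population(
        c(RBC = 200, T = 200, B = 200, M = 200, CTC = 200),
        seed = config$seed)
      train_cell_classifier(train, algorithm = config$algorithm,
                            seed = config$seed)
    } else classifier
  }, verbose)
  features <- stage("inversion", {
    fx <- invert_population(lsps, lut, setup = config$setup,
                            top_k = config$top_k)
    fx$sample_id <- sample_id
    fx
  }, verbose)
  features <- stage("classification",
                    predict(classifier, features), verbose)
  report <- stage("enumeration",
                  enumerate_sample(features, sample_id), verbose)
  list(features = features, report = report, config = config)
}
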