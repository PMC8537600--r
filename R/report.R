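# Per-sample enumeration of classified cells and multi-sample aggregation.

#' Enumerate cell types in one sample
#'
#' Counts each of the six classes and converts to percentages of the sample
#' total; percentages sum to 100 up to rounding.
#'
#' @param records Labelled feature records, or any data frame with a
#'   `label` column.
#' @param sample_id Optional sample identifier; if given and `records` has
#'   a `sample_id` column, the records are filtered to that sample.
#' @return An object of class `sample_report`: list with `sample_id`,
#'   named `counts`, named `percentages` and `total`.
#' @examples
#' counts <- table3_counts()
#' enumerate_sample(counts_to_records(counts, 1), sample_id = "1")
#' @export
enumerate_sample <- function(records, sample_id = NULL) {
  if (!is.null(sample_id) && "sample_id" %in% names(records))
    records <- records[records$sample_id == sample_id, , drop = FALSE]
  if (is.null(sample_id) && "sample_id" %in% names(records)) {
    ids <- unique(as.character(records$sample_id))
    if (length(ids) == 1L) sample_id <- ids
  }
  if (!"label" %in% names(records) || anyNA(records$label))
    stop("all records must be labelled before enumeration")
  if (nrow(records) == 0L)
    stop("no cells to enumerate",
         if (!is.null(sample_id)) paste0(" for sample '", sample_id, "'"))
  lab <- factor(as.character(records$label), levels = CELL_CLASSES)
  if (anyNA(lab))
    stop("labels outside the six known classes: ",
         paste(setdiff(unique(records$label), CELL_CLASSES), collapse = ", "))
  counts <- table(lab)
  total <- sum(counts)
  structure(list(sample_id = if (is.null(sample_id)) NA_character_
                             else as.character(sample_id),
                 counts = setNames(as.integer(counts), CELL_CLASSES),
                 percentages = setNames(100 * as.numeric(counts) / total,
                                        CELL_CLASSES),
                 total = as.integer(total)),
            class = "sample_report")
}

#' @export
print.sample_report <- function(x, ...) {
  cat("<sample_report>", x$sample_id, "-", x$total, "cells\n")
  print(round(x$percentages, 2))
  invisible(x)
}

#' Enumerate every sample in a labelled feature table
#'
#' @param records Labelled records with a `sample_id` column.
#' @return Named list of [enumerate_sample()] reports.
#' @export
enumerate_samples <- function(records) {
  ids <- unique(as.character(records$sample_id))
  setNames(lapply(ids, function(s) enumerate_sample(records, s)), ids)
}

#' Aggregate per-sample percentages over a sample set
#'
#' The aggregate per class is the unweighted mean of the per-sample
#' percentages (not the pooled-count ratio), so every sample contributes
#' equally regardless of its cell count.
#'
#' @param reports A list of `sample_report` objects (e.g. from
#'   [enumerate_samples()]).
#' @param sample_ids Which samples to aggregate; default all.
#' @return Named numeric vector of mean percentages per class.
#' @export
aggregate_reports <- function(reports, sample_ids = NULL) {
  ids <- vapply(reports, `[[`, character(1), "sample_id")
  if (is.null(sample_ids)) sample_ids <- ids
  missing_ids <- setdiff(as.character(sample_ids), ids)
  if (length(missing_ids))
    stop("unknown sample id(s): ", paste(missing_ids, collapse = ", "))
  sel <- reports[match(as.character(sample_ids), ids)]
  pc <- vapply(sel, `[[`, numeric(length(CELL_CLASSES)), "percentages")
  rowMeans(pc)
}

#' Serialize sample reports to JSON or CSV
#'
#' @param reports List of `sample_report` objects.
#' @param path Output file; extension `.json` or `.csv` selects the format.
#' @param aggregate_ids Optional sample ids whose aggregate percentages are
#'   included (JSON only).
#' @return `path`, invisibly.
#' @export
write_report <- function(reports, path, aggregate_ids = NULL) {
  if (inherits(reports, "sample_report")) reports <- list(reports)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    body <- list(
      samples = lapply(unname(reports), function(r)
        list(sample_id = r$sample_id, total = r$total,
             counts = as.list(r$counts),
             percentages = as.list(round(r$percentages, 4)))))
    if (!is.null(aggregate_ids))
      body$aggregate <- list(
        sample_ids = as.character(aggregate_ids),
        percentages = as.list(round(
          aggregate_reports(reports, aggregate_ids), 4)))
    jsonlite::write_json(body, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    rows <- do.call(rbind, lapply(reports, function(r)
      data.frame(sample_id = r$sample_id, class = CELL_CLASSES,
                 count = as.integer(r$counts),
                 percentage = as.numeric(r$percentages))))
    write.csv(rows, path, row.names = FALSE)
  }
  invisible(path)
}

#' Expand a count table into one record per cell
#'
#' Utility to turn per-sample class counts (as in the packaged nine-sample
#' count fixture) into a labelled record table suitable for
#' [enumerate_sample()].
#'
#' @param counts Data frame with columns `class` and one column per sample
#'   (as returned by [table3_counts()]).
#' @param sample Sample number or column name.
#' @return Data frame with `sample_id`, `cell_id`, `label`.
#' @export
counts_to_records <- function(counts, sample) {
  col <- if (is.numeric(sample)) paste0("sample_", sample) else sample
  if (!col %in% names(counts)) stop("no such sample column: ", col)
  lab <- rep(counts$class, counts[[col]])
  if (!length(lab)) stop("sample ", sample, " has zero cells")
  data.frame(sample_id = as.character(sub("^sample_", "", col)),
             cell_id = seq_along(lab), label = lab)
}
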