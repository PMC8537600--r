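# Plain-text interchange formats: two-column LSP CSV and the feature-table
# CSV (sample_id, cell_id, D_um, RI_C, RI_N, NC, label).

#' Read / write a light-scattering profile CSV
#'
#' Two columns `angle_deg,intensity`, header required, '.' decimal.
#'
#' @param path File path.
#' @return `read_lsp` returns an [lsp()]; `write_lsp` returns `path`
#'   invisibly.
#' @export
read_lsp <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("angle_deg", "intensity") %in% names(tab)))
    stop(path, ": expected header 'angle_deg,intensity'")
  lsp(tab$angle_deg, tab$intensity, normalized = FALSE)
}

#' @rdname read_lsp
#' @param x An [lsp()].
#' @export
write_lsp <- function(x, path) {
  stopifnot(inherits(x, "lsp"))
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

# external column name mapping for feature tables
FEATURE_CSV_MAP <- c(sample_id = "sample_id", cell_id = "cell_id",
                     diameter_um = "D_um", ri_cytosol = "RI_C",
                     ri_nucleus = "RI_N", nc_ratio = "NC", label = "label")

#' Read / write a biophysical feature table CSV
#'
#' Columns `sample_id,cell_id,D_um,RI_C,RI_N,NC,label`; `label` may be
#' empty (unlabelled) and `RI_N` may be empty for anucleate cells.
#'
#' @param path File path.
#' @return `read_features` returns a data frame in the package's internal
#'   column naming; `write_features` returns `path` invisibly.
#' @export
read_features <- function(path) {
  # read everything as character: class labels like "T" must not be
  # mistaken for logicals by type sniffing
  tab <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  miss <- setdiff(unname(FEATURE_CSV_MAP[-7]), names(tab))
  if (length(miss))
    stop(path, ": missing column(s) ", paste(miss, collapse = ", "))
  out <- data.frame(
    sample_id = as.character(tab$sample_id),
    cell_id = utils::type.convert(tab$cell_id, as.is = TRUE),
    diameter_um = as.numeric(tab$D_um),
    ri_cytosol = as.numeric(tab$RI_C),
    ri_nucleus = suppressWarnings(as.numeric(tab$RI_N)),
    nc_ratio = as.numeric(tab$NC))
  out$label <- if ("label" %in% names(tab)) {
    lab <- as.character(tab$label)
    lab[!nzchar(lab) | is.na(lab)] <- NA_character_
    lab
  } else NA_character_
  out
}

#' @rdname read_features
#' @param records Feature records (internal naming).
#' @export
write_features <- function(records, path) {
  out <- data.frame(sample_id = records$sample_id,
                    cell_id = records$cell_id,
                    D_um = records$diameter_um,
                    RI_C = records$ri_cytosol,
                    RI_N = records$ri_nucleus,
                    NC = records$nc_ratio,
                    label = if ("label" %in% names(records))
                      as.character(records$label) else "")
  out$label[is.na(out$label)] <- ""
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Validate an input file against its schema
#'
#' Checks column structure and per-row invariants (angle monotonicity and
#' non-negative intensities for profiles; feature ranges for feature
#' tables) and reports line-numbered diagnostics.  Never modifies the
#' input.
#'
#' @param path File path.
#' @param kind `"lsp"` or `"features"`.
#' @return A list with `ok` (logical) and `issues`, a data frame with
#'   `line` (1-based file line, header = line 1) and `message`.
#' @export
validate_inputs <- function(path, kind = c("lsp", "features")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  issues <- data.frame(line = integer(), message = character())
  note <- function(line, msg)
    issues <<- rbind(issues, data.frame(line = line, message = msg))
  tab <- tryCatch(read.csv(path, stringsAsFactors = FALSE,
                           colClasses = "character"),
                  error = function(e) e)
  if (inherits(tab, "error")) {
    note(1L, paste("unreadable CSV:", conditionMessage(tab)))
    return(list(ok = FALSE, issues = issues))
  }
  num <- function(x) suppressWarnings(as.numeric(x))
  for (col in intersect(names(tab), c("angle_deg", "intensity", "D_um",
                                      "RI_C", "RI_N", "NC")))
    tab[[col]] <- num(tab[[col]])
  if (kind == "lsp") {
    if (!all(c("angle_deg", "intensity") %in% names(tab))) {
      note(1L, "header must contain angle_deg and intensity")
    } else {
      for (i in seq_len(nrow(tab))) {
        if (!is.finite(tab$angle_deg[i]))
          note(i + 1L, "angle_deg is not a finite number")
        if (!is.finite(tab$intensity[i]) || tab$intensity[i] < 0)
          note(i + 1L, "intensity must be finite and >= 0")
        if (i > 1 && is.finite(tab$angle_deg[i]) &&
            is.finite(tab$angle_deg[i - 1]) &&
            tab$angle_deg[i] <= tab$angle_deg[i - 1])
          note(i + 1L, "angle_deg must be strictly increasing")
      }
    }
  } else {
    need <- c("D_um", "RI_C", "RI_N", "NC")
    if (!all(need %in% names(tab))) {
      note(1L, paste("header must contain",
                     paste(need, collapse = ", ")))
    } else {
      ri_ok <- function(x) is.na(x) | (is.finite(x) & x >= 1.30 & x <= 1.60)
      for (i in seq_len(nrow(tab))) {
        if (!is.finite(tab$D_um[i]) || tab$D_um[i] <= 0)
          note(i + 1L, "D_um must be > 0")
        if (!ri_ok(suppressWarnings(as.numeric(tab$RI_C[i]))) ||
            is.na(tab$RI_C[i]))
          note(i + 1L, "RI_C must lie in [1.30, 1.60]")
        if (!ri_ok(suppressWarnings(as.numeric(tab$RI_N[i]))))
          note(i + 1L, "RI_N must lie in [1.30, 1.60] or be empty")
        if (!is.finite(tab$NC[i]) || tab$NC[i] <= 0 || tab$NC[i] > 1)
          note(i + 1L, "NC must lie in (0, 1]")
        if ("label" %in% names(tab) && !is.na(tab$label[i]) &&
            nzchar(tab$label[i]) && !tab$label[i] %in% CELL_CLASSES)
          note(i + 1L, paste0("unknown label '", tab$label[i], "'"))
      }
    }
  }
  list(ok = nrow(issues) == 0L, issues = issues)
}
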