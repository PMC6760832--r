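#' Concentration design
#'
#' Per-sample analyte concentrations for a calibration or test set, with an
#' optional matrix of coded factor levels (values in -2, -1, +1, +2 for a
#' 4-level design). All design concentrations must be strictly positive, and
#' when coded levels are present each code must map to exactly one
#' concentration per analyte.
#'
#' @param concentrations numeric matrix (ug/mL), samples in rows, analytes in
#'   columns.
#' @param analyte_names character vector of analyte labels, one per column.
#'   Defaults to the colnames of `concentrations`.
#' @param sample_ids character vector of sample labels, one per row.
#' @param coded_levels optional integer matrix of the same shape as
#'   `concentrations` with the design codes.
#' @return An object of class `concentration_design`.
#' @export
concentration_design <- function(concentrations, analyte_names = NULL,
                                 sample_ids = NULL, coded_levels = NULL) {
  concentrations <- as.matrix(concentrations)
  storage.mode(concentrations) <- "double"
  if (is.null(analyte_names)) analyte_names <- colnames(concentrations)
  if (is.null(analyte_names)) {
    stop("analyte names are required (none found on the concentration matrix)",
         call. = FALSE)
  }
  analyte_names <- as.character(analyte_names)
  if (is.null(sample_ids)) {
    sample_ids <- rownames(concentrations)
    if (is.null(sample_ids)) sample_ids <- paste0("M", seq_len(nrow(concentrations)))
  }
  sample_ids <- as.character(sample_ids)
  if (nrow(concentrations) != length(sample_ids)) {
    stop("shape error: ", nrow(concentrations), " design rows but ",
         length(sample_ids), " sample ids", call. = FALSE)
  }
  if (ncol(concentrations) != length(analyte_names)) {
    stop("shape error: ", ncol(concentrations), " concentration columns but ",
         length(analyte_names), " analyte names", call. = FALSE)
  }
  if (anyNA(concentrations) || any(concentrations <= 0)) {
    stop("validation error: all design concentrations must be > 0", call. = FALSE)
  }
  if (!is.null(coded_levels)) {
    coded_levels <- as.matrix(coded_levels)
    if (!all(dim(coded_levels) == dim(concentrations))) {
      stop("shape error: coded_levels must match the concentration matrix", call. = FALSE)
    }
    if (!all(coded_levels %in% c(-2L, -1L, 1L, 2L))) {
      stop("validation error: coded levels must be in {-2, -1, +1, +2}", call. = FALSE)
    }
    for (j in seq_along(analyte_names)) {
      per_code <- tapply(concentrations[, j], coded_levels[, j],
                         function(v) length(unique(v)))
      if (any(per_code != 1)) {
        stop("validation error: analyte '", analyte_names[j],
             "' maps one code to several concentrations", call. = FALSE)
      }
    }
  }
  rownames(concentrations) <- sample_ids
  colnames(concentrations) <- analyte_names
  structure(
    list(analyte_names = analyte_names,
         concentrations = concentrations,
         coded_levels = coded_levels,
         sample_ids = sample_ids),
    class = "concentration_design"
  )
}

#' @export
print.concentration_design <- function(x, ...) {
  cat("concentration_design: ", length(x$sample_ids), " mixture(s) x ",
      length(x$analyte_names), " analyte(s) [",
      paste(x$analyte_names, collapse = ", "), "]\n", sep = "")
  print(x$concentrations)
  invisible(x)
}

#' Extract one analyte's concentrations from a design
#'
#' @param design a [concentration_design].
#' @param analyte analyte name.
#' @return Named numeric vector of concentrations (ug/mL).
#' @export
design_response <- function(design, analyte) {
  stopifnot(inherits(design, "concentration_design"))
  if (!analyte %in% design$analyte_names) {
    stop("analyte '", analyte, "' not present in the design (have: ",
         paste(design$analyte_names, collapse = ", "), ")", call. = FALSE)
  }
  design$concentrations[, analyte]
}

#' Read a concentration design from CSV
#'
#' Expects a header `sample_id,<analyte1>,<analyte2>,...` followed by one
#' numeric row per mixture.
#'
#' @param path path to a design CSV file.
#' @return A [concentration_design] (without coded levels).
#' @export
read_design_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (ncol(raw) < 2 || names(raw)[1] != "sample_id") {
    stop("parse error: header must be 'sample_id' followed by analyte names",
         call. = FALSE)
  }
  conc <- matrix(NA_real_, nrow = nrow(raw), ncol = ncol(raw) - 1)
  for (j in 2:ncol(raw)) {
    v <- suppressWarnings(as.numeric(raw[[j]]))
    bad <- which(is.na(v))
    if (length(bad) > 0) {
      stop(sprintf("parse error: non-numeric value '%s' at data row %d, column '%s'",
                   raw[[j]][bad[1]], bad[1], names(raw)[j]), call. = FALSE)
    }
    conc[, j - 1] <- v
  }
  concentration_design(conc, analyte_names = names(raw)[-1],
                       sample_ids = raw[[1]])
}

#' Write a concentration design to CSV
#'
#' @param design a [concentration_design].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_design_csv <- function(design, path) {
  stopifnot(inherits(design, "concentration_design"))
  df <- data.frame(sample_id = design$sample_ids,
                   design$concentrations,
                   check.names = FALSE, row.names = NULL)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
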