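#' Absorbance spectra on a uniform wavelength grid
#'
#' Container for a block of UV-visible absorbance spectra: one row per
#' sample, one column per wavelength, together with the wavelength axis in
#' nanometres. The grid must be strictly increasing and uniformly spaced
#' (within 1e-9 nm), and all absorbances must be finite.
#'
#' @param absorbance numeric matrix of absorbances (AU), samples in rows,
#'   wavelengths in columns.
#' @param wavelengths_nm numeric vector of wavelengths (nm), one per column.
#' @param sample_ids character vector of sample labels, one per row. Defaults
#'   to the rownames of `absorbance`, or `S1, S2, ...` when absent.
#' @return An object of class `spectra_matrix`: a list with elements
#'   `wavelengths_nm`, `absorbance` and `sample_ids`.
#' @export
spectra_matrix <- function(absorbance, wavelengths_nm, sample_ids = NULL) {
  absorbance <- as.matrix(absorbance)
  storage.mode(absorbance) <- "double"
  wavelengths_nm <- as.numeric(wavelengths_nm)
  if (is.null(sample_ids)) {
    sample_ids <- rownames(absorbance)
    if (is.null(sample_ids)) {
      sample_ids <- if (nrow(absorbance) > 0) paste0("S", seq_len(nrow(absorbance))) else character(0)
    }
  }
  sample_ids <- as.character(sample_ids)
  if (nrow(absorbance) != length(sample_ids)) {
    stop("shape error: absorbance has ", nrow(absorbance), " rows but there are ",
         length(sample_ids), " sample ids", call. = FALSE)
  }
  if (ncol(absorbance) != length(wavelengths_nm)) {
    stop("shape error: absorbance has ", ncol(absorbance), " columns but there are ",
         length(wavelengths_nm), " wavelengths", call. = FALSE)
  }
  if (anyNA(wavelengths_nm)) stop("grid error: wavelengths contain missing values", call. = FALSE)
  if (length(wavelengths_nm) > 1) {
    d <- diff(wavelengths_nm)
    if (any(d <= 0)) {
      stop("grid error: wavelengths must be strictly increasing", call. = FALSE)
    }
    if (length(d) > 1 && (max(d) - min(d)) > 1e-9) {
      stop("grid error: wavelength spacing is not uniform (spread ",
           format(max(d) - min(d)), " nm)", call. = FALSE)
    }
  }
  if (length(absorbance) > 0 && !all(is.finite(absorbance))) {
    stop("absorbance values must all be finite", call. = FALSE)
  }
  rownames(absorbance) <- sample_ids
  colnames(absorbance) <- NULL
  structure(
    list(wavelengths_nm = wavelengths_nm,
         absorbance = absorbance,
         sample_ids = sample_ids),
    class = "spectra_matrix"
  )
}

#' @export
print.spectra_matrix <- function(x, ...) {
  nw <- length(x$wavelengths_nm)
  cat("spectra_matrix: ", length(x$sample_ids), " sample(s) x ", nw, " wavelength(s)\n", sep = "")
  if (nw > 0) {
    cat("  grid: ", x$wavelengths_nm[1], "-", x$wavelengths_nm[nw], " nm",
        if (nw > 1) paste0(", step ", signif(x$wavelengths_nm[2] - x$wavelengths_nm[1], 6), " nm"),
        "\n", sep = "")
  }
  invisible(x)
}

## Accept either a spectra_matrix or a bare numeric matrix in modeling code.
as_absorbance <- function(x) {
  if (inherits(x, "spectra_matrix")) return(x$absorbance)
  if (is.matrix(x)) return(x)
  if (is.numeric(x)) return(matrix(x, nrow = 1))
  stop("expected a spectra_matrix or a numeric matrix", call. = FALSE)
}

#' Read spectra from CSV
#'
#' Reads a comma-separated file whose first column is `wavelength_nm` and
#' whose remaining columns hold one spectrum each (column header = sample
#' id). The column order of samples is preserved.
#'
#' @param path path to a spectra CSV file.
#' @return A [spectra_matrix].
#' @export
read_spectra_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (ncol(raw) < 1 || names(raw)[1] != "wavelength_nm") {
    stop("parse error: first column header must be 'wavelength_nm'", call. = FALSE)
  }
  num <- vector("list", ncol(raw))
  for (j in seq_along(raw)) {
    v <- suppressWarnings(as.numeric(raw[[j]]))
    bad <- which(is.na(v))
    if (length(bad) > 0) {
      stop(sprintf("parse error: non-numeric value '%s' at data row %d, column '%s'",
                   raw[[j]][bad[1]], bad[1], names(raw)[j]), call. = FALSE)
    }
    num[[j]] <- v
  }
  wl <- num[[1]]
  if (ncol(raw) > 1) {
    A <- t(matrix(unlist(num[-1]), nrow = length(wl),
                  ncol = ncol(raw) - 1))
  } else {
    A <- matrix(numeric(0), nrow = 0, ncol = length(wl))
  }
  spectra_matrix(A, wl, sample_ids = names(raw)[-1])
}

#' Write spectra to CSV
#'
#' Inverse of [read_spectra_csv()]. Values are written with 12 significant
#' digits so that a write/read round trip is lossless well below 1e-9 AU.
#'
#' @param spectra a [spectra_matrix].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_spectra_csv <- function(spectra, path) {
  stopifnot(inherits(spectra, "spectra_matrix"))
  con <- tryCatch(file(path, open = "wt"),
                  error = function(e) stop("I/O error: cannot open '", path,
                                           "' for writing", call. = FALSE),
                  warning = function(w) stop("I/O error: cannot open '", path,
                                             "' for writing", call. = FALSE))
  on.exit(close(con))
  fmt <- function(x) sprintf("%.12g", x)
  writeLines(paste(c("wavelength_nm", spectra$sample_ids), collapse = ","), con)
  for (i in seq_along(spectra$wavelengths_nm)) {
    writeLines(paste(c(fmt(spectra$wavelengths_nm[i]),
                       fmt(spectra$absorbance[, i])), collapse = ","), con)
  }
  invisible(path)
}

#' Check a spectra grid against an expected uniform grid
#'
#' Verifies that the wavelength axis equals `seq(start_nm, end_nm, step_nm)`
#' and returns the number of grid points. The conventional working range for
#' this system, 200-350 nm at 1 nm, has 151 points.
#'
#' @param spectra a [spectra_matrix].
#' @param start_nm,end_nm,step_nm expected grid start, end and spacing (nm).
#' @return Integer number of grid points.
#' @export
validate_grid <- function(spectra, start_nm, end_nm, step_nm) {
  stopifnot(inherits(spectra, "spectra_matrix"))
  expected <- seq(start_nm, end_nm, by = step_nm)
  wl <- spectra$wavelengths_nm
  if (length(wl) != length(expected)) {
    stop("grid error: expected ", length(expected), " wavelengths, found ",
         length(wl), call. = FALSE)
  }
  off <- which(abs(wl - expected) > 1e-9)
  if (length(off) > 0) {
    stop(sprintf("grid error: wavelength %g nm does not match expected %g nm",
                 wl[off[1]], expected[off[1]]), call. = FALSE)
  }
  length(expected)
}
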