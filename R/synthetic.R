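#' Gaussian band model of a pure UV absorber
#'
#' A pure-component UV spectrum modeled as a sum of Gaussian bands in
#' wavelength. One band centre is designated the lambda-max and must be the
#' global argmax of the modeled spectrum on the working grid; this is
#' checked at construction.
#'
#' @param name component (analyte) label.
#' @param centers_nm numeric vector of band centres (nm).
#' @param widths_nm numeric vector of band standard deviations (nm), > 0.
#' @param peak_absorptivities numeric vector of band heights
#'   (AU mL / ug at unit concentration), >= 0.
#' @param lambda_max_nm designated absorption maximum (nm); defaults to the
#'   centre of the tallest band.
#' @param check_grid wavelength grid (nm) on which the lambda-max invariant
#'   is verified; defaults to 200-350 nm at 1 nm.
#' @return An object of class `component_band_model`.
#' @export
component_band_model <- function(name, centers_nm, widths_nm, peak_absorptivities,
                                 lambda_max_nm = centers_nm[which.max(peak_absorptivities)],
                                 check_grid = seq(200, 350, by = 1)) {
  stopifnot(length(centers_nm) == length(widths_nm),
            length(centers_nm) == length(peak_absorptivities))
  if (any(widths_nm <= 0)) stop("band widths must be > 0", call. = FALSE)
  if (any(peak_absorptivities < 0)) stop("peak absorptivities must be >= 0", call. = FALSE)
  obj <- structure(
    list(name = as.character(name),
         bands = data.frame(center_nm = as.numeric(centers_nm),
                            width_nm = as.numeric(widths_nm),
                            peak_absorptivity = as.numeric(peak_absorptivities)),
         lambda_max_nm = as.numeric(lambda_max_nm)),
    class = "component_band_model"
  )
  if (length(check_grid) > 0) {
    s <- pure_spectrum(obj, check_grid)
    at_max <- check_grid[which.max(s)]
    step <- if (length(check_grid) > 1) min(diff(check_grid)) else 1
    if (abs(at_max - lambda_max_nm) > step / 2 + 1e-9) {
      stop("lambda-max invariant violated for '", name, "': spectrum peaks at ",
           at_max, " nm, not ", lambda_max_nm, " nm", call. = FALSE)
    }
  }
  obj
}

#' @export
print.component_band_model <- function(x, ...) {
  cat("component_band_model '", x$name, "': ", nrow(x$bands),
      " band(s), lambda-max ", x$lambda_max_nm, " nm\n", sep = "")
  print(x$bands)
  invisible(x)
}

#' Evaluate a pure-component spectrum at unit concentration
#'
#' @param component a [component_band_model].
#' @param wavelengths_nm wavelengths (nm) at which to evaluate.
#' @return Numeric vector of absorptivities (AU mL / ug).
#' @export
pure_spectrum <- function(component, wavelengths_nm) {
  stopifnot(inherits(component, "component_band_model"))
  b <- component$bands
  s <- numeric(length(wavelengths_nm))
  for (i in seq_len(nrow(b))) {
    s <- s + b$peak_absorptivity[i] *
      exp(-0.5 * ((wavelengths_nm - b$center_nm[i]) / b$width_nm[i])^2)
  }
  s
}

#' Default three-component system (drug + two impurities)
#'
#' Band models for the pyridostigmine bromide (PR) system: PR peaks at
#' 270 nm, impurity A (IMPA) at 262 nm and impurity B (IMPB) at 329 nm on
#' the 200-350 nm working grid. PR and IMPA overlap strongly (their band
#' maxima sit 8 nm apart), which is the feature that makes univariate
#' quantification fail and multivariate calibration necessary. Band shapes
#' and absolute absorptivities are the generator's own stand-ins: only the
#' lambda-max positions and the overlap structure emulate the real system.
#' Absorptivities are scaled so that 10 ug/mL of a pure component gives a
#' peak absorbance of roughly 0.2-0.6 AU, inside the Beer-Lambert validity
#' range.
#'
#' @return Named list of three [component_band_model] objects
#'   (`PR`, `IMPA`, `IMPB`).
#' @export
default_components <- function() {
  list(
    PR = component_band_model(
      "PR",
      centers_nm = c(270, 215),
      widths_nm = c(12, 18),
      peak_absorptivities = c(0.040, 0.025),
      lambda_max_nm = 270
    ),
    IMPA = component_band_model(
      "IMPA",
      centers_nm = c(262, 212),
      widths_nm = c(13, 16),
      peak_absorptivities = c(0.055, 0.030),
      lambda_max_nm = 262
    ),
    IMPB = component_band_model(
      "IMPB",
      centers_nm = c(329, 250),
      widths_nm = c(14, 20),
      peak_absorptivities = c(0.035, 0.020),
      lambda_max_nm = 329
    )
  )
}

#' Additive Gaussian measurement-noise model
#'
#' @param sigma_au standard deviation of the additive absorbance noise (AU);
#'   the default 0.002 AU is a realistic noise floor for a double-beam UV
#'   spectrophotometer.
#' @param seed integer seed making noisy generation reproducible.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(sigma_au = 0.002, seed = 1L) {
  sigma_au <- as.numeric(sigma_au)
  if (length(sigma_au) != 1 || is.na(sigma_au) || sigma_au < 0) {
    stop("sigma_au must be a single value >= 0", call. = FALSE)
  }
  structure(list(sigma_au = sigma_au, seed = as.integer(seed)),
            class = "noise_model")
}

## Table of training mixtures: 4-level 3-factor design, 16 rows, with the
## coded levels -2/-1/+1/+2 mapping to (20,30,50,60) for PR, (0.4,0.6,1,1.2)
## for IMPA and (0.5,0.7,1.1,1.3) for IMPB.
calibration_rows <- function() {
  list(
    PR = c(20, 20, 30, 30, 60, 30, 20, 50, 50, 30, 50, 20, 60, 60, 50, 60),
    IMPA = c(0.4, 0.6, 0.6, 1.2, 0.6, 0.4, 1, 1, 0.6, 1, 0.4, 1.2, 1.2, 1, 1.2, 0.4),
    IMPB = c(0.5, 0.7, 1.3, 0.7, 0.5, 1.1, 1.1, 0.7, 1.1, 0.5, 1.3, 1.3, 1.1, 1.3, 0.5, 0.7)
  )
}

code_levels <- function(x, levels) {
  codes <- c(-2L, -1L, 1L, 2L)
  out <- codes[match(x, levels)]
  stopifnot(!anyNA(out))
  out
}

#' The 16-mixture calibration design
#'
#' The 4-level 3-factor training design for PR with impurities A and B:
#' each analyte takes four coded concentration levels (-2, -1, +1, +2) and
#' each level occurs in exactly four of the 16 mixtures. Concentrations are
#' in ug/mL; impurity levels are roughly 1-3 percent of the drug level.
#'
#' @return A [concentration_design] with 16 rows, analytes `PR`, `IMPA`,
#'   `IMPB`, and coded levels attached.
#' @export
build_calibration_design <- function() {
  r <- calibration_rows()
  conc <- cbind(PR = r$PR, IMPA = r$IMPA, IMPB = r$IMPB)
  codes <- cbind(
    PR = code_levels(r$PR, c(20, 30, 50, 60)),
    IMPA = code_levels(r$IMPA, c(0.4, 0.6, 1, 1.2)),
    IMPB = code_levels(r$IMPB, c(0.5, 0.7, 1.1, 1.3))
  )
  concentration_design(conc,
                       sample_ids = paste0("T", seq_len(16)),
                       coded_levels = codes)
}

#' The 9-mixture independent test design
#'
#' Nine validation mixtures lying inside the concentration space of the
#' calibration design: five repeat training compositions and four new
#' compositions off the coded grid.
#'
#' @return A [concentration_design] with 9 rows and analytes `PR`, `IMPA`,
#'   `IMPB` (no coded levels: four rows sit off the 4-level grid).
#' @export
build_test_design <- function() {
  conc <- cbind(
    PR = c(20, 50, 50, 20, 30, 45, 25, 30, 25),
    IMPA = c(0.6, 1, 0.6, 0.4, 1, 0.5, 0.7, 0.8, 0.5),
    IMPB = c(0.7, 0.7, 1.1, 0.5, 0.5, 0.8, 0.5, 0.5, 0.6)
  )
  concentration_design(conc, sample_ids = paste0("V", seq_len(9)))
}

#' Generate Beer-Lambert mixture spectra
#'
#' Builds absorbance spectra for every mixture in a design as the
#' concentration-weighted sum of the pure-component spectra (Beer-Lambert
#' additivity) plus optional additive Gaussian noise. Generation is
#' bit-reproducible for a given noise seed and leaves the caller's RNG
#' state untouched.
#'
#' @param design a [concentration_design].
#' @param components list of [component_band_model] objects, one per design
#'   analyte, in design-column order (names must match).
#' @param wavelengths_nm working wavelength grid (nm); default 200-350 at 1 nm.
#' @param noise a [noise_model]; use `noise_model(0)` for noiseless spectra.
#' @return A [spectra_matrix] with one row per design mixture.
#' @export
generate_mixture_spectra <- function(design,
                                     components = default_components(),
                                     wavelengths_nm = seq(200, 350, by = 1),
                                     noise = noise_model()) {
  stopifnot(inherits(design, "concentration_design"),
            inherits(noise, "noise_model"))
  comp_names <- vapply(components, function(cc) cc$name, character(1))
  if (length(components) != length(design$analyte_names) ||
      !identical(unname(comp_names), unname(design$analyte_names))) {
    stop("configuration error: design analytes (",
         paste(design$analyte_names, collapse = ", "),
         ") do not match component names (",
         paste(comp_names, collapse = ", "), ")", call. = FALSE)
  }
  S <- t(vapply(components, pure_spectrum, numeric(length(wavelengths_nm)),
                wavelengths_nm = wavelengths_nm))
  A <- design$concentrations %*% S
  if (noise$sigma_au > 0) {
    had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old_seed <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had_seed) assign(".Random.seed", old_seed, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(noise$seed)
    A <- A + matrix(stats::rnorm(length(A), mean = 0, sd = noise$sigma_au),
                    nrow = nrow(A))
  }
  spectra_matrix(A, wavelengths_nm, sample_ids = design$sample_ids)
}
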