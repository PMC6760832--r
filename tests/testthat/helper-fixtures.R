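# Shared fixtures: small synthetic data sets built in code at test time.

# Noiseless Beer-Lambert spectra for the standard designs on the 151-point grid.
noiseless_training <- function() {
  generate_mixture_spectra(build_calibration_design(), noise = noise_model(0))
}
noiseless_test <- function() {
  generate_mixture_spectra(build_test_design(), noise = noise_model(0))
}

# A tiny generic regression fixture (n samples, p features), reproducible.
tiny_xy <- function(n = 8, p = 3, seed = 42) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  beta <- rnorm(p)
  y <- drop(X %*% beta) + rnorm(n, sd = 0.1)
  list(X = X, y = y)
}

centered <- function(X, y) {
  list(X = sweep(X, 2, colMeans(X), `-`), y = y - mean(y),
       mx = colMeans(X), my = mean(y))
}

expect_write_read_roundtrip <- function(sp, tol = 1e-9) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  write_spectra_csv(sp, path)
  sp2 <- read_spectra_csv(path)
  expect_equal(sp2$wavelengths_nm, sp$wavelengths_nm, tolerance = 1e-12)
  expect_identical(sp2$sample_ids, sp$sample_ids)
  expect_lt(max(abs(sp2$absorbance - sp$absorbance), 0), tol)
  invisible(sp2)
}
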