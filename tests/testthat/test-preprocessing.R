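test_that("centering is fit on training data and applied frozen", {
  xy <- tiny_xy(n = 6, p = 4)
  cm <- fit_center(xy$X, xy$y)
  cen <- apply_center(cm, xy$X, xy$y)
  expect_lt(max(abs(colMeans(cen$X))), 1e-12)
  expect_lt(abs(mean(cen$y)), 1e-12)
  # brute-force subtraction oracle on new data
  Xnew <- matrix(rnorm(8), 2, 4)
  expect_equal(apply_center(cm, Xnew),
               Xnew - rep(colMeans(xy$X), each = 2), tolerance = 1e-12)
  # single new sample is fine; means are never re-estimated
  expect_identical(dim(apply_center(cm, Xnew[1, , drop = FALSE])), c(1L, 4L))
  # round trip
  expect_equal(sweep(apply_center(cm, xy$X), 2, cm$column_means, `+`), xy$X,
               tolerance = 1e-12)
  # identical rows centre to zero
  Xsame <- matrix(1, 3, 4)
  expect_true(all(apply_center(fit_center(Xsame), Xsame) == 0))
  expect_error(fit_center(Xsame[1, , drop = FALSE]), "degenerate centering")
  expect_error(apply_center(cm, Xnew[, 1:3]), "shape error")
})

test_that("finite-difference derivative maps ramps and constants correctly", {
  wl <- seq(200, 210, by = 1)
  flat <- spectra_matrix(matrix(3, 1, 11), wl, "flat")
  ramp <- spectra_matrix(matrix(2 * wl, 1, 11, byrow = TRUE), wl, "ramp")
  d_flat <- first_derivative(flat)
  d_ramp <- first_derivative(ramp)
  expect_true(all(d_flat$absorbance == 0))
  expect_equal(unname(d_ramp$absorbance[1, ]), rep(2, 10), tolerance = 1e-12)
  # grid shortens by one onto midpoints
  expect_length(d_flat$wavelengths_nm, 10)
  expect_equal(d_flat$wavelengths_nm[1], 200.5)
})

test_that("Savitzky-Golay derivative matches the analytic derivative of a cubic", {
  wl <- seq(200, 240, by = 1)
  f <- function(x) 1e-4 * (x - 220)^3 - 0.02 * (x - 220) + 0.5
  fp <- function(x) 3e-4 * (x - 220)^2 - 0.02
  sp <- spectra_matrix(matrix(f(wl), 1, byrow = TRUE), wl, "cubic")
  d <- first_derivative(sp, method = "savitzky_golay", window = 7, polyorder = 3)
  interior <- 4:(length(wl) - 3)
  expect_lt(max(abs(d$absorbance[1, interior] - fp(wl[interior]))), 1e-8)
  expect_length(d$wavelengths_nm, length(wl))
  expect_error(first_derivative(sp, method = "savitzky_golay", window = 6),
               "odd")
  expect_error(first_derivative(sp, method = "savitzky_golay", window = 7,
                                polyorder = 7), "polyorder")
  expect_error(first_derivative(sp, method = "savitzky_golay", window = 43),
               "parameter error")
})

test_that("derivative operators are linear", {
  wl <- seq(200, 230, by = 1)
  set.seed(3)
  A <- matrix(runif(2 * 31), 2, 31)
  B <- matrix(runif(2 * 31), 2, 31)
  for (m in c("finite_difference", "savitzky_golay")) {
    da <- first_derivative(spectra_matrix(A, wl), method = m)$absorbance
    db <- first_derivative(spectra_matrix(B, wl), method = m)$absorbance
    dab <- first_derivative(spectra_matrix(2 * A - 3 * B, wl), method = m)$absorbance
    expect_lt(max(abs(dab - (2 * da - 3 * db))), 1e-10)
  }
})

test_that("OPLS is a no-op when X carries nothing orthogonal to y", {
  set.seed(8)
  y <- rnorm(10); y <- y - mean(y)
  a <- rnorm(6)
  X <- outer(y, a)
  expect_message(filt <- fit_opls(X, y, n_ortho = 1), "stopping early")
  expect_identical(filt$n_ortho, 0L)
  expect_equal(apply_opls(filt, X), X, tolerance = 1e-12)
})

test_that("OPLS removes an exactly constructed orthogonal component", {
  set.seed(9)
  n <- 12; J <- 20
  y <- rnorm(n); y <- y - mean(y)
  a <- rnorm(J)
  t_o <- rnorm(n)
  t_o <- t_o - sum(t_o * y) / sum(y * y) * y     # make t_o orthogonal to y
  p_o <- rnorm(J) + 0.5 * a                      # generic: not parallel to a,
  stopifnot(abs(sum(p_o * a)) > 1e-3)            # but not orthogonal either
  X <- outer(y, a) + outer(t_o, p_o)
  filt <- fit_opls(X, y, n_ortho = 1)
  expect_identical(filt$n_ortho, 1L)
  expect_lt(norm(filt$X_filtered - outer(y, a), "F") / norm(outer(y, a), "F"),
            1e-8)
})

test_that("OPLS training scores are orthogonal to y and weights unit-norm", {
  sp <- generate_mixture_spectra(build_calibration_design(),
                                 noise = noise_model(0.002, seed = 21))
  y <- design_response(build_calibration_design(), "PR")
  cm <- fit_center(sp, y)
  cen <- apply_center(cm, sp, y)
  filt <- fit_opls(cen$X, cen$y, n_ortho = 3)
  expect_identical(filt$n_ortho, 3L)
  for (a in 1:3) {
    t_o <- filt$T_ortho[, a]
    expect_lt(abs(sum(t_o * cen$y)),
              1e-8 * sqrt(sum(t_o^2)) * sqrt(sum(cen$y^2)))
    expect_equal(sum(filt$W_ortho[, a]^2), 1, tolerance = 1e-12)
  }
})

test_that("OPLS application is frozen, idempotent and norm-non-increasing", {
  tr <- build_calibration_design()
  sp <- generate_mixture_spectra(tr, noise = noise_model(0.002, seed = 22))
  spte <- generate_mixture_spectra(build_test_design(),
                                   noise = noise_model(0.002, seed = 23))
  y <- design_response(tr, "PR")
  cm <- fit_center(sp, y)
  cen <- apply_center(cm, sp, y)
  Xte <- apply_center(cm, spte)
  for (k in 1:2) {
    filt <- fit_opls(cen$X, cen$y, n_ortho = k)
    # re-applying to the training matrix reproduces the fit-time residual
    expect_equal(apply_opls(filt, cen$X), filt$X_filtered, tolerance = 1e-10)
    # idempotent on new data
    once <- apply_opls(filt, Xte)
    expect_equal(apply_opls(filt, once), once, tolerance = 1e-10)
    # filtering never inflates the data
    expect_lte(norm(once, "F"), norm(Xte, "F") + 1e-12)
    expect_lte(norm(filt$X_filtered, "F"), norm(cen$X, "F") + 1e-12)
  }
  expect_error(apply_opls(fit_opls(cen$X, cen$y, 1), Xte[, 1:10]), "shape error")
  expect_error(fit_opls(cen$X, rep(0, 16)), "degenerate response")
})

test_that("1-LV PLS after OPLS does not fit worse than 1-LV PLS alone", {
  tr <- build_calibration_design()
  sp <- noiseless_training()
  y <- design_response(tr, "PR")
  cm <- fit_center(sp, y)
  cen <- apply_center(cm, sp, y)
  plain <- fit_pls1(cen$X, cen$y, 1)
  filt <- fit_opls(cen$X, cen$y, n_ortho = 1)
  opls <- fit_pls1(filt$X_filtered, cen$y, 1)
  rmsec_plain <- sqrt(mean((plain$fitted - cen$y)^2))
  rmsec_opls <- sqrt(mean((opls$fitted - cen$y)^2))
  expect_lte(rmsec_opls, rmsec_plain + 1e-12)
})
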