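test_that("rank-1 data is fit exactly with one latent variable", {
  set.seed(1)
  y <- rnorm(9); y <- y - mean(y)
  s <- rnorm(12)
  X <- outer(y, s)
  fit <- fit_pls1(X, y, 1)
  expect_lt(sqrt(sum((fit$fitted - y)^2)), 1e-10)
})

test_that("PLS1 at full LV count equals the least-squares oracle", {
  xy <- tiny_xy(n = 6, p = 4, seed = 12)
  cen <- centered(xy$X, xy$y)
  expect_error(fit_pls1(cen$X, cen$y, 5), "n_lv")  # cap is min(n - 1, p) = 4
  fit <- fit_pls1(cen$X, cen$y, 4)
  Xnew <- matrix(rnorm(20), 5, 4)
  expect_equal(drop(Xnew %*% fit$regression_vector),
               ols_oracle_predict(cen$X, cen$y, Xnew), tolerance = 1e-8)
})

test_that("NIPALS matches an independently coded oracle step for step", {
  set.seed(4)
  X <- matrix(rnorm(12), 4, 3)
  X <- sweep(X, 2, colMeans(X), `-`)
  y <- rnorm(4); y <- y - mean(y)
  fit <- fit_pls1(X, y, 3)
  orc <- nipals_oracle(X, y, 3)
  for (a in 1:3) {
    # weight sign is fixed by w = X'y/|X'y| in both implementations
    expect_equal(fit$W[, a], orc$W[, a], tolerance = 1e-10)
    expect_equal(fit$P[, a], orc$P[, a], tolerance = 1e-10)
    expect_equal(fit$T[, a], orc$T[, a], tolerance = 1e-10)
    expect_equal(fit$q[a], orc$q[a], tolerance = 1e-10)
  }
})

test_that("score vectors are mutually orthogonal and RMSEC never increases with LV", {
  sp <- generate_mixture_spectra(build_calibration_design(),
                                 noise = noise_model(0.002, seed = 31))
  y <- design_response(build_calibration_design(), "PR")
  cm <- fit_center(sp, y)
  cen <- apply_center(cm, sp, y)
  fit <- fit_pls1(cen$X, cen$y, 6)
  G <- crossprod(fit$T)
  offdiag <- abs(G[upper.tri(G)]) / sqrt(diag(G)[row(G)[upper.tri(G)]] *
                                           diag(G)[col(G)[upper.tri(G)]])
  expect_lt(max(offdiag), 1e-8)
  rmsec <- vapply(1:6, function(k) {
    f <- fit_pls1(cen$X, cen$y, k)
    sqrt(mean((f$fitted - cen$y)^2))
  }, numeric(1))
  expect_true(all(diff(rmsec) <= 1e-10))
  # score route and regression-vector route agree
  expect_equal(unname(drop(fit$T %*% fit$q)),
               unname(drop(cen$X %*% fit$regression_vector)),
               tolerance = 1e-10)
})

test_that("prediction centers new data with the stored model", {
  sp <- noiseless_training()
  y <- design_response(build_calibration_design(), "PR")
  cm <- fit_center(sp, y)
  cen <- apply_center(cm, sp, y)
  fit <- fit_pls1(cen$X, cen$y, 3, centering = cm)
  # predicting the training set reproduces the fitted values
  expect_equal(predict(fit, sp), fit$fitted + cm$response_mean, tolerance = 1e-10)
  # a spectrum equal to the stored means predicts the response mean
  at_mean <- matrix(cm$column_means, 1)
  expect_equal(predict(fit, at_mean), cm$response_mean, tolerance = 1e-8)
  expect_error(predict(fit, sp$absorbance[, 1:10]), "shape error")
})

test_that("3-LV PLS recovers all 25 noiseless concentrations to 1e-6", {
  tr <- build_calibration_design(); te <- build_test_design()
  sp <- noiseless_training(); spte <- noiseless_test()
  y <- design_response(tr, "PR")
  cm <- fit_center(sp, y)
  cen <- apply_center(cm, sp, y)
  fit <- fit_pls1(cen$X, cen$y, 3, centering = cm)
  expect_lt(max(abs(predict(fit, sp) - y)), 1e-6)
  expect_lt(max(abs(predict(fit, spte) - design_response(te, "PR"))), 1e-6)
})

test_that("requesting more LVs than the data rank is an error naming the rank", {
  set.seed(5)
  y <- rnorm(8); y <- y - mean(y)
  s1 <- rnorm(10); s2 <- rnorm(10)
  X <- outer(y, s1) + outer(y^2 - mean(y^2), s2)   # rank 2
  expect_error(fit_pls1(X, y, 5), "rank 2")
})

test_that("bootstrap LV selection picks 1 LV on rank-1 data and is seed-stable", {
  set.seed(6)
  y <- rnorm(15, mean = 10)
  s <- abs(rnorm(20))
  X <- outer(y, s)
  b <- bootstrap_select_lv(X, y, max_lv = 4, n_iterations = 50, seed = 2)
  expect_identical(b$chosen_lv, 1L)
  b2 <- bootstrap_select_lv(X, y, max_lv = 4, n_iterations = 50, seed = 2)
  expect_identical(b$mean_rmsep_by_lv, b2$mean_rmsep_by_lv)
  b3 <- bootstrap_select_lv(X, y, max_lv = 4, n_iterations = 50, seed = 3)
  expect_false(identical(b$mean_rmsep_by_lv, b3$mean_rmsep_by_lv))
})

test_that("bootstrap split sizes and feasibility checks follow the 2/3 rule", {
  sp <- noiseless_training()
  y <- design_response(build_calibration_design(), "PR")
  b <- bootstrap_select_lv(sp, y, max_lv = 3, n_iterations = 5, seed = 1)
  expect_identical(b$n_train, 11L)           # ceiling(2 * 16 / 3)
  expect_error(bootstrap_select_lv(sp, y, max_lv = 11, n_iterations = 5, seed = 1),
               "parameter error")
  expect_error(bootstrap_select_lv(sp$absorbance[1:2, ], y[1:2], max_lv = 1,
                                   n_iterations = 5, seed = 1),
               "at least 3 samples")
})
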