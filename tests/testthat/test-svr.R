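test_that("a constant response gives a flat model with bias at that value", {
  X <- matrix(rnorm(10), 5, 2)
  m <- train_linear_svr(X, rep(3.5, 5), epsilon = 0.1, cost = 10)
  expect_equal(svr_weights(m), c(0, 0), tolerance = 1e-12)
  expect_equal(m$bias, 3.5, tolerance = 1e-12)
  expect_length(m$support_indices, 0)
  expect_equal(unname(predict(m, X)), rep(3.5, 5), tolerance = 1e-12)
})

test_that("SMO solution matches the brute-force KKT enumeration oracle", {
  set.seed(17)
  X <- matrix(rnorm(10), 5, 2)
  y <- c(1.8, -0.6, 0.3, 2.4, -1.9)
  for (prm in list(c(0.3, 2), c(0.1, 5), c(0.5, 1))) {
    eps <- prm[1]; C <- prm[2]
    m <- train_linear_svr(X, y, epsilon = eps, cost = C)
    orc <- svr_bruteforce_oracle(X, y, eps, C)
    expect_equal(m$dual_coefficients, orc$beta, tolerance = 1e-6)
    # b is only pinned when a free support vector exists; in general both
    # solutions must lie in the KKT-feasible bias interval
    iv <- svr_bias_interval(orc$beta, X, y, eps, C)
    expect_gte(m$bias, iv[1] - 1e-6)
    expect_lte(m$bias, iv[2] + 1e-6)
    expect_gte(orc$bias, iv[1] - 1e-6)
    expect_lte(orc$bias, iv[2] + 1e-6)
  }
})

test_that("dual solution satisfies its box, balance and KKT conditions", {
  sp <- generate_mixture_spectra(build_calibration_design(),
                                 noise = noise_model(0.02, seed = 44))
  y <- design_response(build_calibration_design(), "PR")
  cm <- fit_center(sp, y)
  cen <- apply_center(cm, sp, y)
  eps <- 0.3; C <- 50
  m <- train_linear_svr(cen$X, cen$y, epsilon = eps, cost = C, centering = cm)
  beta <- m$dual_coefficients
  expect_true(all(beta >= -C - 1e-9 & beta <= C + 1e-9))
  expect_lt(abs(sum(beta)), 1e-8 * C)
  resid <- cen$y - (drop(cen$X %*% svr_weights(m)) + m$bias)
  free <- which(abs(beta) > 1e-7 & abs(abs(beta) - C) > 1e-7)
  expect_gt(length(free), 0)
  expect_lt(max(abs(abs(resid[free]) - eps)), 1e-5)
  inside <- which(abs(resid) < eps - 1e-5)
  expect_true(all(abs(beta[inside]) < 1e-7))
  # every non-support training sample sits strictly inside the tube
  non_sv <- setdiff(seq_along(y), m$support_indices)
  expect_true(all(abs(resid[non_sv]) < eps + 1e-7))
  # primal and dual objectives agree within the gap tolerance
  P <- svr_primal_objective(m, cen$X, cen$y)
  D <- svr_dual_objective(m, cen$y)
  expect_gte(P - D, -1e-8 * (1 + abs(P)))
  expect_lte(P - D, 1e-6 * (1 + abs(P)))
})

test_that("prediction equals the explicit weight-vector form and the dual form", {
  xy <- tiny_xy(n = 7, p = 3, seed = 23)
  cen <- centered(xy$X, xy$y)
  m <- train_linear_svr(cen$X, cen$y, epsilon = 0.05, cost = 20)
  Xnew <- matrix(rnorm(9), 3, 3)
  via_w <- drop(Xnew %*% svr_weights(m)) + m$bias
  expect_equal(unname(predict(m, Xnew)), via_w, tolerance = 1e-10)
  # all-zero dual coefficients predict the bias everywhere
  flat <- train_linear_svr(cen$X, rep(0, 7), epsilon = 1, cost = 5)
  expect_equal(unname(predict(flat, Xnew)), rep(flat$bias, 3), tolerance = 1e-12)
})

test_that("exactly linear data inside the tube yields zero-loss models", {
  set.seed(29)
  X <- matrix(rnorm(24), 8, 3)
  beta0 <- c(1, -2, 0.5)
  y <- drop(X %*% beta0)
  m <- train_linear_svr(X, y, epsilon = 0.2, cost = 100)
  resid <- y - unname(predict(m, X))
  expect_true(all(abs(resid) <= 0.2 + 1e-7))
})

test_that("widening the tube never recruits more support vectors", {
  sp <- generate_mixture_spectra(build_calibration_design(),
                                 noise = noise_model(0.02, seed = 45))
  y <- design_response(build_calibration_design(), "PR")
  cm <- fit_center(sp, y)
  cen <- apply_center(cm, sp, y)
  n_sv <- vapply(c(0.05, 0.1, 0.3, 0.6, 1.2), function(eps) {
    length(train_linear_svr(cen$X, cen$y, epsilon = eps, cost = 50)$support_indices)
  }, integer(1))
  expect_true(all(diff(n_sv) <= 0))
})

test_that("small-epsilon SVR recovers noiseless test concentrations within 10 epsilon", {
  tr <- build_calibration_design(); te <- build_test_design()
  sp <- noiseless_training(); spte <- noiseless_test()
  y <- design_response(tr, "PR")
  cm <- fit_center(sp, y)
  cen <- apply_center(cm, sp, y)
  eps <- 0.05
  m <- train_linear_svr(cen$X, cen$y, epsilon = eps, cost = 1000, centering = cm)
  expect_lt(max(abs(predict(m, spte) - design_response(te, "PR"))), 10 * eps)
})

test_that("SVR input validation", {
  X <- matrix(rnorm(10), 5, 2)
  y <- rnorm(5)
  expect_error(train_linear_svr(X, y, epsilon = -0.1, cost = 1), "epsilon")
  expect_error(train_linear_svr(X, y, epsilon = 0.1, cost = 0), "cost")
  m <- train_linear_svr(X, y, epsilon = 0.1, cost = 1)
  expect_error(predict(m, matrix(0, 2, 3)), "shape error")
})

test_that("grid search returns the argmin of its own RMSECV table", {
  sp <- generate_mixture_spectra(build_calibration_design(),
                                 noise = noise_model(0.01, seed = 46))
  y <- design_response(build_calibration_design(), "PR")
  gs <- grid_search_svr(sp, y, epsilon_grid = c(0.05, 0.2, 0.5),
                        cost_grid = c(30, 100, 500), k = 4, seed = 9)
  expect_identical(nrow(gs$grid), 9L)
  best_row <- gs$grid[gs$grid$epsilon == gs$best_epsilon &
                        gs$grid$cost == gs$best_cost, ]
  expect_lte(best_row$rmsecv, min(gs$grid$rmsecv) + 1e-9)
  # ties prefer smaller C then smaller epsilon
  tied <- gs$grid[gs$grid$rmsecv <= min(gs$grid$rmsecv) + 1e-9, ]
  pick <- tied[order(tied$cost, tied$epsilon), ][1, ]
  expect_identical(c(gs$best_epsilon, gs$best_cost), c(pick$epsilon, pick$cost))
})

test_that("grid search is deterministic under a fixed seed", {
  sp <- generate_mixture_spectra(build_calibration_design(),
                                 noise = noise_model(0.01, seed = 47))
  y <- design_response(build_calibration_design(), "PR")
  g1 <- grid_search_svr(sp, y, epsilon_grid = c(0.1, 0.3), cost_grid = c(50, 200),
                        k = 4, seed = 5)
  g2 <- grid_search_svr(sp, y, epsilon_grid = c(0.1, 0.3), cost_grid = c(50, 200),
                        k = 4, seed = 5)
  expect_identical(g1$grid, g2$grid)
  # a single-candidate grid returns that candidate
  g3 <- grid_search_svr(sp, y, epsilon_grid = 0.2, cost_grid = 100, k = 4, seed = 5)
  expect_identical(c(g3$best_epsilon, g3$best_cost), c(0.2, 100))
  expect_error(grid_search_svr(sp, y, epsilon_grid = numeric(0),
                               cost_grid = 100, k = 4, seed = 1), "nonempty")
  expect_error(grid_search_svr(sp, y, epsilon_grid = 0.1, cost_grid = 100,
                               k = 20, seed = 1), "parameter error")
})

test_that("SMO agrees with an independent SVR implementation when available", {
  skip_if_not_installed("e1071")
  xy <- tiny_xy(n = 10, p = 4, seed = 31)
  cen <- centered(xy$X, xy$y)
  eps <- 0.1; C <- 10
  m <- train_linear_svr(cen$X, cen$y, epsilon = eps, cost = C)
  ref <- e1071::svm(cen$X, cen$y, type = "eps-regression", kernel = "linear",
                    cost = C, epsilon = eps, scale = FALSE, tolerance = 1e-8)
  w_ref <- drop(t(ref$coefs) %*% cen$X[ref$index, , drop = FALSE])
  expect_equal(svr_weights(m), w_ref, tolerance = 1e-4)
  expect_equal(m$bias, -ref$rho, tolerance = 1e-4)
})
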