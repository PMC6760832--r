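#' Train a linear epsilon-insensitive support vector regression model
#'
#' Solves the standard epsilon-SVR dual for the linear kernel by sequential
#' minimal optimization (maximal-violating-pair working sets), yielding the
#' signed dual coefficients beta_i = alpha_i - alpha_i* in [-C, C] with
#' sum(beta) = 0, and the bias from the KKT conditions averaged over free
#' support vectors. Residuals smaller than `epsilon` cost nothing; `cost`
#' (C) penalizes tube violations.
#'
#' @param X centered spectra matrix (samples x wavelengths).
#' @param y centered response vector; `epsilon` is interpreted on this
#'   centered concentration scale.
#' @param epsilon half-width of the insensitive tube (>= 0).
#' @param cost box constraint C (> 0).
#' @param centering optional [centering_model] recorded for prediction.
#' @param tol KKT gap tolerance for the SMO solver.
#' @param max_iter iteration cap for the SMO solver.
#' @return An object of class `svr_model` with `dual_coefficients` (beta),
#'   `bias`, `epsilon`, `cost`, `support_indices`, `training_inputs` (the
#'   centered training spectra) and `centering`.
#' @export
train_linear_svr <- function(X, y, epsilon, cost, centering = NULL,
                             tol = 1e-8, max_iter = 2000000L) {
  X <- as_absorbance(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), nrow(X) >= 1)
  if (epsilon < 0) stop("epsilon must be >= 0", call. = FALSE)
  if (cost <= 0) stop("cost must be > 0", call. = FALSE)
  K <- tcrossprod(X)
  sol <- smo_svr_solve(K, y, epsilon, cost, tol, as.integer(max_iter))
  if (!sol$converged) {
    stop(sprintf("solver error: SMO did not converge in %d iterations (KKT gap %.3e)",
                 sol$iterations, sol$kkt_gap), call. = FALSE)
  }
  beta <- sol$beta
  structure(
    list(dual_coefficients = beta,
         bias = sol$bias,
         epsilon = epsilon,
         cost = cost,
         support_indices = which(abs(beta) > 1e-10 * max(cost, 1)),
         training_inputs = X,
         centering = centering,
         kkt_gap = sol$kkt_gap,
         iterations = sol$iterations),
    class = "svr_model"
  )
}

#' Predict concentrations from a linear SVR model
#'
#' Applies the stored centering (if any), evaluates
#' f(x) = sum_i beta_i <x_i, x> + b, and adds back the stored response
#' mean. Identical to applying the explicit weight vector
#' w = sum_i beta_i x_i.
#'
#' @param object an [svr_model].
#' @param newdata a [spectra_matrix] or numeric matrix on the training
#'   wavelength axis.
#' @param ... unused.
#' @return Numeric vector of predicted concentrations (ug/mL).
#' @export
predict.svr_model <- function(object, newdata, ...) {
  A <- as_absorbance(newdata)
  if (ncol(A) != ncol(object$training_inputs)) {
    stop("shape error: data has ", ncol(A), " columns but the model was fit on ",
         ncol(object$training_inputs), call. = FALSE)
  }
  rm_ <- 0
  if (!is.null(object$centering)) {
    if (!is.null(object$centering$column_means)) {
      A <- sweep(A, 2, object$centering$column_means, `-`)
    }
    if (!is.null(object$centering$response_mean)) rm_ <- object$centering$response_mean
  }
  drop(A %*% crossprod(object$training_inputs, object$dual_coefficients)) +
    object$bias + rm_
}

#' Explicit weight vector of a linear SVR model
#'
#' @param model an [svr_model].
#' @return Numeric vector w = sum_i beta_i x_i in wavelength space.
#' @export
svr_weights <- function(model) {
  stopifnot(inherits(model, "svr_model"))
  drop(crossprod(model$training_inputs, model$dual_coefficients))
}

#' @export
print.svr_model <- function(x, ...) {
  cat("svr_model: epsilon ", x$epsilon, ", C ", x$cost, ", ",
      length(x$support_indices), "/", length(x$dual_coefficients),
      " support vector(s)\n", sep = "")
  invisible(x)
}

#' Grid search over (epsilon, C) by k-fold cross validation
#'
#' Randomly partitions the samples into `k` folds of as-equal-as-possible
#' size (16 samples and 4 folds give 4 folds of 4). For every candidate
#' (epsilon, C) pair and every fold, centering is re-estimated on the
#' retained samples, a linear SVR is trained on them, and the held-out fold
#' is predicted; squared errors are pooled over all samples into one
#' RMSECV per pair. The returned optimum minimizes RMSECV; among ties
#' within 1e-9 the smaller C and then the smaller epsilon wins.
#'
#' @param X spectra matrix (uncentered) or [spectra_matrix].
#' @param y response vector (ug/mL).
#' @param epsilon_grid candidate tube half-widths; default 0.01 to 1 in
#'   steps of 0.01.
#' @param cost_grid candidate C values; default 30 to 1000 in steps of 10.
#' @param k number of folds (default 4).
#' @param seed integer seed for the fold assignment; identical seeds give
#'   identical folds and an identical RMSECV table.
#' @param tol SMO KKT tolerance used during the search (looser than the
#'   final-fit default: the search only ranks candidates).
#' @return An object of class `grid_search_result` with `grid` (a data
#'   frame of epsilon, cost, rmsecv), `best_epsilon`, `best_cost`,
#'   `k_folds` and `seed`.
#' @export
grid_search_svr <- function(X, y,
                            epsilon_grid = seq(0.01, 1, by = 0.01),
                            cost_grid = seq(30, 1000, by = 10),
                            k = 4L, seed = 1L, tol = 1e-5) {
  X <- as_absorbance(X)
  y <- as.numeric(y)
  n <- nrow(X)
  stopifnot(length(y) == n)
  k <- as.integer(k)
  if (k < 2 || k > n) stop("parameter error: k must be between 2 and the sample count",
                           call. = FALSE)
  if (length(epsilon_grid) < 1 || length(cost_grid) < 1) {
    stop("parameter error: grids must be nonempty", call. = FALSE)
  }
  set.seed(seed)
  fold <- sample(rep(seq_len(k), length.out = n))
  sse <- matrix(0, nrow = length(epsilon_grid), ncol = length(cost_grid))
  for (f in seq_len(k)) {
    hold <- fold == f
    Xtr <- X[!hold, , drop = FALSE]
    ytr <- y[!hold]
    mu <- colMeans(Xtr)
    ybar <- mean(ytr)
    Xtr <- sweep(Xtr, 2, mu, `-`)
    Xte <- sweep(X[hold, , drop = FALSE], 2, mu, `-`)
    yc <- ytr - ybar
    K <- tcrossprod(Xtr)
    Kte <- tcrossprod(Xte, Xtr)
    sse <- smo_svr_grid_fold(K, yc, Kte, y[hold], ybar,
                             as.numeric(epsilon_grid), as.numeric(cost_grid),
                             order(epsilon_grid) - 1L, order(cost_grid) - 1L,
                             sse, tol = tol)
  }
  rmsecv <- sqrt(sse / n)
  best <- which(rmsecv <= min(rmsecv) + 1e-9, arr.ind = TRUE)
  ## ties: smaller C first, then smaller epsilon
  best <- best[order(cost_grid[best[, 2]], epsilon_grid[best[, 1]]), , drop = FALSE]
  grid <- data.frame(
    epsilon = rep(epsilon_grid, times = length(cost_grid)),
    cost = rep(cost_grid, each = length(epsilon_grid)),
    rmsecv = as.vector(rmsecv)
  )
  structure(
    list(grid = grid,
         rmsecv_matrix = rmsecv,
         best_epsilon = epsilon_grid[best[1, 1]],
         best_cost = cost_grid[best[1, 2]],
         k_folds = k, seed = as.integer(seed)),
    class = "grid_search_result"
  )
}

#' @export
print.grid_search_result <- function(x, ...) {
  cat("grid_search_result: ", nrow(x$grid), " (epsilon, C) pairs, ",
      x$k_folds, "-fold CV, seed ", x$seed, "\n",
      "  best: epsilon ", x$best_epsilon, ", C ", x$best_cost,
      " (RMSECV ", signif(min(x$grid$rmsecv), 5), ")\n", sep = "")
  invisible(x)
}
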