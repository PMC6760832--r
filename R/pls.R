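## NIPALS PLS1 core: X (n x J) and y (n) are assumed centered. Extracts up
## to `K` components, stopping early when the remaining covariance or score
## variance collapses (rank exhausted). Returns weights W, scores T,
## X-loadings P and y-loadings q for the attained number of components.
nipals_pls1 <- function(X, y, K) {
  n <- nrow(X)
  J <- ncol(X)
  W <- matrix(0, J, K)
  P <- matrix(0, J, K)
  Tm <- matrix(0, n, K)
  q <- numeric(K)
  wnorm0 <- NA_real_
  tt0 <- NA_real_
  attained <- 0L
  for (a in seq_len(K)) {
    w <- drop(crossprod(X, y))
    nw <- sqrt(sum(w^2))
    if (is.na(wnorm0)) wnorm0 <- nw
    if (nw <= 1e-12 || nw <= 1e-10 * wnorm0) break
    w <- w / nw
    t_a <- drop(X %*% w)
    tt <- sum(t_a^2)
    if (is.na(tt0)) tt0 <- tt
    if (tt <= 1e-24 || tt <= 1e-20 * tt0) break
    p_a <- drop(crossprod(X, t_a)) / tt
    q_a <- sum(y * t_a) / tt
    X <- X - tcrossprod(t_a, p_a)
    y <- y - q_a * t_a
    W[, a] <- w
    P[, a] <- p_a
    Tm[, a] <- t_a
    q[a] <- q_a
    attained <- a
  }
  list(W = W[, seq_len(attained), drop = FALSE],
       P = P[, seq_len(attained), drop = FALSE],
       T = Tm[, seq_len(attained), drop = FALSE],
       q = q[seq_len(attained)],
       attained = attained)
}

## Regression vectors for all truncations 1..A in one solve: b_k is column k
## of W backsolve(P'W) applied cumulatively. P'W is upper triangular for
## NIPALS PLS1, and the inverse of its leading principal block equals the
## leading block of its inverse, so b_k = R[, 1:k] %*% q[1:k] with
## R = W (P'W)^-1.
pls_rotation <- function(fit) {
  U <- crossprod(fit$P, fit$W)
  fit$W %*% backsolve(U, diag(nrow = ncol(fit$W)))
}

#' Fit a PLS1 calibration model (NIPALS)
#'
#' Decomposes the centered spectra X = T P' + E and the centered response
#' c = T q + f with `n_lv` latent variables, extracting components by the
#' NIPALS recursion (w = X'y normalized; t = Xw; p = X't/(t't);
#' q_a = y't/(t't); deflate X and y). The regression vector mapping a
#' centered spectrum to a centered concentration is W (P'W)^-1 q.
#'
#' @param X centered spectra matrix (samples x wavelengths).
#' @param y centered response vector (ug/mL).
#' @param n_lv number of latent variables, between 1 and
#'   `min(nrow(X) - 1, ncol(X))`.
#' @param centering optional [centering_model] recorded for prediction:
#'   [predict.pls_model()] subtracts its column means from new spectra and
#'   adds back its response mean.
#' @return An object of class `pls_model` with elements `n_lv`, `W`, `T`,
#'   `P`, `q`, `regression_vector`, `centering` and `fitted` (training
#'   predictions on the centered scale).
#' @export
fit_pls1 <- function(X, y, n_lv, centering = NULL) {
  X <- as_absorbance(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y))
  n_lv <- as.integer(n_lv)
  cap <- min(nrow(X) - 1L, ncol(X))
  if (n_lv < 1 || n_lv > cap) {
    stop("n_lv must be between 1 and min(samples - 1, wavelengths) = ", cap,
         call. = FALSE)
  }
  fit <- nipals_pls1(X, y, n_lv)
  if (fit$attained < n_lv) {
    stop("rank-deficiency error: attained rank ", fit$attained,
         " is below the requested ", n_lv, " latent variables", call. = FALSE)
  }
  b <- drop(pls_rotation(fit) %*% fit$q)
  structure(
    list(n_lv = n_lv, W = fit$W, T = fit$T, P = fit$P, q = fit$q,
         regression_vector = b, centering = centering,
         fitted = drop(X %*% b)),
    class = "pls_model"
  )
}

#' Predict concentrations from a PLS1 model
#'
#' Applies the stored centering (if any) to the new spectra, applies the
#' regression vector, and adds back the stored response mean.
#'
#' @param object a [pls_model].
#' @param newdata a [spectra_matrix] or numeric matrix on the training
#'   wavelength axis.
#' @param ... unused.
#' @return Numeric vector of predicted concentrations (ug/mL).
#' @export
predict.pls_model <- function(object, newdata, ...) {
  A <- as_absorbance(newdata)
  if (ncol(A) != length(object$regression_vector)) {
    stop("shape error: data has ", ncol(A), " columns but the model was fit on ",
         length(object$regression_vector), call. = FALSE)
  }
  rm_ <- 0
  if (!is.null(object$centering)) {
    if (!is.null(object$centering$column_means)) {
      A <- sweep(A, 2, object$centering$column_means, `-`)
    }
    if (!is.null(object$centering$response_mean)) rm_ <- object$centering$response_mean
  }
  yhat <- drop(A %*% object$regression_vector) + rm_
  if (!all(is.finite(yhat))) stop("non-finite predictions", call. = FALSE)
  yhat
}

#' @export
print.pls_model <- function(x, ...) {
  cat("pls_model: ", x$n_lv, " latent variable(s), ",
      length(x$regression_vector), " wavelength(s)\n", sep = "")
  invisible(x)
}

#' Bootstrap selection of the number of latent variables
#'
#' Repeatedly partitions the training set at random into a two-thirds
#' bootstrap-training part (`ceiling(2n/3)` rows, drawn without
#' replacement) and a one-third bootstrap-test part, re-estimates the
#' centering inside each iteration, fits PLS1 for every candidate LV count
#' and records the root mean square error of prediction on the held-out
#' part. RMSEP values are averaged over iterations and the chosen LV count
#' is the smallest one whose mean RMSEP is within 1e-6 of the minimum
#' (parsimony tie rule).
#'
#' @param X spectra matrix (uncentered; centering is re-estimated per
#'   iteration) or [spectra_matrix].
#' @param y response vector (ug/mL).
#' @param max_lv largest LV count examined; must be feasible for the
#'   bootstrap-training size (at most `ceiling(2n/3) - 1`).
#' @param n_iterations number of random splits (default 1000).
#' @param seed integer seed; identical seeds reproduce the RMSEP curve
#'   bit-identically.
#' @return An object of class `bootstrap_result` with `mean_rmsep_by_lv`,
#'   `chosen_lv`, `n_iterations` and `seed`.
#' @export
bootstrap_select_lv <- function(X, y, max_lv = 10L, n_iterations = 1000L, seed = 1L) {
  X <- as_absorbance(X)
  y <- as.numeric(y)
  n <- nrow(X)
  stopifnot(length(y) == n)
  if (n < 3) stop("need at least 3 samples for a 2/3-1/3 split", call. = FALSE)
  n_iterations <- as.integer(n_iterations)
  if (n_iterations < 1) stop("n_iterations must be >= 1", call. = FALSE)
  max_lv <- as.integer(max_lv)
  n_train <- as.integer(ceiling(2 * n / 3))
  cap <- min(n_train - 1L, ncol(X))
  if (max_lv < 1 || max_lv > cap) {
    stop("parameter error: max_lv must be between 1 and ", cap,
         " for a ", n_train, "/", n - n_train, " split", call. = FALSE)
  }
  set.seed(seed)
  rmsep_sum <- numeric(max_lv)
  for (it in seq_len(n_iterations)) {
    idx <- sample.int(n, n_train)
    Xtr <- X[idx, , drop = FALSE]
    ytr <- y[idx]
    Xte <- X[-idx, , drop = FALSE]
    yte <- y[-idx]
    mu <- colMeans(Xtr)
    ybar <- mean(ytr)
    Xtr <- sweep(Xtr, 2, mu, `-`)
    Xte <- sweep(Xte, 2, mu, `-`)
    fit <- nipals_pls1(Xtr, ytr - ybar, max_lv)
    if (fit$attained == 0) {
      ## no usable component: predict the mean for every LV count
      rmsep_sum <- rmsep_sum + sqrt(mean((yte - ybar)^2))
      next
    }
    scores_te <- Xte %*% pls_rotation(fit)
    contrib <- sweep(scores_te, 2, fit$q, `*`)
    cum <- contrib
    if (ncol(cum) > 1) {
      for (k in 2:ncol(cum)) cum[, k] <- cum[, k - 1] + cum[, k]
    }
    rmsep_k <- sqrt(colMeans((cum + ybar - yte)^2))
    ## LV counts beyond the attained rank cannot grow the model further
    if (fit$attained < max_lv) {
      rmsep_k <- c(rmsep_k, rep(rmsep_k[fit$attained], max_lv - fit$attained))
    }
    rmsep_sum <- rmsep_sum + rmsep_k
  }
  mean_rmsep <- rmsep_sum / n_iterations
  chosen <- which(mean_rmsep <= min(mean_rmsep) + 1e-6)[1]
  structure(
    list(mean_rmsep_by_lv = mean_rmsep, chosen_lv = as.integer(chosen),
         n_iterations = n_iterations, seed = as.integer(seed),
         max_lv = max_lv, n_train = n_train),
    class = "bootstrap_result"
  )
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat("bootstrap_result: chosen ", x$chosen_lv, " LV(s) from ",
      x$n_iterations, " iteration(s), seed ", x$seed, "\n", sep = "")
  print(round(x$mean_rmsep_by_lv, 5))
  invisible(x)
}
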