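#' Mean-centering model
#'
#' Stores the per-wavelength column means of a training block (and
#' optionally the training response mean) so the identical centering can be
#' applied, frozen, to new data. `column_means = NULL` builds a model that
#' leaves spectra unchanged but still carries a response mean; the pipeline
#' uses this for representations that are centered and filtered upstream.
#'
#' @param column_means numeric vector of column means (AU), or `NULL`.
#' @param response_mean optional response mean (ug/mL).
#' @return An object of class `centering_model`.
#' @export
centering_model <- function(column_means, response_mean = NULL) {
  structure(list(column_means = column_means, response_mean = response_mean),
            class = "centering_model")
}

#' Fit a mean-centering model
#'
#' @param X a [spectra_matrix] or numeric matrix (samples x wavelengths).
#' @param y optional response vector whose mean is stored alongside.
#' @return A [centering_model].
#' @export
fit_center <- function(X, y = NULL) {
  A <- as_absorbance(X)
  if (nrow(A) < 2) {
    stop("degenerate centering error: need at least 2 samples to estimate means",
         call. = FALSE)
  }
  centering_model(colMeans(A),
                  response_mean = if (!is.null(y)) mean(y) else NULL)
}

#' Apply a frozen centering model
#'
#' Subtracts the stored training means; never re-estimates means on the new
#' data, so applying to a single new sample is well defined.
#'
#' @param model a [centering_model].
#' @param X a [spectra_matrix] or numeric matrix.
#' @param y optional response vector to centre with the stored response mean.
#' @return The centered matrix, or `list(X = , y = )` when `y` is supplied.
#' @export
apply_center <- function(model, X, y = NULL) {
  stopifnot(inherits(model, "centering_model"))
  A <- as_absorbance(X)
  if (!is.null(model$column_means)) {
    if (ncol(A) != length(model$column_means)) {
      stop("shape error: data has ", ncol(A), " columns but the centering model was fit on ",
           length(model$column_means), call. = FALSE)
    }
    A <- sweep(A, 2, model$column_means, `-`)
  }
  if (is.null(y)) return(A)
  if (is.null(model$response_mean)) {
    stop("centering model holds no response mean", call. = FALSE)
  }
  list(X = A, y = y - model$response_mean)
}

#' First-derivative transform of spectra
#'
#' Computes dA/d(lambda) for every spectrum, either as forward finite
#' differences on band midpoints (shortening the grid by one point) or as a
#' same-length Savitzky-Golay smoothed derivative. Derivative spectra
#' suppress broad baseline structure and reduce band overlap, at the cost
#' of amplifying high-frequency noise.
#'
#' @param X a [spectra_matrix].
#' @param method `"finite_difference"` (default) or `"savitzky_golay"`.
#' @param window odd filter length for Savitzky-Golay (default 5).
#' @param polyorder polynomial order for Savitzky-Golay (default 2); must be
#'   below `window`.
#' @return A [spectra_matrix] of derivative spectra (AU/nm) with its grid
#'   metadata updated.
#' @export
first_derivative <- function(X, method = c("finite_difference", "savitzky_golay"),
                             window = 5L, polyorder = 2L) {
  stopifnot(inherits(X, "spectra_matrix"))
  method <- match.arg(method)
  wl <- X$wavelengths_nm
  J <- length(wl)
  if (J < 2) stop("parameter error: need at least 2 wavelengths", call. = FALSE)
  step <- wl[2] - wl[1]
  if (method == "finite_difference") {
    D <- (X$absorbance[, -1, drop = FALSE] - X$absorbance[, -J, drop = FALSE]) / step
    spectra_matrix(D, wl[-J] + step / 2, sample_ids = X$sample_ids)
  } else {
    window <- as.integer(window)
    polyorder <- as.integer(polyorder)
    if (window %% 2 == 0) stop("parameter error: window must be odd", call. = FALSE)
    if (polyorder >= window) {
      stop("parameter error: polyorder must be below the window length", call. = FALSE)
    }
    if (window >= J + 1) {
      stop("parameter error: window (", window, ") must not exceed the number of wavelengths (",
           J, ")", call. = FALSE)
    }
    D <- t(apply(X$absorbance, 1, function(r) {
      signal::sgolayfilt(r, p = polyorder, n = window, m = 1, ts = step)
    }))
    if (nrow(X$absorbance) == 0) D <- matrix(numeric(0), nrow = 0, ncol = J)
    spectra_matrix(D, wl, sample_ids = X$sample_ids)
  }
}

#' Fit an OPLS filter (removal of response-orthogonal variation)
#'
#' Orthogonal projection to latent structures: estimates, on mean-centered
#' training data, spectral components whose scores are orthogonal to the
#' (centered) response, and removes them from X. Per component the
#' single-response recursion is: w = X'y normalized; t = Xw;
#' p = X't/(t't); w_o = p - (w'p) w, normalized; t_o = X w_o;
#' p_o = X' t_o / (t_o' t_o); X <- X - t_o p_o'. Removed training scores
#' are exactly orthogonal to y by construction.
#'
#' @param X centered spectra matrix (samples x wavelengths).
#' @param y centered response vector.
#' @param n_ortho number of orthogonal components to remove (>= 1). If the
#'   orthogonal weight collapses earlier, fewer components are stored and a
#'   notice is emitted.
#' @return An object of class `opls_filter` with elements `n_ortho`,
#'   `W_ortho`, `P_ortho` (wavelength-space vectors, one column per removed
#'   component; weights have unit norm), `T_ortho` (training scores) and
#'   `X_filtered` (the filtered training matrix).
#' @export
fit_opls <- function(X, y, n_ortho = 1L) {
  X <- as_absorbance(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y))
  n_ortho <- as.integer(n_ortho)
  if (n_ortho < 1) stop("n_ortho must be >= 1", call. = FALSE)
  if (all(y == 0)) {
    stop("degenerate response error: y is identically zero", call. = FALSE)
  }
  J <- ncol(X)
  W_o <- matrix(numeric(0), nrow = J, ncol = 0)
  P_o <- matrix(numeric(0), nrow = J, ncol = 0)
  T_o <- matrix(numeric(0), nrow = nrow(X), ncol = 0)
  for (a in seq_len(n_ortho)) {
    w <- drop(crossprod(X, y))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) {
      message("OPLS: X'y vanished after ", a - 1,
              " component(s); stopping early")
      break
    }
    w <- w / nw
    t_pred <- drop(X %*% w)
    p <- drop(crossprod(X, t_pred)) / sum(t_pred^2)
    w_o <- p - drop(crossprod(w, p)) * w
    ## second Gram-Schmidt pass: keeps t_o exactly orthogonal to y even for
    ## later components where rounding in one pass would accumulate
    w_o <- w_o - drop(crossprod(w, w_o)) * w
    n_wo <- sqrt(sum(w_o^2))
    if (n_wo < 1e-12) {
      message("OPLS: no orthogonal variation left after ", a - 1,
              " component(s); stopping early")
      break
    }
    w_o <- w_o / n_wo
    t_o <- drop(X %*% w_o)
    p_o <- drop(crossprod(X, t_o)) / sum(t_o^2)
    X <- X - tcrossprod(t_o, p_o)
    W_o <- cbind(W_o, w_o)
    P_o <- cbind(P_o, p_o)
    T_o <- cbind(T_o, t_o)
  }
  structure(
    list(n_ortho = ncol(W_o), W_ortho = W_o, P_ortho = P_o,
         T_ortho = T_o, X_filtered = X),
    class = "opls_filter"
  )
}

#' Apply a fitted OPLS filter to new (centered) spectra
#'
#' Sequentially removes each stored orthogonal component:
#' t_o = X w_o; X <- X - t_o p_o'. Uses only training-derived vectors; the
#' operation is idempotent.
#'
#' @param filter an [opls_filter] from [fit_opls()].
#' @param X_new matrix of new spectra centered with the training means.
#' @return The filtered matrix.
#' @export
apply_opls <- function(filter, X_new) {
  stopifnot(inherits(filter, "opls_filter"))
  X_new <- as_absorbance(X_new)
  if (filter$n_ortho == 0) return(X_new)
  if (ncol(X_new) != nrow(filter$W_ortho)) {
    stop("shape error: data has ", ncol(X_new), " columns but the filter was fit on ",
         nrow(filter$W_ortho), call. = FALSE)
  }
  for (a in seq_len(filter$n_ortho)) {
    t_o <- drop(X_new %*% filter$W_ortho[, a])
    X_new <- X_new - tcrossprod(t_o, filter$P_ortho[, a])
  }
  X_new
}

#' @export
print.opls_filter <- function(x, ...) {
  cat("opls_filter: ", x$n_ortho, " orthogonal component(s), ",
      nrow(x$W_ortho), " wavelength(s)\n", sep = "")
  invisible(x)
}
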