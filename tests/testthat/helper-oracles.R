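# Independent oracles used to cross-check the production implementations.
# These are deliberately written as plain, slow, direct computations.

# Ordinary least squares on centered data via the normal equations /
# QR; the PLS1 solution must coincide with this at full LV count.
ols_oracle_predict <- function(Xc, yc, Xc_new) {
  fit <- qr(Xc)
  beta <- qr.coef(fit, yc)
  beta[is.na(beta)] <- 0
  drop(Xc_new %*% beta)
}

# Independently coded NIPALS PLS1: straightforward loops, no shared code
# with the package internals.
nipals_oracle <- function(X, y, K) {
  W <- NULL; P <- NULL; Tm <- NULL; q <- c()
  for (a in seq_len(K)) {
    w <- as.vector(t(X) %*% y)
    w <- w / sqrt(sum(w * w))
    t_a <- as.vector(X %*% w)
    p_a <- as.vector(t(X) %*% t_a) / sum(t_a * t_a)
    q_a <- sum(y * t_a) / sum(t_a * t_a)
    X <- X - outer(t_a, p_a)
    y <- y - q_a * t_a
    W <- cbind(W, w); P <- cbind(P, p_a); Tm <- cbind(Tm, t_a); q <- c(q, q_a)
  }
  list(W = W, P = P, T = Tm, q = q)
}

# Brute-force epsilon-SVR oracle: enumerate every per-sample KKT state
# (beta_i = 0, free positive, free negative, +C, -C), solve the resulting
# linear system for the free coefficients and the bias, and keep the
# configuration satisfying all KKT inequalities. Exponential in n; only
# for tiny fixtures.
svr_bruteforce_oracle <- function(X, y, epsilon, C, tol = 1e-7) {
  n <- length(y)
  K <- X %*% t(X)
  states <- c("zero", "free_pos", "free_neg", "bound_pos", "bound_neg")
  grid <- do.call(expand.grid, rep(list(states), n))
  for (r in seq_len(nrow(grid))) {
    st <- as.character(unlist(grid[r, ]))
    free <- which(st %in% c("free_pos", "free_neg"))
    if (length(free) == 0) next  # need a free vector to pin the bias
    beta <- numeric(n)
    beta[st == "bound_pos"] <- C
    beta[st == "bound_neg"] <- -C
    s <- ifelse(st == "free_pos", 1, ifelse(st == "free_neg", -1, 0))
    nf <- length(free)
    A <- rbind(cbind(K[free, free, drop = FALSE], rep(1, nf)),
               c(rep(1, nf), 0))
    bound <- which(st %in% c("bound_pos", "bound_neg"))
    rhs_top <- y[free] - s[free] * epsilon
    if (length(bound) > 0) {
      rhs_top <- rhs_top - drop(K[free, bound, drop = FALSE] %*% beta[bound])
    }
    rhs <- c(rhs_top, -sum(beta[bound]))
    sol <- tryCatch(solve(A, rhs), error = function(e) NULL)
    if (is.null(sol)) next
    beta[free] <- sol[seq_len(nf)]
    b <- sol[nf + 1]
    # feasibility of the free coefficients
    ok <- TRUE
    for (i in free) {
      if (s[i] == 1 && !(beta[i] > -tol && beta[i] < C + tol)) ok <- FALSE
      if (s[i] == -1 && !(beta[i] < tol && beta[i] > -C - tol)) ok <- FALSE
    }
    if (!ok) next
    resid <- y - drop(K %*% beta) - b
    for (i in seq_len(n)) {
      ri <- resid[i]
      if (st[i] == "zero" && abs(ri) > epsilon + tol) ok <- FALSE
      if (st[i] == "bound_pos" && ri < epsilon - tol) ok <- FALSE
      if (st[i] == "bound_neg" && ri > -epsilon + tol) ok <- FALSE
      if (st[i] == "free_pos" && abs(ri - epsilon) > tol) ok <- FALSE
      if (st[i] == "free_neg" && abs(ri + epsilon) > tol) ok <- FALSE
    }
    if (ok) return(list(beta = beta, bias = b))
  }
  stop("brute-force oracle found no KKT-consistent configuration")
}

# Feasible bias interval implied by the KKT conditions for a given dual
# solution: free coefficients pin b exactly; bound/zero ones bound it.
# When no coefficient is free the optimal b is any point of the interval.
svr_bias_interval <- function(beta, X, y, epsilon, C, tol = 1e-7) {
  g <- drop(X %*% t(X) %*% beta)
  lo <- -Inf; hi <- Inf
  for (i in seq_along(y)) {
    r <- y[i] - g[i]
    if (abs(beta[i]) <= tol) {                       # inside or on tube
      lo <- max(lo, r - epsilon); hi <- min(hi, r + epsilon)
    } else if (beta[i] >= C - tol) {                 # at +C: residual >= eps
      hi <- min(hi, r - epsilon)
    } else if (beta[i] <= -C + tol) {                # at -C: residual <= -eps
      lo <- max(lo, r + epsilon)
    } else if (beta[i] > 0) {                        # free positive
      lo <- max(lo, r - epsilon); hi <- min(hi, r - epsilon)
    } else {                                         # free negative
      lo <- max(lo, r + epsilon); hi <- min(hi, r + epsilon)
    }
  }
  c(lo, hi)
}

# Primal and dual objective values of the linear epsilon-SVR problem, for
# duality-gap checks.
svr_primal_objective <- function(model, X, y) {
  w <- svr_weights(model)
  f <- drop(X %*% w) + model$bias
  loss <- pmax(0, abs(y - f) - model$epsilon)
  0.5 * sum(w^2) + model$cost * sum(loss)
}
svr_dual_objective <- function(model, y) {
  beta <- model$dual_coefficients
  K <- model$training_inputs %*% t(model$training_inputs)
  -0.5 * drop(t(beta) %*% K %*% beta) - model$epsilon * sum(abs(beta)) + sum(y * beta)
}
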