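#' Support vector regression surrogate (RBF kernel, dual solver)
#'
#' Fits one epsilon-insensitive support vector regression per output with
#' the radial kernel \eqn{k(x, x') = \exp(-\gamma \|x - x'\|^2)}. The dual
#' problem is solved by pairwise coordinate optimization: writing
#' \eqn{\beta_i = \alpha_i - \alpha_i^*}, the dual is
#' \deqn{\min_\beta \tfrac12 \beta^\top K \beta - y^\top \beta +
#'   \epsilon \|\beta\|_1, \quad \sum_i \beta_i = 0,\; |\beta_i| \le C,}
#' and each step picks the maximally KKT-violating pair and minimizes the
#' resulting one-dimensional piecewise quadratic exactly. Iteration stops
#' when the maximal KKT violation falls below `tol`.
#'
#' The baseline kernel width for these 4-dimensional inputs is
#' `gamma = 1/4 = 0.25` (inverse of the input dimension).
#'
#' @param data Training `sample_tbl`.
#' @param gamma RBF kernel width (> 0); default is the 0.25 baseline.
#' @param C Box constraint on the dual coefficients (> 0).
#' @param epsilon Half-width of the insensitive tube (>= 0).
#' @param tol KKT violation tolerance for convergence.
#' @param max_iter Cap on pairwise updates per output.
#' @return An object of class `svr_surrogate` with one dual model per
#'   output (coefficients `beta`, bias `b`, support indices).
#' @export
fit_svr <- function(data, gamma = 0.25, C = 1, epsilon = 0.1,
                    tol = 1e-3, max_iter = 100000L) {
  check_columns(data, c(input_names(), output_names()))
  if (gamma <= 0) abort("`gamma` must be > 0")
  if (C <= 0) abort("`C` must be > 0")
  if (epsilon < 0) abort("`epsilon` must be >= 0")
  X <- input_matrix(data)
  Y <- output_matrix(data)
  K <- rbf_kernel(X, X, gamma)
  models <- lapply(output_names(), function(nm) {
    svr_solve_dual(K, Y[, nm], C, epsilon, tol, max_iter)
  })
  names(models) <- output_names()
  structure(
    list(X = X, models = models, gamma = gamma, C = C, epsilon = epsilon,
         tol = tol),
    class = "svr_surrogate"
  )
}

rbf_kernel <- function(A, B, gamma) {
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  d2 <- outer(an, bn, `+`) - 2 * tcrossprod(A, B)
  exp(-gamma * pmax(d2, 0))
}

# Pairwise-coordinate (SMO-style) solver for the epsilon-SVR dual in the
# beta = alpha - alpha* parameterization. Maximal-violating-pair selection;
# exact line search on the piecewise quadratic (breakpoints where beta_i or
# beta_j changes sign).
svr_solve_dual <- function(K, y, C, epsilon, tol, max_iter) {
  n <- length(y)
  beta <- numeric(n)
  f <- numeric(n) # K %*% beta
  objective <- 0  # primal value of the dual QP being minimized
  obj_path <- numeric(0)
  iter <- 0L
  repeat {
    g <- y - f
    # admissible range of the equality multiplier for each coordinate:
    # a lower bound wherever beta_i can still increase, an upper bound
    # wherever it can still decrease; interior coordinates pin it exactly
    L <- ifelse(beta >= C, -Inf, ifelse(beta <= 0, g + epsilon, g - epsilon))
    L[beta == 0] <- g[beta == 0] - epsilon
    U <- ifelse(beta <= -C, Inf, ifelse(beta >= 0, g - epsilon, g + epsilon))
    U[beta == 0] <- g[beta == 0] + epsilon
    i <- which.max(L)
    j <- which.min(U)
    violation <- L[i] - U[j]
    if (violation < tol) {
      b <- (max(L[is.finite(L)]) + min(U[is.finite(U)])) / 2
      return(list(
        beta = beta, b = b, support = which(beta != 0),
        iterations = iter, kkt_violation = max(violation, 0),
        objective_path = obj_path
      ))
    }
    if (iter >= max_iter) {
      abort(sprintf(
        "SVR dual solver did not converge in %d updates; residual KKT violation %.3g",
        max_iter, violation
      ))
    }
    eta <- K[i, i] + K[j, j] - 2 * K[i, j]
    g0 <- (f[i] - y[i]) - (f[j] - y[j])
    lo <- max(-C - beta[i], beta[j] - C)
    hi <- min(C - beta[i], beta[j] + C)
    phi <- function(t) {
      0.5 * eta * t^2 + g0 * t +
        epsilon * (abs(beta[i] + t) + abs(beta[j] - t) -
                     abs(beta[i]) - abs(beta[j]))
    }
    cand <- c(lo, hi, -beta[i], beta[j])
    if (eta > 0) {
      cand <- c(cand, -(g0 - 2 * epsilon) / eta, -g0 / eta,
                -(g0 + 2 * epsilon) / eta)
    }
    cand <- pmin(pmax(cand, lo), hi)
    t_star <- cand[which.min(phi(cand))]
    if (abs(t_star) < 1e-15) {
      # numerically stuck: accept current state as converged
      b <- (max(L[is.finite(L)]) + min(U[is.finite(U)])) / 2
      return(list(
        beta = beta, b = b, support = which(beta != 0),
        iterations = iter, kkt_violation = violation,
        objective_path = obj_path
      ))
    }
    objective <- objective + phi(t_star)
    beta[i] <- beta[i] + t_star
    beta[j] <- beta[j] - t_star
    f <- f + t_star * (K[, i] - K[, j])
    iter <- iter + 1L
    obj_path[iter] <- objective
  }
}

#' @export
print.svr_surrogate <- function(x, ...) {
  nsv <- vapply(x$models, function(m) length(m$support), integer(1))
  cat(sprintf(
    "<svr_surrogate> RBF gamma = %g, C = %g, epsilon = %g\n",
    x$gamma, x$C, x$epsilon
  ))
  cat("  support vectors per output:",
      paste(names(nsv), nsv, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @rdname predict.linear_surrogate
#' @export
predict.svr_surrogate <- function(object, newdata, ...) {
  Xn <- input_matrix(newdata)
  out <- lapply(output_names(), function(nm) {
    m <- object$models[[nm]]
    if (length(m$support) == 0) {
      return(rep(m$b, nrow(Xn)))
    }
    Ks <- rbf_kernel(Xn, object$X[m$support, , drop = FALSE], object$gamma)
    drop(Ks %*% m$beta[m$support]) + m$b
  })
  names(out) <- output_names()
  tibble::as_tibble(out)
}
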