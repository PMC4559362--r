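#' Multilayer perceptron surrogate trained by back-propagation
#'
#' A single-hidden-layer feed-forward network (4 inputs, `hidden_size`
#' hidden neurons, 5 outputs) with logistic activation on both the hidden
#' and the output layer — outputs are normalized to `[0, 1]`, so a bounded
#' output unit is appropriate. Training is full-batch gradient descent on
#' half the sum of squared errors (SSE/2), the gradients coming from
#' standard back-propagation. Weights and biases are initialized
#' Uniform(-0.5, 0.5) under `seed`; training stops after `max_epochs`
#' epochs or when the SSE improves by less than `tol` between epochs.
#'
#' @param data Training `sample_tbl`; outputs must lie in `[0, 1]`.
#' @param hidden_size Number of hidden neurons (default 7, the size that
#'   wins the hidden-layer scan under the standard protocol).
#' @param learning_rate Gradient-descent step size.
#' @param max_epochs Epoch cap.
#' @param tol Stopping tolerance on the epoch-to-epoch SSE change.
#' @param seed Integer seed for weight initialization.
#' @return An object of class `mlp_surrogate` carrying the weights and a
#'   training record (`epochs`, `initial_sse`, `final_sse`, `converged`).
#' @export
fit_mlp <- function(data, hidden_size = 7, learning_rate = 0.1,
                    max_epochs = 50000, tol = 1e-8, seed = 1L) {
  check_columns(data, c(input_names(), output_names()))
  if (hidden_size < 1 || hidden_size != round(hidden_size)) {
    abort("`hidden_size` must be a positive integer")
  }
  X <- unname(input_matrix(data))
  Y <- unname(output_matrix(data))
  if (any(Y < 0) || any(Y > 1)) {
    abort("MLP targets must lie in [0, 1]; normalize the table first")
  }
  w <- withr::with_seed(seed, mlp_init(hidden_size))
  # one forward pass per epoch serves both the SSE record and the gradient
  fwd <- mlp_forward(w, X)
  sse <- sum((fwd$Yhat - Y)^2) / 2
  initial_sse <- sse
  epochs <- 0L
  converged <- FALSE
  while (epochs < max_epochs) {
    d2 <- (fwd$Yhat - Y) * fwd$Yhat * (1 - fwd$Yhat)
    d1 <- (d2 %*% t(w$W2)) * fwd$H * (1 - fwd$H)
    w <- list(
      W1 = w$W1 - learning_rate * crossprod(X, d1),
      b1 = w$b1 - learning_rate * colSums(d1),
      W2 = w$W2 - learning_rate * crossprod(fwd$H, d2),
      b2 = w$b2 - learning_rate * colSums(d2)
    )
    fwd <- mlp_forward(w, X)
    new_sse <- sum((fwd$Yhat - Y)^2) / 2
    if (!is.finite(new_sse)) {
      abort(sprintf(
        "MLP training diverged (SSE not finite) at learning_rate = %g",
        learning_rate
      ))
    }
    epochs <- epochs + 1L
    if (abs(sse - new_sse) < tol) {
      sse <- new_sse
      converged <- TRUE
      break
    }
    sse <- new_sse
  }
  structure(
    list(
      hidden_size = as.integer(hidden_size), weights = w,
      learning_rate = learning_rate, seed = seed,
      epochs = epochs, initial_sse = initial_sse, final_sse = sse,
      converged = converged
    ),
    class = "mlp_surrogate"
  )
}

mlp_init <- function(hidden_size) {
  list(
    W1 = matrix(runif(4 * hidden_size, -0.5, 0.5), nrow = 4),
    b1 = runif(hidden_size, -0.5, 0.5),
    W2 = matrix(runif(hidden_size * 5, -0.5, 0.5), nrow = hidden_size),
    b2 = runif(5, -0.5, 0.5)
  )
}

logistic <- function(z) 1 / (1 + exp(-z))

mlp_forward <- function(w, X) {
  H <- logistic(sweep(X %*% w$W1, 2, w$b1, `+`))
  Yhat <- logistic(sweep(H %*% w$W2, 2, w$b2, `+`))
  list(H = H, Yhat = Yhat)
}

mlp_sse <- function(w, X, Y) {
  sum((mlp_forward(w, X)$Yhat - Y)^2) / 2
}

# Back-propagated gradient of SSE/2 with respect to all weights.
mlp_gradient <- function(w, X, Y) {
  fwd <- mlp_forward(w, X)
  H <- fwd$H
  Yhat <- fwd$Yhat
  d2 <- (Yhat - Y) * Yhat * (1 - Yhat)    # n x 5
  d1 <- (d2 %*% t(w$W2)) * H * (1 - H)     # n x h
  list(
    W1 = crossprod(X, d1), b1 = colSums(d1),
    W2 = crossprod(H, d2), b2 = colSums(d2)
  )
}

#' @export
print.mlp_surrogate <- function(x, ...) {
  cat(sprintf(
    "<mlp_surrogate> 4-%d-5 logistic network; %d epochs, SSE %.4g -> %.4g%s\n",
    x$hidden_size, x$epochs, x$initial_sse, x$final_sse,
    if (x$converged) " (converged)" else ""
  ))
  invisible(x)
}

#' @rdname predict.linear_surrogate
#' @export
predict.mlp_surrogate <- function(object, newdata, ...) {
  X <- input_matrix(newdata)
  Yhat <- mlp_forward(object$weights, X)$Yhat
  colnames(Yhat) <- output_names()
  tibble::as_tibble(Yhat)
}
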