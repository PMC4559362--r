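#' Linear (ordinary least squares) surrogate
#'
#' Fits a multi-output linear map from the augmented input
#' `(1, IFNg, IL12, IL6, TGFb)` to the five outputs by ordinary least
#' squares. The fitted transformation matrix has one row per output — in
#' the conventional order (FOXP3, IFNg_out, IL17, RORgt, Tbet) — and one
#' column per augmented input, so predictions are a single matrix-vector
#' product.
#'
#' @param data A training `sample_tbl` (or any data frame with the nine
#'   canonical columns) with at least 5 rows and a full-rank design.
#' @return An object of class `linear_surrogate`.
#' @seealso [linear_surrogate()] to construct one from a known matrix.
#' @export
fit_linear <- function(data) {
  check_columns(data, c(input_names(), output_names()))
  X <- cbind(`(Intercept)` = 1, input_matrix(data))
  Y <- output_matrix(data)[, linear_output_order(), drop = FALSE]
  if (nrow(X) < ncol(X)) {
    abort("fit_linear needs at least 5 training rows")
  }
  fit <- stats::lm.fit(X, Y)
  if (fit$rank < ncol(X)) {
    abort(sprintf(
      "rank-deficient design: rank %d < %d columns", fit$rank, ncol(X)
    ))
  }
  coef_matrix <- t(fit$coefficients) # outputs x (1 + inputs)
  linear_surrogate(coef_matrix, n_train = nrow(X))
}

linear_output_order <- function() {
  c("FOXP3", "IFNg_out", "IL17", "RORgt", "Tbet")
}

#' Construct a linear surrogate from a given transformation matrix
#'
#' @param coef_matrix 5x5 numeric matrix; rows are the outputs in the
#'   order (FOXP3, IFNg_out, IL17, RORgt, Tbet), columns the augmented
#'   input (intercept, IFNg, IL12, IL6, TGFb).
#' @param n_train Optional training-set size for the record.
#' @return An object of class `linear_surrogate`.
#' @export
linear_surrogate <- function(coef_matrix, n_train = NA_integer_) {
  coef_matrix <- as.matrix(coef_matrix)
  if (!all(dim(coef_matrix) == c(5, 5)) || !all(is.finite(coef_matrix))) {
    abort("`coef_matrix` must be a finite 5x5 matrix")
  }
  dimnames(coef_matrix) <- list(
    linear_output_order(),
    c("(Intercept)", input_names())
  )
  structure(
    list(coef_matrix = coef_matrix, n_train = n_train),
    class = "linear_surrogate"
  )
}

#' @export
print.linear_surrogate <- function(x, ...) {
  cat("<linear_surrogate> 5x5 transformation matrix\n")
  print(round(x$coef_matrix, 4))
  invisible(x)
}

#' Predict steady-state outputs with a fitted surrogate
#'
#' All four surrogate families share this contract: `newdata` is a data
#' frame with the four input columns and the result is a tibble with the
#' five output columns, one row per input row.
#'
#' @param object A fitted surrogate.
#' @param newdata Data frame with columns `IFNg`, `IL12`, `IL6`, `TGFb`.
#' @param ... Unused.
#' @return A tibble with columns `IL17`, `RORgt`, `IFNg_out`, `Tbet`,
#'   `FOXP3`.
#' @export
predict.linear_surrogate <- function(object, newdata, ...) {
  X <- cbind(1, input_matrix(newdata))
  Y <- X %*% t(object$coef_matrix) # n x 5, linear output order
  tibble::as_tibble(Y)[output_names()]
}
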