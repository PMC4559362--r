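#' Hill activation and inhibition functions
#'
#' Sigmoidal saturation kinetics used for every regulatory edge of the
#' reduced differentiation model. `hill_activation()` is the standard Hill
#' function \eqn{x^n / (K^n + x^n)}; `hill_inhibition()` is its complement
#' \eqn{K^n / (K^n + y^n)}, used for repression edges.
#'
#' @param x,y Nonnegative ligand/regulator level.
#' @param K Half-saturation constant, strictly positive. At `x = K` the
#'   activation equals exactly 0.5.
#' @param n Hill coefficient, at least 1; controls switch steepness.
#'
#' @return A numeric vector of fractions in `[0, 1)` (activation) or
#'   `(0, 1]` (inhibition).
#'
#' @examples
#' hill_activation(0.25, K = 0.25, n = 2) # 0.5 at half-saturation
#' hill_inhibition(0, K = 0.35, n = 2)    # no repressor -> fully open
#' @export
hill_activation <- function(x, K, n = 2) {
  check_hill_args(x, K, n)
  xn <- x^n
  xn / (K^n + xn)
}

#' @rdname hill_activation
#' @export
hill_inhibition <- function(y, K, n = 2) {
  check_hill_args(y, K, n)
  Kn <- K^n
  Kn / (Kn + y^n)
}

check_hill_args <- function(x, K, n) {
  if (!all(is.finite(x)) || any(x < 0)) {
    abort("Hill input levels must be finite and nonnegative")
  }
  if (!is.finite(K) || K <= 0) abort("half-saturation `K` must be > 0")
  if (!is.finite(n) || n < 1) abort("Hill coefficient `n` must be >= 1")
  invisible(TRUE)
}
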