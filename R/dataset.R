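#' Build a steady-state dataset from an input grid
#'
#' Runs the reduced kinetic model to steady state at every grid point and
#' pairs inputs with the resulting output panel. Outputs are on the raw
#' model scale; apply [normalize_outputs()] afterwards to reproduce the
#' standard protocol.
#'
#' @param grid Data frame of cytokine inputs (see [generate_grid()]).
#' @param params A [kinetic_params()] object.
#' @return A raw-scale [as_sample_table()] with one row per grid point.
#' @examples
#' small <- generate_grid(grid_spec(IFNg = c(0, 1), IL12 = 0,
#'                                  IL6 = c(0, 1), TGFb = c(0, 1)))
#' build_dataset(small)
#' @export
build_dataset <- function(grid, params = kinetic_params()) {
  check_columns(grid, input_names())
  if (nrow(grid) == 0) abort("`grid` must contain at least one row")
  outputs <- steady_state(grid, params)
  as_sample_table(
    dplyr::bind_cols(tibble::as_tibble(grid)[input_names()], outputs),
    provenance = list(generator = "reference_model")
  )
}

#' Min-max normalize the output columns of a sample table
#'
#' Rescales each output column to span exactly `[0, 1]` over the table
#' (`(y - min) / (max - min)`), recording the per-output (min, max) in the
#' `scaling` attribute so raw values remain recoverable. A degenerate
#' column (max == min) maps to all zeros. Scaling is computed on the full
#' table, before any train/test split.
#'
#' @param table A `sample_tbl` with at least two rows.
#' @return A normalized `sample_tbl`.
#' @export
normalize_outputs <- function(table) {
  table <- as_sample_table(table, scaling = attr(table, "scaling"),
                           provenance = attr(table, "provenance"))
  if (nrow(table) < 2) {
    abort("normalization needs at least 2 rows to define a range")
  }
  Y <- output_matrix(table)
  mins <- apply(Y, 2, min)
  maxs <- apply(Y, 2, max)
  span <- maxs - mins
  Yn <- sweep(Y, 2, mins)
  for (j in seq_along(span)) {
    Yn[, j] <- if (span[j] > 0) Yn[, j] / span[j] else 0
  }
  out <- dplyr::bind_cols(
    tibble::as_tibble(unclass_sample(table))[input_names()],
    tibble::as_tibble(Yn)
  )
  as_sample_table(
    out,
    scaling = tibble::tibble(output = output_names(),
                             min = unname(mins), max = unname(maxs)),
    provenance = attr(table, "provenance") %||% list()
  )
}

#' Inject multiplicative uniform noise into the outputs
#'
#' Implements the noise protocol: each output value `y` is replaced by
#' `y * (1 + u)` with `u ~ Uniform(-a, a)` drawn independently per cell
#' (column-major order under the given seed), then clamped at zero. Inputs
#' are untouched. `half_width = 0.005` and `0.01` correspond to the
#' \eqn{\pm 0.5\%} and \eqn{\pm 1\%} protocols; `half_width = 0` is the
#' identity.
#'
#' @param table A (typically normalized) `sample_tbl`.
#' @param half_width Relative noise half-amplitude `a >= 0`.
#' @param seed Integer RNG seed; identical seeds reproduce the table.
#' @return A `sample_tbl` with noisy outputs and updated provenance.
#' @export
add_output_noise <- function(table, half_width, seed = 1L) {
  table <- as_sample_table(table, scaling = attr(table, "scaling"),
                           provenance = attr(table, "provenance"))
  if (!is.numeric(half_width) || length(half_width) != 1 ||
      !is.finite(half_width) || half_width < 0) {
    abort("`half_width` must be a single number >= 0")
  }
  if (half_width == 0) {
    return(restamp(table, table, noise = 0))
  }
  Y <- output_matrix(table)
  u <- withr::with_seed(seed,
    matrix(runif(length(Y), -half_width, half_width), nrow = nrow(Y))
  )
  Yn <- pmax(Y * (1 + u), 0)
  colnames(Yn) <- output_names()
  out <- dplyr::bind_cols(
    tibble::as_tibble(unclass_sample(table))[input_names()],
    tibble::as_tibble(Yn)
  )
  restamp(out, table, noise = half_width, noise_seed = seed)
}

#' Randomly split a sample table into training and test sets
#'
#' Draws `n_train` rows uniformly without replacement (seeded) for
#' training; the complement is the test set. The default protocol takes
#' 100 of the 625 grid samples for training and tests on the remaining
#' 525.
#'
#' @param table A `sample_tbl`.
#' @param n_train Training-set size, strictly between 0 and `nrow(table)`.
#' @param seed Integer RNG seed.
#' @return A list with `sample_tbl` elements `train` and `test`.
#' @examples
#' \dontrun{
#' data <- normalize_outputs(build_dataset(generate_grid()))
#' parts <- split_samples(data, n_train = 100, seed = 42)
#' nrow(parts$train); nrow(parts$test)
#' }
#' @export
split_samples <- function(table, n_train = 100, seed = 1L) {
  table <- as_sample_table(table, scaling = attr(table, "scaling"),
                           provenance = attr(table, "provenance"))
  n <- nrow(table)
  if (!is.numeric(n_train) || length(n_train) != 1 ||
      n_train != round(n_train) || n_train <= 0 || n_train >= n) {
    abort("`n_train` must be an integer strictly between 0 and nrow(table)")
  }
  idx <- withr::with_seed(seed, sort(sample.int(n, n_train)))
  list(
    train = restamp(table[idx, ], table, split = "train", split_seed = seed),
    test = restamp(table[-idx, ], table, split = "test", split_seed = seed)
  )
}
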