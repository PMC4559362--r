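# Shared fixtures, built once per test run and memoized.

.fixture_cache <- new.env(parent = emptyenv())

# strip sample_tbl metadata for value comparisons
unclass_tbl <- function(x) {
  x <- as.data.frame(x)
  attr(x, "scaling") <- NULL
  attr(x, "provenance") <- NULL
  x
}

# Raw 625-point steady-state grid dataset (expensive; reused everywhere).
grid_dataset_raw <- function() {
  if (is.null(.fixture_cache$raw)) {
    .fixture_cache$raw <- build_dataset(generate_grid())
  }
  .fixture_cache$raw
}

# Normalized benchmark dataset per the standard protocol.
grid_dataset <- function() {
  if (is.null(.fixture_cache$norm)) {
    .fixture_cache$norm <- normalize_outputs(grid_dataset_raw())
  }
  .fixture_cache$norm
}

benchmark_parts <- function(seed = 1L) {
  split_samples(grid_dataset(), n_train = 100, seed = seed)
}

# Small deterministic training table for fast fits: 3^4 = 81-point grid.
small_table <- function() {
  if (is.null(.fixture_cache$small)) {
    g <- generate_grid(grid_spec(
      IFNg = c(0, 0.5, 1), IL12 = c(0, 0.5, 1),
      IL6 = c(0, 0.5, 1), TGFb = c(0, 0.5, 1)
    ))
    .fixture_cache$small <- normalize_outputs(build_dataset(g))
  }
  .fixture_cache$small
}

# Data from a planted affine map (no noise): outputs clipped to stay
# finite but NOT clipped to [0,1] -- used for exact linear recovery.
planted_affine_map <- function() {
  M <- rbind(
    c(0.20, 0.10, -0.05, 0.30, 0.40),
    c(0.05, 0.50, 0.20, -0.10, 0.15),
    c(0.10, -0.20, 0.30, 0.25, 0.05),
    c(0.00, 0.15, 0.10, 0.40, -0.30),
    c(0.30, 0.05, -0.15, 0.20, 0.10)
  ) # rows: outputs in (FOXP3, IFNg_out, IL17, RORgt, Tbet) order
  list(model = linear_surrogate(M), coef = M)
}

affine_table <- function(n = 40, seed = 11L) {
  planted <- planted_affine_map()
  X <- withr::with_seed(seed, matrix(runif(n * 4), ncol = 4))
  colnames(X) <- c("IFNg", "IL12", "IL6", "TGFb")
  inputs <- tibble::as_tibble(X)
  dplyr::bind_cols(inputs, predict(planted$model, inputs))
}

# Damped fixed-point oracle for the model steady state: iterates
# state <- (1 - w) * state + w * drive(state) / delta from zero. This is
# an independent route to the same equilibrium as the ODE integration.
fixed_point_oracle <- function(input, params = kinetic_params(),
                               damping = 0.5, max_iter = 10000,
                               tol = 1e-13) {
  state <- c(Tbet = 0, RORgt = 0, FOXP3 = 0, IL17 = 0, IFNg_out = 0)
  A <- function(x) x^params$n_hill / (params$K_act^params$n_hill + x^params$n_hill)
  I <- function(y) params$K_inh^params$n_hill / (params$K_inh^params$n_hill + y^params$n_hill)
  I6 <- function(y) params$K_act^params$n_hill / (params$K_act^params$n_hill + y^params$n_hill)
  S <- function(x) x^params$n_hill / (params$K_sec^params$n_hill + x^params$n_hill)
  for (k in seq_len(max_iter)) {
    target <- c(
      params$v * A(input[["IFNg"]] + input[["IL12"]]) *
        I(state[["RORgt"]]) * I(state[["FOXP3"]]),
      params$v * A(input[["TGFb"]]) * A(input[["IL6"]]) *
        I(state[["Tbet"]]) * I(state[["FOXP3"]]),
      params$v * A(input[["TGFb"]]) * I6(input[["IL6"]]) *
        I(state[["Tbet"]]) * I(state[["RORgt"]]),
      params$v * S(state[["RORgt"]]),
      params$v * S(state[["Tbet"]])
    ) / params$delta
    new_state <- (1 - damping) * state + damping * setNames(target, names(state))
    if (max(abs(new_state - state)) < tol) {
      state <- new_state
      break
    }
    state <- new_state
  }
  c(IL17 = state[["IL17"]], RORgt = state[["RORgt"]],
    IFNg_out = state[["IFNg_out"]], Tbet = state[["Tbet"]],
    FOXP3 = state[["FOXP3"]])
}
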