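#' Right-hand side of the reduced differentiation model
#'
#' Computes the instantaneous rates of change of the five state variables
#' (T-bet, RORgt, FOXP3, secreted IL-17 and IFNg) given the extracellular
#' cytokine milieu. Each master regulator is produced under Hill-type
#' activation by its inducing cytokines and Hill-type repression by the
#' competing regulators, and decays by first-order mass action:
#'
#' \describe{
#'   \item{T-bet}{activated by IFNg + IL-12; repressed by RORgt and FOXP3
#'     (Th1 axis).}
#'   \item{RORgt}{requires both TGFb and IL-6; repressed by T-bet and FOXP3
#'     (Th17 axis).}
#'   \item{FOXP3}{activated by TGFb, shut off by IL-6; repressed by T-bet
#'     and RORgt (Treg axis).}
#'   \item{IL-17, secreted IFNg}{driven by their master regulators RORgt
#'     and T-bet respectively.}
#' }
#'
#' @param state Named numeric vector with elements `Tbet`, `RORgt`,
#'   `FOXP3`, `IL17`, `IFNg_out`, all finite and nonnegative.
#' @param input Named numeric vector with elements `IFNg`, `IL12`, `IL6`,
#'   `TGFb` in `[0, 1]`.
#' @param params A [kinetic_params()] object.
#'
#' @return Named numeric vector of rates, in the same order as `state`.
#' @examples
#' p <- kinetic_params()
#' s0 <- c(Tbet = 0, RORgt = 0, FOXP3 = 0, IL17 = 0, IFNg_out = 0)
#' diff_rates(s0, c(IFNg = 0, IL12 = 0, IL6 = 0, TGFb = 1), p)
#' @export
diff_rates <- function(state, input, params = kinetic_params()) {
  stopifnot(inherits(params, "kinetic_params"))
  state <- state[state_names()]
  input <- input[input_names()]
  if (anyNA(state) || !all(is.finite(state))) {
    abort("`state` must contain finite Tbet, RORgt, FOXP3, IL17, IFNg_out")
  }
  if (any(state < 0)) abort("state components must be nonnegative")
  check_input_levels(input)
  A <- function(x) hill_activation(x, params$K_act, params$n_hill)
  I <- function(y) hill_inhibition(y, params$K_inh, params$n_hill)
  I6 <- function(y) hill_inhibition(y, params$K_act, params$n_hill)
  S <- function(x) hill_activation(x, params$K_sec, params$n_hill)
  v <- params$v
  d <- params$delta
  c(
    Tbet = v * A(input[["IFNg"]] + input[["IL12"]]) *
      I(state[["RORgt"]]) * I(state[["FOXP3"]]) - d * state[["Tbet"]],
    RORgt = v * A(input[["TGFb"]]) * A(input[["IL6"]]) *
      I(state[["Tbet"]]) * I(state[["FOXP3"]]) - d * state[["RORgt"]],
    FOXP3 = v * A(input[["TGFb"]]) * I6(input[["IL6"]]) *
      I(state[["Tbet"]]) * I(state[["RORgt"]]) - d * state[["FOXP3"]],
    IL17 = v * S(state[["RORgt"]]) - d * state[["IL17"]],
    IFNg_out = v * S(state[["Tbet"]]) - d * state[["IFNg_out"]]
  )
}

state_names <- function() c("Tbet", "RORgt", "FOXP3", "IL17", "IFNg_out")

zero_state <- function() {
  setNames(numeric(5), state_names())
}

check_input_levels <- function(input) {
  if (anyNA(input) || !all(is.finite(input))) {
    abort("cytokine input must contain finite IFNg, IL12, IL6, TGFb")
  }
  if (any(input < 0) || any(input > 1)) {
    abort("cytokine input levels must lie in [0, 1]")
  }
  invisible(input)
}

# Pre-resolved constants for the integrator hot path; drive terms that
# depend only on the (fixed) input are evaluated once per condition.
model_ctx <- function(input, params) {
  n <- params$n_hill
  A <- function(x) hill_activation(x, params$K_act, n)
  I6 <- function(y) hill_inhibition(y, params$K_act, n)
  list(
    n = n, Kin = params$K_inh^n, Ksn = params$K_sec^n,
    v = params$v, delta = params$delta, tol_ss = params$tol_ss,
    drive_tbet = params$v * A(input[["IFNg"]] + input[["IL12"]]),
    drive_rorgt = params$v * A(input[["TGFb"]]) * A(input[["IL6"]]),
    drive_foxp3 = params$v * A(input[["TGFb"]]) * I6(input[["IL6"]])
  )
}

# deSolve-facing RHS; y arrives in state_names() order
# (Tbet, RORgt, FOXP3, IL17, IFNg_out). Plain arithmetic: this runs
# hundreds of times per grid point.
model_rhs <- function(t, y, parms) {
  y <- pmax(y, 0) # guard integrator undershoot below 0
  yn <- y[1:3]^parms$n
  inh <- parms$Kin / (parms$Kin + yn) # repression by Tbet, RORgt, FOXP3
  sec <- yn[1:2] / (parms$Ksn + yn[1:2]) # secretion drive from Tbet, RORgt
  list(c(
    parms$drive_tbet * inh[2] * inh[3] - parms$delta * y[1],
    parms$drive_rorgt * inh[1] * inh[3] - parms$delta * y[2],
    parms$drive_foxp3 * inh[1] * inh[2] - parms$delta * y[3],
    parms$v * sec[2] - parms$delta * y[4],
    parms$v * sec[1] - parms$delta * y[5]
  ))
}

model_root <- function(t, y, parms) {
  rates <- model_rhs(t, y, parms)[[1]]
  max(abs(rates)) - parms$tol_ss
}

#' Steady-state readouts of the differentiation model
#'
#' Integrates the reduced kinetic model from the all-zero naive state until
#' the max-norm of the rate vector drops below `tol_ss`, for each row of
#' cytokine inputs. The all-zero initial condition makes the reachable
#' steady state unique and reproducible even though mutual inhibition
#' between the master regulators admits multistability in general.
#'
#' @param data Data frame with numeric columns `IFNg`, `IL12`, `IL6`,
#'   `TGFb`, one row per condition, all values in `[0, 1]`.
#' @param params A [kinetic_params()] object.
#'
#' @return A tibble with one row per input row and columns `IL17`,
#'   `RORgt`, `IFNg_out`, `Tbet`, `FOXP3` (raw scale, in `[0, v/delta]`).
#' @examples
#' steady_state(data.frame(IFNg = 0, IL12 = 0, IL6 = 0, TGFb = 1))
#' @export
steady_state <- function(data, params = kinetic_params()) {
  check_columns(data, input_names())
  out <- purrr::map(seq_len(nrow(data)), function(i) {
    input <- setNames(as.numeric(data[i, input_names()]), input_names())
    steady_state_one(input, params, row = i)
  })
  tibble::as_tibble(do.call(rbind, out))[output_names()]
}

steady_state_one <- function(input, params, row = NULL) {
  check_input_levels(input)
  y0 <- zero_state()
  rates0 <- diff_rates(y0, input, params)
  if (max(abs(rates0)) < params$tol_ss) {
    return(as.data.frame(as.list(y0[output_names()])))
  }
  sol <- deSolve::ode(
    y = y0, times = c(0, params$t_max), func = model_rhs,
    parms = model_ctx(input, params),
    method = "lsodar", rootfunc = model_root,
    atol = 1e-12, rtol = 1e-10
  )
  final <- sol[nrow(sol), -1]
  resid <- max(abs(diff_rates(pmax(final, 0), input, params)))
  if (resid >= params$tol_ss) {
    where <- if (is.null(row)) "" else paste0(" (row ", row, ")")
    abort(sprintf(
      "steady state not reached by t_max = %g%s; residual max|rate| = %.3g",
      params$t_max, where, resid
    ))
  }
  as.data.frame(as.list(pmax(final, 0)[output_names()]))
}

#' Simulate a time course of the differentiation model
#'
#' Integrates the reduced model from the all-zero state over an explicit
#' time grid, for diagnostics and plotting.
#'
#' @param input Named numeric vector (`IFNg`, `IL12`, `IL6`, `TGFb`) or a
#'   one-row data frame of input levels in `[0, 1]`.
#' @param params A [kinetic_params()] object.
#' @param t_grid Strictly increasing numeric vector of time points, first
#'   element >= 0.
#'
#' @return A tibble of class `th_timecourse` with column `time` followed by
#'   the five state variables; see [autoplot.th_timecourse()].
#' @examples
#' tc <- simulate_timecourse(
#'   c(IFNg = 0, IL12 = 0, IL6 = 0, TGFb = 1),
#'   t_grid = seq(0, 20, by = 0.5)
#' )
#' tail(tc, 1)
#' @export
simulate_timecourse <- function(input, params = kinetic_params(),
                                t_grid = seq(0, params$t_max, length.out = 201)) {
  if (is.data.frame(input)) {
    stopifnot(nrow(input) == 1)
    input <- setNames(as.numeric(input[1, input_names()]), input_names())
  }
  input <- input[input_names()]
  check_input_levels(input)
  if (length(t_grid) < 1 || t_grid[1] < 0 ||
      (length(t_grid) > 1 && any(diff(t_grid) <= 0))) {
    abort("`t_grid` must be strictly increasing and start at >= 0")
  }
  y0 <- zero_state()
  if (length(t_grid) == 1) {
    res <- tibble::as_tibble(as.list(c(time = t_grid, y0)))
  } else {
    sol <- deSolve::ode(
      y = y0, times = t_grid, func = model_rhs,
      parms = model_ctx(input, params),
      method = "lsoda", atol = 1e-12, rtol = 1e-10
    )
    res <- tibble::as_tibble(as.data.frame(sol))
    names(res)[1] <- "time"
  }
  class(res) <- c("th_timecourse", class(res))
  attr(res, "input") <- input
  res
}
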