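#' Kinetic parameters of the reduced differentiation model
#'
#' Bundles the rate constants of the five-state Hill-kinetics model of CD4+
#' T cell differentiation. All regulatory edges share three half-saturation
#' constants (activation, inhibition, secretion); production is capped at
#' `v` and every species decays by first-order mass action at rate `delta`,
#' so all steady states lie in `[0, v/delta]`.
#'
#' Defaults put the second grid level (0.25) exactly at activation
#' half-saturation, which keeps the steady-state response informative across
#' the whole `[0,1]` input range.
#'
#' @param n_hill Hill coefficient shared by all edges (>= 1).
#' @param K_act Half-saturation of activating edges.
#' @param K_inh Half-saturation of repressive edges between master
#'   regulators.
#' @param K_sec Half-saturation of cytokine secretion driven by its master
#'   regulator.
#' @param v Maximal production rate (per time unit).
#' @param delta First-order decay rate (per time unit).
#' @param tol_ss Steady-state tolerance: integration stops once the
#'   max-norm of the rate vector falls below this.
#' @param t_max Integration horizon; failing to reach `tol_ss` by `t_max`
#'   is reported as a convergence error.
#'
#' @return An object of class `kinetic_params` (a named list).
#' @seealso [steady_state()], [diff_rates()], [read_kinetic_params()]
#' @examples
#' p <- kinetic_params()
#' p$K_act
#' @export
kinetic_params <- function(n_hill = 2, K_act = 0.25, K_inh = 0.35,
                           K_sec = 0.30, v = 1, delta = 1,
                           tol_ss = 1e-8, t_max = 200) {
  vals <- list(
    n_hill = n_hill, K_act = K_act, K_inh = K_inh, K_sec = K_sec,
    v = v, delta = delta, tol_ss = tol_ss, t_max = t_max
  )
  for (nm in names(vals)) {
    x <- vals[[nm]]
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
      abort(paste0("`", nm, "` must be a single finite number"))
    }
  }
  if (vals$n_hill < 1) abort("`n_hill` must be >= 1")
  for (nm in c("K_act", "K_inh", "K_sec", "v", "delta", "tol_ss")) {
    if (vals[[nm]] <= 0) abort(paste0("`", nm, "` must be > 0"))
  }
  if (vals$t_max <= 0) abort("`t_max` must be > 0")
  structure(vals, class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("<kinetic_params>\n")
  cat(sprintf(
    "  Hill n = %g; K_act = %g, K_inh = %g, K_sec = %g\n",
    x$n_hill, x$K_act, x$K_inh, x$K_sec
  ))
  cat(sprintf(
    "  v = %g, delta = %g; tol_ss = %g, t_max = %g\n",
    x$v, x$delta, x$tol_ss, x$t_max
  ))
  invisible(x)
}

#' Read and write kinetic parameters (JSON or YAML)
#'
#' Serialization round-trips a [kinetic_params()] object through a plain
#' JSON or YAML mapping; the format is inferred from the file extension
#' (`.json`, `.yml`/`.yaml`).
#'
#' @param path File path.
#' @param params A `kinetic_params` object.
#' @return `read_kinetic_params()` returns a `kinetic_params` object;
#'   `write_kinetic_params()` returns `path` invisibly.
#' @export
read_kinetic_params <- function(path) {
  vals <- switch(param_format(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yaml = yaml::read_yaml(path)
  )
  do.call(kinetic_params, as.list(vals))
}

#' @rdname read_kinetic_params
#' @export
write_kinetic_params <- function(params, path) {
  stopifnot(inherits(params, "kinetic_params"))
  vals <- unclass(params)
  switch(param_format(path),
    json = jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA),
    yaml = yaml::write_yaml(vals, path)
  )
  invisible(path)
}

param_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") return("json")
  if (ext %in% c("yml", "yaml")) return("yaml")
  abort("parameter files must end in .json, .yml or .yaml")
}
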