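#' Tidy and glance methods for fitted surrogates and reports
#'
#' Broom-style accessors: `tidy()` returns per-component detail (one row
#' per coefficient, weight, output or fold) and `glance()` a one-row
#' model-level summary.
#'
#' @param x A fitted surrogate or report object.
#' @param ... Unused.
#' @return A tibble.
#' @name thsurr-tidiers
NULL

#' @rdname thsurr-tidiers
#' @export
tidy.linear_surrogate <- function(x, ...) {
  cm <- x$coef_matrix
  tidyr::expand_grid(output = rownames(cm), term = colnames(cm)) |>
    dplyr::mutate(estimate = as.vector(t(cm)))
}

#' @rdname thsurr-tidiers
#' @export
glance.linear_surrogate <- function(x, ...) {
  tibble::tibble(n_train = x$n_train, n_coef = length(x$coef_matrix))
}

#' @rdname thsurr-tidiers
#' @export
tidy.mlp_surrogate <- function(x, ...) {
  w <- x$weights
  edge_rows <- function(M, layer, from_names, to_names) {
    tidyr::expand_grid(from = from_names, to = to_names) |>
      dplyr::mutate(layer = layer, weight = as.vector(t(M))) |>
      dplyr::select("layer", "from", "to", "weight")
  }
  hid <- paste0("h", seq_len(x$hidden_size))
  dplyr::bind_rows(
    edge_rows(w$W1, "input-hidden", input_names(), hid),
    edge_rows(matrix(w$b1, nrow = 1), "input-hidden", "(bias)", hid),
    edge_rows(w$W2, "hidden-output", hid, output_names()),
    edge_rows(matrix(w$b2, nrow = 1), "hidden-output", "(bias)",
              output_names())
  )
}

#' @rdname thsurr-tidiers
#' @export
glance.mlp_surrogate <- function(x, ...) {
  tibble::tibble(
    hidden_size = x$hidden_size, epochs = x$epochs,
    initial_sse = x$initial_sse, final_sse = x$final_sse,
    converged = x$converged, learning_rate = x$learning_rate
  )
}

#' @rdname thsurr-tidiers
#' @export
tidy.svr_surrogate <- function(x, ...) {
  dplyr::bind_rows(lapply(output_names(), function(nm) {
    m <- x$models[[nm]]
    tibble::tibble(
      output = nm, n_support = length(m$support), bias = m$b,
      iterations = m$iterations, kkt_violation = m$kkt_violation
    )
  }))
}

#' @rdname thsurr-tidiers
#' @export
glance.svr_surrogate <- function(x, ...) {
  tibble::tibble(
    gamma = x$gamma, C = x$C, epsilon = x$epsilon,
    total_support = sum(vapply(x$models, function(m) length(m$support),
                               integer(1)))
  )
}

#' @rdname thsurr-tidiers
#' @export
tidy.rf_surrogate <- function(x, ...) {
  if (x$bootstrap) {
    oob_error(x)
  } else {
    tibble::tibble(output = output_names(), oob_mse = NA_real_,
                   n_oob_samples = 0L, n_never_oob = nrow(x$X))
  }
}

#' @rdname thsurr-tidiers
#' @export
glance.rf_surrogate <- function(x, ...) {
  tibble::tibble(
    ntree = x$ntree, mtry = x$mtry, min_node_size = x$min_node_size,
    bootstrap = x$bootstrap,
    mean_oob_mse = if (x$bootstrap) mean(oob_error(x)$oob_mse) else NA_real_
  )
}

#' @rdname thsurr-tidiers
#' @export
tidy.error_report <- function(x, ...) {
  tibble::as_tibble(x) |>
    tidyr::pivot_longer(dplyr::all_of(output_names()),
                        names_to = "output", values_to = "mae")
}

#' @rdname thsurr-tidiers
#' @export
glance.cv_report <- function(x, ...) {
  avg <- colMeans(as.matrix(tibble::as_tibble(x)[output_names()]))
  out <- dplyr::bind_cols(
    tibble::tibble(method = attr(x, "method"), k = nrow(x),
                   seed = attr(x, "seed")),
    tibble::as_tibble(as.list(avg))
  )
  out$sum_mse <- sum(avg)
  out
}

#' @rdname thsurr-tidiers
#' @export
tidy.cv_report <- function(x, ...) {
  tibble::as_tibble(x) |>
    tidyr::pivot_longer(dplyr::all_of(output_names()),
                        names_to = "output", values_to = "mse")
}
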