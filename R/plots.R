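#' Plot a simulated time course
#'
#' Line plot of the five state variables against time.
#'
#' @param object A `th_timecourse` from [simulate_timecourse()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.th_timecourse <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object), -"time",
    names_to = "species", values_to = "level"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$level,
                                     colour = .data$species)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::labs(x = "time", y = "level",
                  title = "Differentiation model time course") +
    ggplot2::theme_minimal()
}

#' Plot a hyperparameter scan
#'
#' Sum of prediction error against the scanned hyperparameter; the
#' selected configuration is highlighted. Kernel-width scans use a log
#' axis; forest scans colour by `mtry`.
#'
#' @param object A `scan_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scan_result <- function(object, ...) {
  over <- attr(object, "scan_over")
  sel <- scan_selection(object)
  d <- tibble::as_tibble(object)
  xvar <- over[1]
  p <- if (length(over) == 2) {
    ggplot2::ggplot(d, ggplot2::aes(.data[[xvar]], .data$sum_error,
                                    colour = factor(.data[[over[2]]]))) +
      ggplot2::labs(colour = over[2])
  } else {
    ggplot2::ggplot(d, ggplot2::aes(.data[[xvar]], .data$sum_error))
  }
  p <- p + ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::annotate("point", x = sel[[xvar]], y = sel$sum_error,
                      shape = 1, size = 4) +
    ggplot2::labs(y = "sum of prediction error") +
    ggplot2::theme_minimal()
  if (xvar == "gamma") p <- p + ggplot2::scale_x_log10()
  p
}

#' Plot per-output benchmark errors
#'
#' Bar chart of per-output mean absolute error, one facet per method.
#'
#' @param object An `error_report` (e.g. `run_benchmark()$errors`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.error_report <- function(object, ...) {
  long <- tidy.error_report(object)
  ggplot2::ggplot(long, ggplot2::aes(.data$output, .data$mae)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~method) +
    ggplot2::labs(y = "mean absolute error", x = NULL) +
    ggplot2::theme_minimal()
}

#' Plot noise-robustness results
#'
#' Sum of prediction error as a function of the injected relative noise
#' half-width, one line per surrogate family.
#'
#' @param object A `noise_report` from [noise_robustness()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.noise_report <- function(object, ...) {
  d <- tibble::as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$noise, .data$sum_error,
                                  colour = .data$method)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "relative noise half-width",
                  y = "sum of prediction error") +
    ggplot2::theme_minimal()
}
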