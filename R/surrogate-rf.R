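#' Random forest surrogate (per-output regression forests)
#'
#' Grows one forest of CART-style regression trees per output cytokine.
#' Each tree is fit on a bootstrap sample (n draws with replacement); at
#' every node `mtry` features are sampled without replacement and the
#' split maximizing the variance reduction is taken, with thresholds at
#' midpoints of consecutive distinct sorted values. Nodes with fewer than
#' `min_node_size` samples, or zero target variance, become leaves storing
#' the mean of their training targets; predictions average over trees.
#' Out-of-bag (OOB) predictions — each sample predicted only by trees
#' whose bootstrap excluded it — are stored for [oob_error()].
#'
#' @param data Training `sample_tbl`.
#' @param ntree Number of trees per output (default 1000, the selected
#'   setting of the standard protocol).
#' @param mtry Features sampled as split candidates at each node
#'   (1 to 4; default 4).
#' @param min_node_size Minimal node size still eligible for splitting.
#' @param seed Integer RNG seed for bootstraps and feature sampling.
#' @param bootstrap Set `FALSE` to train every tree on the full sample
#'   (disables OOB error).
#' @return An object of class `rf_surrogate`.
#' @export
fit_rf <- function(data, ntree = 1000, mtry = 4, min_node_size = 5,
                   seed = 1L, bootstrap = TRUE) {
  check_columns(data, c(input_names(), output_names()))
  if (ntree < 1 || ntree != round(ntree)) abort("`ntree` must be >= 1")
  if (mtry < 1 || mtry > 4 || mtry != round(mtry)) {
    abort("`mtry` must be an integer between 1 and the number of inputs (4)")
  }
  if (min_node_size < 1) abort("`min_node_size` must be >= 1")
  X <- input_matrix(data)
  Y <- output_matrix(data)
  forests <- withr::with_seed(seed, {
    lapply(output_names(), function(nm) {
      rf_fit_cpp(X, Y[, nm], as.integer(ntree), as.integer(mtry),
                 as.integer(min_node_size), bootstrap)
    })
  })
  names(forests) <- output_names()
  structure(
    list(
      forests = forests, X = X, Y = Y,
      ntree = as.integer(ntree), mtry = as.integer(mtry),
      min_node_size = as.integer(min_node_size),
      seed = seed, bootstrap = bootstrap
    ),
    class = "rf_surrogate"
  )
}

#' @export
print.rf_surrogate <- function(x, ...) {
  cat(sprintf(
    "<rf_surrogate> %d trees x 5 outputs; mtry = %d, min_node_size = %d%s\n",
    x$ntree, x$mtry, x$min_node_size,
    if (x$bootstrap) "" else " (bootstrap disabled)"
  ))
  invisible(x)
}

#' @rdname predict.linear_surrogate
#' @export
predict.rf_surrogate <- function(object, newdata, ...) {
  Xn <- input_matrix(newdata)
  out <- lapply(output_names(), function(nm) {
    rf_predict_cpp(object$forests[[nm]]$trees, Xn)
  })
  names(out) <- output_names()
  tibble::as_tibble(out)
}

#' Out-of-bag error of a random forest surrogate
#'
#' For each training sample, averages the predictions of the trees whose
#' bootstrap sample excluded it, and reports the per-output mean squared
#' error over all samples that were out-of-bag for at least one tree.
#' Samples in every tree's bootstrap (possible for tiny forests) are
#' excluded and counted.
#'
#' @param model A bootstrap-trained `rf_surrogate`.
#' @return A tibble with columns `output`, `oob_mse`, `n_oob_samples`,
#'   `n_never_oob`.
#' @export
oob_error <- function(model) {
  stopifnot(inherits(model, "rf_surrogate"))
  if (!model$bootstrap) {
    abort("OOB error is undefined when bootstrap is disabled")
  }
  rows <- lapply(output_names(), function(nm) {
    forest <- model$forests[[nm]]
    oob <- forest$inbag == 0 # n x ntree
    preds <- rf_predict_all_cpp(forest$trees, model$X)
    n_oob_trees <- rowSums(oob)
    has_oob <- n_oob_trees > 0
    oob_pred <- rowSums(preds * oob) / pmax(n_oob_trees, 1)
    err <- (oob_pred[has_oob] - model$Y[has_oob, nm])^2
    tibble::tibble(
      output = nm, oob_mse = mean(err),
      n_oob_samples = sum(has_oob), n_never_oob = sum(!has_oob)
    )
  })
  dplyr::bind_rows(rows)
}
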