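#' Serialize fitted surrogates to JSON
#'
#' All four surrogate families round-trip losslessly through a versioned
#' JSON document (`format` tag `thsurr-surrogate/1`): the linear
#' transformation matrix, MLP weight matrices, SVR dual coefficients and
#' retained inputs, or the full node arrays of every forest tree.
#'
#' @param model A fitted surrogate.
#' @param path Output file path.
#' @return `write_surrogate()` returns `path` invisibly;
#'   `read_surrogate()` returns the reconstructed surrogate.
#' @export
write_surrogate <- function(model, path) {
  payload <- list(format = "thsurr-surrogate/1", class = class(model)[1])
  payload$fields <- switch(class(model)[1],
    linear_surrogate = list(
      coef_matrix = model$coef_matrix, n_train = model$n_train
    ),
    mlp_surrogate = model[c("hidden_size", "weights", "learning_rate",
                            "seed", "epochs", "initial_sse", "final_sse",
                            "converged")],
    svr_surrogate = list(
      X = model$X, gamma = model$gamma, C = model$C,
      epsilon = model$epsilon, tol = model$tol,
      models = lapply(model$models, function(m) {
        m[c("beta", "b", "support", "iterations", "kkt_violation")]
      })
    ),
    rf_surrogate = list(
      X = model$X, Y = model$Y, ntree = model$ntree, mtry = model$mtry,
      min_node_size = model$min_node_size, seed = model$seed,
      bootstrap = model$bootstrap,
      forests = lapply(model$forests, function(f) {
        list(trees = f$trees, inbag = f$inbag)
      })
    ),
    abort("unknown surrogate class")
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_surrogate
#' @export
read_surrogate <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE)
  if (!identical(payload$format, "thsurr-surrogate/1")) {
    abort("not a recognized surrogate file")
  }
  f <- payload$fields
  switch(payload$class,
    linear_surrogate = linear_surrogate(f$coef_matrix, f$n_train),
    mlp_surrogate = {
      w <- f$weights
      w$W1 <- as.matrix(w$W1)
      w$W2 <- as.matrix(w$W2)
      structure(
        list(
          hidden_size = as.integer(f$hidden_size), weights = w,
          learning_rate = f$learning_rate, seed = f$seed,
          epochs = as.integer(f$epochs), initial_sse = f$initial_sse,
          final_sse = f$final_sse, converged = f$converged
        ),
        class = "mlp_surrogate"
      )
    },
    svr_surrogate = {
      X <- as.matrix(f$X)
      colnames(X) <- input_names()
      models <- lapply(f$models, function(m) {
        m$support <- as.integer(m$support)
        m$objective_path <- numeric(0)
        m
      })
      structure(
        list(X = X, models = models[output_names()], gamma = f$gamma,
             C = f$C, epsilon = f$epsilon, tol = f$tol),
        class = "svr_surrogate"
      )
    },
    rf_surrogate = {
      X <- as.matrix(f$X)
      colnames(X) <- input_names()
      Y <- as.matrix(f$Y)
      colnames(Y) <- output_names()
      forests <- lapply(f$forests, function(fo) {
        list(trees = fo$trees, inbag = as.matrix(fo$inbag))
      })
      structure(
        list(forests = forests[output_names()], X = X, Y = Y,
             ntree = as.integer(f$ntree), mtry = as.integer(f$mtry),
             min_node_size = as.integer(f$min_node_size), seed = f$seed,
             bootstrap = f$bootstrap),
        class = "rf_surrogate"
      )
    },
    abort("unknown surrogate class in file")
  )
}
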