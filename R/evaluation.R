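#' Per-output mean absolute prediction error
#'
#' Column-wise mean of `|prediction - truth|` over the five outputs — the
#' "prediction error" used throughout the hold-out benchmarks.
#'
#' @param predictions,truth Data frames (or matrices) with the five
#'   output columns and equal row counts.
#' @return Named numeric vector of five mean absolute errors.
#' @export
mae_per_output <- function(predictions, truth) {
  P <- if (is.matrix(predictions)) predictions else output_matrix(predictions)
  Tr <- if (is.matrix(truth)) truth else output_matrix(truth)
  if (!all(dim(P) == dim(Tr))) {
    abort("`predictions` and `truth` must have identical shapes")
  }
  colMeans(abs(P - Tr))
}

#' Sum of prediction error
#'
#' Aggregates the five per-output mean absolute errors into the single
#' "sum of prediction error" column of the benchmark tables.
#'
#' @param values Numeric vector of five finite per-output errors.
#' @return Their sum.
#' @examples
#' sum_error(c(0.0561, 0.0419, 0.0407, 0.0142, 0.0368))
#' @export
sum_error <- function(values) {
  if (length(values) != 5 || !all(is.finite(values))) {
    abort("`values` must be 5 finite per-output errors")
  }
  sum(values)
}

#' Evaluate a fitted surrogate on a test table
#'
#' @param model A fitted surrogate.
#' @param test Test `sample_tbl`.
#' @param method Optional method label; defaults to the surrogate class.
#' @return A one-row `error_report` tibble: `method`, the five per-output
#'   mean absolute errors, and `sum_error`.
#' @export
evaluate_surrogate <- function(model, test, method = NULL) {
  method <- method %||% sub("_surrogate$", "", class(model)[1])
  mae <- mae_per_output(predict(model, test), test)
  new_error_report(method, mae)
}

new_error_report <- function(method, mae, extra = NULL) {
  row <- tibble::tibble(method = method)
  if (!is.null(extra)) row <- dplyr::bind_cols(row, extra)
  row <- dplyr::bind_cols(row, tibble::as_tibble(as.list(mae)))
  row$sum_error <- sum_error(unname(mae))
  class(row) <- c("error_report", class(row))
  row
}

#' Scan MLP hidden-layer sizes
#'
#' Fits one MLP per candidate hidden-layer size (common weight seed),
#' evaluates each on the test table, and selects the size minimizing the
#' sum of prediction error (ties resolve to the smaller size). The default
#' candidate list is the standard scan (1, 2, 4, 5, 6, 7, 8, 10, 11).
#'
#' @param train,test Training and test `sample_tbl`s.
#' @param sizes Candidate hidden-layer sizes.
#' @param seed Weight-initialization seed shared across fits.
#' @param ... Passed on to [fit_mlp()].
#' @return A `scan_result` tibble (one row per size) whose
#'   `"selected"` attribute holds the winning configuration.
#' @export
scan_mlp_hidden <- function(train, test, sizes = c(1, 2, 4, 5, 6, 7, 8, 10, 11),
                            seed = 1L, ...) {
  if (length(sizes) == 0) abort("`sizes` must be non-empty")
  rows <- purrr::map(sizes, function(h) {
    model <- fit_mlp(train, hidden_size = h, seed = seed, ...)
    new_error_report("mlp", mae_per_output(predict(model, test), test),
                     extra = tibble::tibble(hidden_size = h))
  })
  finish_scan(dplyr::bind_rows(rows), order_cols = "hidden_size")
}

#' Scan SVR kernel widths
#'
#' Evaluates one RBF support vector regression per candidate `gamma` and
#' selects the width minimizing the sum of prediction error (ties resolve
#' to the smaller gamma). The default candidates are the baseline 0.25
#' (inverse input dimension) together with 1, 0.1, 0.01 and 0.001.
#'
#' @param train,test Training and test `sample_tbl`s.
#' @param gammas Candidate kernel widths.
#' @param ... Passed on to [fit_svr()].
#' @return A `scan_result` tibble with attribute `"selected"`.
#' @export
scan_svr_gamma <- function(train, test, gammas = c(0.25, 1, 0.1, 0.01, 0.001),
                           ...) {
  if (length(gammas) == 0) abort("`gammas` must be non-empty")
  rows <- purrr::map(gammas, function(g) {
    model <- fit_svr(train, gamma = g, ...)
    new_error_report("svr", mae_per_output(predict(model, test), test),
                     extra = tibble::tibble(gamma = g))
  })
  finish_scan(dplyr::bind_rows(rows), order_cols = "gamma")
}

#' Scan random-forest size and split candidates
#'
#' Grid evaluation over `ntree` x `mtry`; the pair minimizing the sum of
#' prediction error wins, ties resolving to smaller `ntree` then smaller
#' `mtry`.
#'
#' @param train,test Training and test `sample_tbl`s.
#' @param ntrees,mtrys Candidate values.
#' @param seed RNG seed shared across fits.
#' @param ... Passed on to [fit_rf()].
#' @return A `scan_result` tibble with attribute `"selected"`.
#' @export
scan_rf <- function(train, test, ntrees = c(250, 500, 750, 1000),
                    mtrys = 1:4, seed = 1L, ...) {
  if (length(ntrees) == 0 || length(mtrys) == 0) {
    abort("`ntrees` and `mtrys` must be non-empty")
  }
  grid <- tidyr::expand_grid(ntree = ntrees, mtry = mtrys)
  rows <- purrr::pmap(grid, function(ntree, mtry) {
    model <- fit_rf(train, ntree = ntree, mtry = mtry, seed = seed, ...)
    new_error_report("rf", mae_per_output(predict(model, test), test),
                     extra = tibble::tibble(ntree = ntree, mtry = mtry))
  })
  finish_scan(dplyr::bind_rows(rows), order_cols = c("ntree", "mtry"))
}

# argmin sum_error with deterministic tie-break on the ordering columns
finish_scan <- function(tbl, order_cols) {
  ord <- do.call(order, c(list(tbl$sum_error), tbl[order_cols]))
  best <- tbl[ord[1], , drop = FALSE]
  structure(
    tbl,
    class = c("scan_result", class(tibble::tibble())),
    selected = as.list(best[c(order_cols, "sum_error")]),
    scan_over = order_cols
  )
}

#' @rdname scan_mlp_hidden
#' @param x A `scan_result`.
#' @export
scan_selection <- function(x) attr(x, "selected")

#' Assign samples to k folds
#'
#' Seeded shuffle followed by contiguous chunking into folds whose sizes
#' differ by at most one (the first `n %% k` folds get the extra sample).
#' Partitioning 625 samples into 10 folds yields five folds of 63 and
#' five of 62.
#'
#' @param n Number of samples.
#' @param k Number of folds, `2 <= k <= n`.
#' @param seed Integer RNG seed.
#' @return Integer vector of length `n` with fold labels in `1..k`.
#' @export
kfold_partition <- function(n, k = 10, seed = 1L) {
  if (k < 2 || k > n) abort("`k` must satisfy 2 <= k <= n")
  sizes <- rep(floor(n / k), k)
  extra <- n - sum(sizes)
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  perm <- withr::with_seed(seed, sample.int(n))
  fold <- integer(n)
  fold[perm] <- rep(seq_len(k), times = sizes)
  fold
}

fit_method <- function(method, train, seed, control = list()) {
  args <- c(list(train), control[[method]] %||% list())
  switch(method,
    linear = do.call(fit_linear, args),
    mlp = do.call(fit_mlp, c(args, list(seed = seed))),
    svr = do.call(fit_svr, args),
    rf = do.call(fit_rf, c(args, list(seed = seed))),
    abort(paste0("unknown method: ", method))
  )
}

#' k-fold cross-validation of a surrogate family
#'
#' Splits the table into `k` folds ([kfold_partition()]), fits the chosen
#' surrogate on each training complement and scores the held-out fold by
#' per-output mean squared error; fold MSEs are averaged into the summary
#' accuracy estimate.
#'
#' @param table A `sample_tbl` (typically the full normalized dataset).
#' @param method One of `"linear"`, `"mlp"`, `"svr"`, `"rf"`.
#' @param k Number of folds (default 10).
#' @param seed Seed for the fold shuffle and for seeded fits.
#' @param control Named list of extra arguments per method, e.g.
#'   `list(mlp = list(hidden_size = 7))`.
#' @return A `cv_report` tibble with one row per fold (per-output MSE),
#'   attributes `fold_assignment`, `method`, `seed`; see
#'   [glance.cv_report()] for the fold-averaged summary.
#' @export
cross_validate <- function(table, method = c("linear", "mlp", "svr", "rf"),
                           k = 10, seed = 1L, control = list()) {
  method <- match.arg(method)
  table <- as_sample_table(table, scaling = attr(table, "scaling"),
                           provenance = attr(table, "provenance"))
  fold <- kfold_partition(nrow(table), k, seed)
  rows <- purrr::map(seq_len(k), function(f) {
    train <- restamp(table[fold != f, ], table)
    test <- restamp(table[fold == f, ], table)
    model <- tryCatch(
      fit_method(method, train, seed = seed, control = control),
      error = function(e) {
        abort(paste0("fold ", f, ": ", conditionMessage(e)))
      }
    )
    mse <- colMeans((output_matrix(predict(model, test)) -
                       output_matrix(test))^2)
    dplyr::bind_cols(tibble::tibble(fold = f),
                     tibble::as_tibble(as.list(mse)))
  })
  out <- dplyr::bind_rows(rows)
  structure(
    out,
    class = c("cv_report", class(tibble::tibble())),
    fold_assignment = fold, method = method, seed = seed
  )
}

#' Noise-robustness benchmark
#'
#' Repeats the full benchmark at each relative noise level: the clean raw
#' dataset is normalized, multiplicative uniform noise of the given
#' half-width is injected into all outputs (whole table, before
#' splitting), the table is re-split with the same split seed, all four
#' surrogates are refit and scored on the (noisy) test outputs. Level 0
#' reproduces the noise-free benchmark exactly.
#'
#' @param params [kinetic_params()] for the generator.
#' @param levels Noise half-widths; the default (0, 0.005, 0.01) covers
#'   the clean, +/-0.5% and +/-1% protocols.
#' @param n_train Training-set size.
#' @param seed Master seed (split/fit/noise seeds derive from it).
#' @param control Per-method argument list as in [cross_validate()].
#' @param methods Methods to include.
#' @param data Optional pre-built clean normalized `sample_tbl`,
#'   bypassing the generator run.
#' @return A `noise_report` tibble: one `error_report` row per
#'   (level, method).
#' @export
noise_robustness <- function(params = kinetic_params(),
                             levels = c(0, 0.005, 0.01),
                             n_train = 100, seed = 1L,
                             control = list(),
                             methods = c("linear", "mlp", "svr", "rf"),
                             data = NULL) {
  if (!0 %in% levels) abort("`levels` must include 0 (the clean baseline)")
  clean <- data %||% normalize_outputs(build_dataset(generate_grid(), params))
  rows <- purrr::map(levels, function(a) {
    noisy <- add_output_noise(clean, a, seed = seed + 3L)
    parts <- split_samples(noisy, n_train = n_train, seed = seed)
    purrr::map(methods, function(m) {
      model <- fit_method(m, parts$train, seed = seed + 1L, control = control)
      rep <- evaluate_surrogate(model, parts$test, method = m)
      dplyr::bind_cols(tibble::tibble(noise = a), rep)
    }) |> dplyr::bind_rows()
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("noise_report", "error_report", class(tibble::tibble()))
  out
}

#' Measure surrogate training and prediction time
#'
#' Times `fit` and `predict` for each method with `proc.time()`, reporting
#' the median over `repeats` of both elapsed (wall-clock) and process
#' (user + system CPU) seconds. Timings are hardware-dependent
#' diagnostics, not comparable across machines.
#'
#' @param train,test Training and test `sample_tbl`s.
#' @param methods Methods to time.
#' @param repeats Number of repetitions (>= 1).
#' @param seed Seed passed to seeded fits.
#' @param control Per-method argument list as in [cross_validate()].
#' @return A tibble with one row per method: train/test elapsed and
#'   process seconds.
#' @export
measure_runtime <- function(train, test,
                            methods = c("linear", "mlp", "svr", "rf"),
                            repeats = 1, seed = 1L, control = list()) {
  if (repeats < 1) abort("`repeats` must be >= 1")
  take <- function(expr) {
    tm <- system.time(expr)
    c(process = unname(tm[1] + tm[2]), elapsed = unname(tm[3]))
  }
  rows <- purrr::map(methods, function(m) {
    tr <- matrix(0, repeats, 2)
    te <- matrix(0, repeats, 2)
    for (r in seq_len(repeats)) {
      model <- NULL
      tr[r, ] <- take(model <- fit_method(m, train, seed, control))
      te[r, ] <- take(predict(model, test))
    }
    tibble::tibble(
      method = m,
      train_process = median(tr[, 1]), train_elapsed = median(tr[, 2]),
      test_process = median(te[, 1]), test_elapsed = median(te[, 2])
    )
  })
  dplyr::bind_rows(rows)
}

#' Run the standard surrogate benchmark
#'
#' End-to-end protocol: generate the 625-point steady-state grid dataset,
#' min-max normalize, split into 100 training / 525 test samples, fit the
#' four surrogate families with their selected hyperparameters, and score
#' each on the test set.
#'
#' @param params [kinetic_params()] for the generator.
#' @param seed Master seed. Component seeds derive from it (split =
#'   `seed`, MLP init = `seed + 1`, RF bootstrap = `seed + 2`).
#' @param n_train Training-set size (default 100 of 625).
#' @param methods Surrogate families to include.
#' @param control Per-method argument list as in [cross_validate()],
#'   overriding the defaults (MLP hidden 7; SVR gamma 0.25; RF 1000x4).
#' @param data Optional pre-built normalized `sample_tbl`, to reuse the
#'   generator output across seeds.
#' @return A list of class `benchmark_result`: `train`, `test`, fitted
#'   `models`, and `errors` (an `error_report` with one row per method).
#' @export
run_benchmark <- function(params = kinetic_params(), seed = 1L,
                          n_train = 100,
                          methods = c("linear", "mlp", "svr", "rf"),
                          control = list(), data = NULL) {
  if (is.null(data)) {
    data <- normalize_outputs(build_dataset(generate_grid(), params))
  }
  parts <- split_samples(data, n_train = n_train, seed = seed)
  models <- list()
  for (m in methods) {
    fit_seed <- if (m == "mlp") seed + 1L else seed + 2L
    models[[m]] <- fit_method(m, parts$train, seed = fit_seed,
                              control = control)
  }
  errors <- dplyr::bind_rows(purrr::imap(
    models, function(mod, m) evaluate_surrogate(mod, parts$test, method = m)
  ))
  class(errors) <- c("error_report", class(tibble::tibble()))
  structure(
    list(train = parts$train, test = parts$test, models = models,
         errors = errors, seed = seed),
    class = "benchmark_result"
  )
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf(
    "<benchmark_result> %d train / %d test samples (seed %s)\n",
    nrow(x$train), nrow(x$test), format(x$seed)
  ))
  print(tibble::as_tibble(x$errors))
  invisible(x)
}
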