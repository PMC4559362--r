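#' Sample tables of paired cytokine inputs and steady-state outputs
#'
#' A `sample_tbl` is a tibble with the four input columns (`IFNg`, `IL12`,
#' `IL6`, `TGFb`) followed by the five output columns (`IL17`, `RORgt`,
#' `IFNg_out`, `Tbet`, `FOXP3`), carrying two attributes:
#' `scaling` — a per-output tibble of the (min, max) used by
#' [normalize_outputs()], or `NULL` on the raw scale — and `provenance`,
#' a list recording how the table was produced (generator, seeds, noise
#' level).
#'
#' @param data Data frame containing the nine canonical columns.
#' @param scaling Optional scaling tibble (columns `output`, `min`, `max`).
#' @param provenance Named list of provenance fields.
#' @return A tibble of class `sample_tbl`.
#' @export
as_sample_table <- function(data, scaling = NULL, provenance = list()) {
  check_columns(data, c(input_names(), output_names()))
  out <- tibble::as_tibble(data)[c(input_names(), output_names())]
  if (any(!is.finite(as.matrix(out)))) {
    abort("sample tables must not contain missing or non-finite values")
  }
  if (!is.null(scaling)) {
    stopifnot(is.data.frame(scaling),
              all(c("output", "min", "max") %in% names(scaling)))
    scaling <- tibble::as_tibble(scaling)
  }
  structure(out,
    class = c("sample_tbl", class(tibble::tibble())),
    scaling = scaling, provenance = provenance
  )
}

#' @export
print.sample_tbl <- function(x, ...) {
  prov <- attr(x, "provenance")
  cat(sprintf(
    "<sample_tbl> %d samples, %s scale\n", nrow(x),
    if (is.null(attr(x, "scaling"))) "raw" else "normalized"
  ))
  if (length(prov) > 0) {
    cat("  provenance:",
        paste(names(prov), unlist(prov), sep = "=", collapse = ", "), "\n")
  }
  NextMethod()
}

#' @rdname as_sample_table
#' @param x A `sample_tbl`.
#' @export
sample_scaling <- function(x) attr(x, "scaling")

#' @rdname as_sample_table
#' @export
sample_provenance <- function(x) attr(x, "provenance")

# rebuild a sample_tbl from a plain tibble, carrying metadata over
restamp <- function(data, template, ...) {
  prov <- utils::modifyList(attr(template, "provenance") %||% list(),
                            list(...))
  as_sample_table(data, scaling = attr(template, "scaling"),
                  provenance = prov)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

unclass_sample <- function(x) {
  x <- as.data.frame(x)
  attr(x, "scaling") <- NULL
  attr(x, "provenance") <- NULL
  x
}

#' Read and write sample tables as CSV
#'
#' The on-disk dialect is a comma-separated file with '.' decimal marks and
#' the exact header `IFNg,IL12,IL6,TGFb,IL17,RORgt,IFNg_out,Tbet,FOXP3`;
#' scientific notation is accepted. Values round-trip at full double
#' precision. Scaling and provenance metadata travel in a JSON sidecar
#' (`<path>.json`) written alongside the CSV when present.
#'
#' @param path CSV file path.
#' @param table A `sample_tbl`.
#' @return `read_sample_csv()` returns a `sample_tbl`;
#'   `write_sample_csv()` returns `path` invisibly.
#' @export
read_sample_csv <- function(path) {
  expected <- c(input_names(), output_names())
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (!identical(names(raw), expected)) {
    abort(paste0(
      "expected columns ", paste(expected, collapse = ","),
      " but found ", paste(names(raw), collapse = ",")
    ))
  }
  parsed <- raw
  for (cl in expected) {
    vals <- suppressWarnings(as.numeric(raw[[cl]]))
    bad <- which(is.na(vals) & !is.na(raw[[cl]]))
    if (length(bad) > 0) {
      abort(sprintf(
        "non-numeric value '%s' at row %d, column %s",
        raw[[cl]][bad[1]], bad[1], cl
      ))
    }
    if (anyNA(vals)) {
      abort(sprintf("missing value at row %d, column %s",
                    which(is.na(vals))[1], cl))
    }
    parsed[[cl]] <- vals
  }
  scaling <- NULL
  provenance <- list()
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$scaling)) scaling <- tibble::as_tibble(meta$scaling)
    if (!is.null(meta$provenance)) provenance <- as.list(meta$provenance)
  }
  as_sample_table(parsed, scaling = scaling, provenance = provenance)
}

#' @rdname read_sample_csv
#' @export
write_sample_csv <- function(table, path) {
  table <- as_sample_table(table, scaling = attr(table, "scaling"),
                           provenance = attr(table, "provenance"))
  out <- tibble::as_tibble(unclass_sample(table))
  readr::write_csv(out, path, progress = FALSE)
  scaling <- attr(table, "scaling")
  provenance <- attr(table, "provenance")
  if (!is.null(scaling) || length(provenance) > 0) {
    jsonlite::write_json(
      list(scaling = scaling, provenance = provenance),
      paste0(path, ".json"),
      auto_unbox = TRUE, digits = NA, null = "null"
    )
  }
  invisible(path)
}
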