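#' Construct a response dataset
#'
#' A response dataset is a tibble of drug-response records keyed by
#' (cell line, drug). Multiple records for the same pair are retained and
#' treated as replicates; each record keeps a stable `.row_id` so replicates
#' stay distinguishable. Exactly one response measure (e.g. `LN_IC50`, `AUC`)
#' is attached to the whole dataset: models benchmarked together must predict
#' the same measure.
#'
#' @param records A data frame with columns `cell_line_id`, `drug_id` and
#'   `response`; optionally `tissue` and `quality_p`. Rows with missing
#'   `response` are dropped (with a message reporting the count).
#' @param measure Name of the response measure, e.g. `"LN_IC50"`, `"IC50"`,
#'   `"EC50"`, `"pEC50"`, `"AUC"`, or a custom label.
#' @param name Dataset label used in outputs.
#' @return A tibble of class `drb_response` with columns `cell_line_id`,
#'   `drug_id`, `tissue`, `response`, `quality_p`, `.row_id`, and attributes
#'   `measure` and `dataset_name`.
#' @export
#' @examples
#' response_dataset(
#'   tibble::tibble(
#'     cell_line_id = c("c1", "c1", "c2"),
#'     drug_id = c("dX", "dY", "dX"),
#'     response = c(1, 3, 2)
#'   ),
#'   measure = "LN_IC50"
#' )
response_dataset <- function(records, measure, name = "dataset") {
  stopifnot(is.data.frame(records))
  required <- c("cell_line_id", "drug_id", "response")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    abort(sprintf(
      "Response records lack required column(s): %s.",
      paste(missing_cols, collapse = ", ")
    ))
  }
  if (!is.character(measure) || length(measure) != 1L || !nzchar(measure)) {
    abort("`measure` must be a single non-empty string.")
  }
  out <- tibble::as_tibble(records)
  if (!"tissue" %in% names(out)) out$tissue <- NA_character_
  if (!"quality_p" %in% names(out)) out$quality_p <- NA_real_
  out$cell_line_id <- as.character(out$cell_line_id)
  out$drug_id <- as.character(out$drug_id)
  out$tissue <- as.character(out$tissue)
  out$response <- as.numeric(out$response)
  out$quality_p <- as.numeric(out$quality_p)

  n_dropped <- sum(!is.finite(out$response))
  if (n_dropped > 0) {
    out <- out[is.finite(out$response), , drop = FALSE]
    inform(sprintf("Dropped %d record(s) with missing response value.", n_dropped))
  }
  if (nrow(out) == 0) abort("Response dataset has no records with a finite response.")

  out <- out[, c("cell_line_id", "drug_id", "tissue", "response", "quality_p")]
  out$.row_id <- seq_len(nrow(out))
  structure(
    out,
    measure = measure,
    dataset_name = name,
    n_dropped = n_dropped,
    class = c("drb_response", class(tibble::tibble()))
  )
}

#' @export
print.drb_response <- function(x, ...) {
  cat(sprintf(
    "<drb_response '%s': %d records, %d cell lines x %d drugs, measure %s>\n",
    attr(x, "dataset_name"), nrow(x),
    dplyr::n_distinct(x$cell_line_id), dplyr::n_distinct(x$drug_id),
    attr(x, "measure")
  ))
  NextMethod()
}

#' @rdname response_dataset
#' @param x A `drb_response` object.
#' @export
response_measure <- function(x) attr(x, "measure")

#' Read a response table from delimited text
#'
#' Expects a CSV with header columns `cell_line_id`, `drug_id`, the measure
#' column (named after `measure`), and optionally `tissue` and `quality_p`.
#' Rows whose measure value is empty are dropped and counted. Duplicate
#' (cell line, drug) rows are kept as replicates of the pair.
#'
#' @param path Path to a CSV file.
#' @param measure Name of the measure column to read as the response.
#' @param name Dataset label; defaults to the file name.
#' @return A [response_dataset()].
#' @export
read_response_table <- function(path, measure, name = NULL) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(tab) == 0) abort(sprintf("Response table %s is empty.", path))
  for (col in c("cell_line_id", "drug_id", measure)) {
    if (!col %in% names(tab)) {
      abort(sprintf("Response table %s lacks required column '%s'.", path, col))
    }
  }
  tab$response <- as.numeric(tab[[measure]])
  response_dataset(
    tab[, intersect(c("cell_line_id", "drug_id", "tissue", "response", "quality_p"),
                    names(tab))],
    measure = measure,
    name = name %||% basename(path)
  )
}

#' Write a response dataset back to CSV
#'
#' Inverse of [read_response_table()]: the measure column carries the
#' dataset's measure name, so write-then-read reproduces records, measure and
#' order exactly.
#'
#' @param dataset A `drb_response`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_response_table <- function(dataset, path) {
  stopifnot(inherits(dataset, "drb_response"))
  out <- tibble::tibble(
    cell_line_id = dataset$cell_line_id,
    drug_id = dataset$drug_id,
    tissue = dataset$tissue
  )
  out[[response_measure(dataset)]] <- dataset$response
  if (any(!is.na(dataset$quality_p))) out$quality_p <- dataset$quality_p
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Filter records by curve-fit quality
#'
#' Removes records whose dose-response curve fit p-value (`quality_p`)
#' exceeds `alpha`. With `alpha = NULL` (the default used in benchmarking, to
#' avoid data loss) the dataset is returned unchanged. Idempotent for a fixed
#' `alpha`.
#'
#' @param dataset A `drb_response`.
#' @param alpha Significance threshold in (0, 1], or `NULL` for no filtering.
#' @return The filtered `drb_response`.
#' @export
filter_by_curve_quality <- function(dataset, alpha = NULL) {
  stopifnot(inherits(dataset, "drb_response"))
  if (is.null(alpha)) return(dataset)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1) {
    abort("`alpha` must be a single value in (0, 1], or NULL.")
  }
  if (any(is.na(dataset$quality_p))) {
    abort("Quality filtering requested but `quality_p` is missing for some records.")
  }
  keep <- dataset$quality_p <= alpha
  out <- dataset[keep, , drop = FALSE]
  if (nrow(out) == 0) abort("Quality filter removed every record.")
  attr(out, "measure") <- attr(dataset, "measure")
  attr(out, "dataset_name") <- attr(dataset, "dataset_name")
  class(out) <- class(dataset)
  out
}
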