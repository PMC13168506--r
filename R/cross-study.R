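# Cross-study evaluation: models trained on one screen predict another.
# Records of the external screen that overlap the training data per the
# split-mode's notion of "seen" are excluded first, so the external metric
# measures genuine transfer rather than recall.

#' Exclude external records overlapping a training set
#'
#' Removes from the external dataset the records the trained model has, in
#' the sense of its split mode, already seen: under LPO the training
#' (cell line, drug) pairs; under LCO the training cell lines; under LTO
#' the training tissues; under LDO the training drugs. Idempotent, and the
#' filtered set is always a subset of the external records.
#'
#' @param train Training response records (tibble or [response_dataset()]).
#' @param external External response dataset (same measure as training).
#' @param mode Split mode.
#' @return The filtered external records, with attribute `"n_removed"`.
#' @export
cross_study_filter <- function(train, external, mode = c("LPO", "LCO", "LTO", "LDO")) {
  mode <- match.arg(mode)
  m_train <- attr(train, "measure")
  m_ext <- attr(external, "measure")
  if (!is.null(m_train) && !is.null(m_ext) && !identical(m_train, m_ext)) {
    abort(sprintf("Measure mismatch: training uses %s, external uses %s.",
                  m_train, m_ext))
  }
  train <- tibble::as_tibble(train)
  ext <- tibble::as_tibble(external)
  seen <- if (mode == "LPO") {
    !(pair_key(ext$cell_line_id, ext$drug_id) %in%
        pair_key(train$cell_line_id, train$drug_id))
  } else {
    col <- group_column(mode)
    !(ext[[col]] %in% unique(train[[col]]))
  }
  out <- ext[seen, , drop = FALSE]
  attr(out, "n_removed") <- sum(!seen)
  out
}

#' Evaluate fold-trained models on external datasets
#'
#' For every cross-validation fold of a benchmark run (executed with
#' `keep_models = TRUE`) and every external dataset: filters the external
#' records against that fold's training records per the split mode,
#' predicts the survivors, and computes the per-fold metric suite (plain
#' and normalized). The normalization reference is a mean-effects naive
#' model fitted on the same fold's training records and applied to the same
#' filtered external records, so the naive reference is evaluated under
#' identical conditions. External datasets left empty after filtering are
#' skipped with a warning.
#'
#' @param cv A `drb_cv` from [run_cross_validation()] with
#'   `keep_models = TRUE`.
#' @param externals A named list of [response_dataset()]s.
#' @param features Named list of [feature_set()]s covering the external
#'   entities (records lacking required features are dropped with counts).
#' @return A tibble: one metric-suite row per model x fold x external
#'   dataset x normalization, including rows for the
#'   `naive_mean_effects_reference`.
#' @export
cross_study_evaluate <- function(cv, externals, features = list()) {
  stopifnot(inherits(cv, "drb_cv"))
  if (is.null(cv$models)) {
    abort("Run the benchmark with keep_models = TRUE to enable cross-study evaluation.")
  }
  if (inherits(externals, "drb_response")) externals <- list(external = externals)
  if (is.null(names(externals))) {
    names(externals) <- paste0("external_", seq_along(externals))
  }

  out <- list()
  for (ext_name in names(externals)) {
    external <- externals[[ext_name]]
    for (f in seq_len(cv$k)) {
      train <- cv$records[cv$records$.row_id %in% cv$train_rows[[f]], , drop = FALSE]
      filtered <- cross_study_filter(train, external, cv$mode)
      if (nrow(filtered) == 0) {
        warn(sprintf(
          "External dataset '%s' shares no unseen records with fold %d training data; skipped.",
          ext_name, f
        ))
        next
      }
      naive_ref <- fit_naive(train, "mean_effects")
      y_naive <- predict_naive(naive_ref, "mean_effects", filtered)

      eval_one <- function(name, pred, records, y_naive) {
        dplyr::bind_rows(
          dplyr::mutate(compute_metric_suite(records$response, pred),
                        normalized = FALSE),
          dplyr::mutate(
            normalized_metric_suite(records$response, pred, y_naive),
            normalized = TRUE
          )
        ) %>%
          dplyr::mutate(model = name, fold = f, dataset = ext_name,
                        n_removed = attr(filtered, "n_removed"), .before = 1)
      }

      out[[length(out) + 1L]] <- eval_one(
        "naive_mean_effects_reference", y_naive, filtered, y_naive
      )
      for (model_name in names(cv$models)) {
        spec <- cv$model_specs[[model_name]]
        m_ext <- drop_missing_features(filtered, spec, features)
        if (nrow(m_ext) == 0) next
        idx <- match(m_ext$.row_id, filtered$.row_id)
        pred <- spec$predict(cv$models[[model_name]][[f]], m_ext, features)
        ok <- is.finite(pred)
        out[[length(out) + 1L]] <- eval_one(
          model_name, pred[ok], m_ext[ok, , drop = FALSE], y_naive[idx][ok]
        )
      }
    }
  }
  if (length(out) == 0) {
    abort("No external dataset yielded any evaluable records.")
  }
  dplyr::bind_rows(out)
}
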