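# Benchmark executor: folds -> tune -> fit -> predict, with runtime leakage
# guards. For every fold the grouping keys of the test records must be
# invisible to everything that touched training data; this is asserted, not
# assumed.

assert_no_leakage <- function(train, test, mode) {
  col <- group_column(mode)
  overlap <- if (mode == "LPO") {
    intersect(pair_key(train$cell_line_id, train$drug_id),
              pair_key(test$cell_line_id, test$drug_id))
  } else {
    intersect(unique(train[[col]]), unique(test[[col]]))
  }
  if (length(overlap) > 0) {
    abort(sprintf(
      "Leakage guard: %d %s group(s) appear in both train and test.",
      length(overlap), mode
    ))
  }
  invisible(TRUE)
}

drop_missing_features <- function(records, spec, features) {
  keep <- rep(TRUE, nrow(records))
  for (mod in spec$required_modalities) {
    fs <- features[[mod]]
    if (is.null(fs)) abort(sprintf("Feature modality '%s' not supplied.", mod))
    covered <- feature_entities(fs)
    if (length(covered) == 0) next # shared graph: no per-entity coverage
    ids <- if (fs$entity_kind == "cell_line") records$cell_line_id else records$drug_id
    keep <- keep & ids %in% covered
  }
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    inform(sprintf(
      "Model '%s': dropped %d record(s) lacking required features.",
      spec$name, n_dropped
    ))
  }
  records[keep, , drop = FALSE]
}

fit_for_fold <- function(spec, train, mode, features, val_fraction, seed) {
  if (length(spec$grid) > 1) {
    tuned <- grid_search_tune(spec, train, mode, features,
                              val_fraction = val_fraction, seed = seed)
    list(fitted = tuned$fitted, hyper = tuned$hyper, val_rmse = tuned$val_rmse)
  } else {
    hyper <- if (length(spec$grid) == 1) spec$grid[[1]] else list()
    ctx <- list(es_validation = NULL)
    if (spec$needs_early_stopping) {
      parts <- make_inner_split(train, mode, val_fraction = val_fraction,
                                seed = seed, early_stopping = TRUE)
      ctx$es_validation <- parts$es_validation
      train <- parts$train
    }
    list(fitted = spec$fit(train, features, hyper, seed, ctx),
         hyper = hyper, val_rmse = NA_real_)
  }
}

#' Run a cross-validated benchmark
#'
#' Splits the dataset per the chosen mode, then per fold and model: tunes on
#' an inner holdout (for models with a grid), fits, and predicts the test
#' fold. A mean-effects naive predictor is fitted on every fold's training
#' records as the normalization reference, and its test predictions are
#' carried in the `y_naive` column. Models that cannot predict unseen drugs
#' are excluded from LDO runs with a warning.
#'
#' @param dataset A [response_dataset()].
#' @param models A list of [model_spec()]s.
#' @param mode Split mode (see [make_folds()]).
#' @param k Number of folds.
#' @param seed Root seed for folds, tuning splits and model fits.
#' @param features Named list of [feature_set()]s.
#' @param val_fraction Inner-validation fraction for tuning.
#' @param keep_models Keep fitted per-fold models in the result (needed for
#'   [cross_study_evaluate()] and [run_ablation()] reuse).
#' @return An object of class `drb_cv` with elements `predictions` (tibble:
#'   `model`, `fold`, `cell_line_id`, `drug_id`, `tissue`, `y_true`,
#'   `y_pred`, `y_naive`), `folds`, `mode`, `k`, `seed`, `measure`,
#'   `hyper` (chosen configuration per model x fold), and (optionally)
#'   `models` plus per-fold `train_rows`.
#' @export
#' @examples
#' sim <- generate_response_dataset(synthetic_config(
#'   n_cell_lines = 30, n_drugs = 10, completeness = 0.8, seed = 1
#' ))
#' cv <- run_cross_validation(
#'   sim$dataset, models = list(naive_model("overall"), naive_model("mean_effects")),
#'   mode = "LCO", k = 3, seed = 1
#' )
#' head(cv$predictions)
run_cross_validation <- function(dataset, models, mode = c("LPO", "LCO", "LTO", "LDO"),
                                 k = 10, seed = 1, features = list(),
                                 val_fraction = 0.1, keep_models = FALSE) {
  mode <- match.arg(mode)
  if (inherits(models, "drb_model_spec")) models <- list(models)
  names(models) <- vapply(models, `[[`, character(1), "name")
  if (anyDuplicated(names(models))) abort("Model names must be unique within a run.")

  if (mode == "LDO") {
    excluded <- names(models)[!vapply(models, `[[`, logical(1), "predicts_unseen_drugs")]
    if (length(excluded) > 0) {
      warn(sprintf(
        "Excluding from LDO (cannot predict unseen drugs): %s.",
        paste(excluded, collapse = ", ")
      ))
      models <- models[setdiff(names(models), excluded)]
    }
  }
  if (length(models) == 0) abort("No models left to benchmark.")

  records <- tibble::as_tibble(dataset)
  if (!".row_id" %in% names(records)) records$.row_id <- seq_len(nrow(records))
  folds <- make_folds(records, mode, k = k, seed = seed)
  fold_of <- setNames(folds$fold, folds$.row_id)

  preds <- list()
  hyper_log <- list()
  fitted_models <- if (keep_models) list()
  train_rows <- list()

  for (f in seq_len(k)) {
    test <- records[fold_of[as.character(records$.row_id)] == f, , drop = FALSE]
    train <- records[fold_of[as.character(records$.row_id)] != f, , drop = FALSE]
    assert_no_leakage(train, test, mode)
    train_rows[[f]] <- train$.row_id

    naive_ref <- fit_naive(train, "mean_effects")
    y_naive <- predict_naive(naive_ref, "mean_effects", test)

    for (spec in models) {
      m_train <- drop_missing_features(train, spec, features)
      m_test <- drop_missing_features(test, spec, features)
      naive_idx <- match(m_test$.row_id, test$.row_id)
      fold_seed <- derive_seed(seed, "fit", spec$name, f)
      fit <- fit_for_fold(spec, m_train, mode, features, val_fraction, fold_seed)
      y_pred <- spec$predict(fit$fitted, m_test, features)
      if (length(y_pred) != nrow(m_test)) {
        abort(sprintf("Model '%s' returned %d predictions for %d test records.",
                      spec$name, length(y_pred), nrow(m_test)))
      }
      n_na <- sum(!is.finite(y_pred))
      if (n_na > 0) {
        warn(sprintf(
          "Model '%s', fold %d: %d unpredictable test record(s) dropped.",
          spec$name, f, n_na
        ))
      }
      ok <- is.finite(y_pred)
      preds[[length(preds) + 1L]] <- tibble::tibble(
        model = spec$name, fold = f,
        cell_line_id = m_test$cell_line_id[ok], drug_id = m_test$drug_id[ok],
        tissue = m_test$tissue[ok], y_true = m_test$response[ok],
        y_pred = y_pred[ok], y_naive = y_naive[naive_idx][ok]
      )
      hyper_log[[length(hyper_log) + 1L]] <- tibble::tibble(
        model = spec$name, fold = f,
        hyper = list(fit$hyper)
      )
      if (keep_models) fitted_models[[spec$name]][[f]] <- fit$fitted
    }
  }

  structure(
    list(
      predictions = dplyr::bind_rows(preds),
      hyper = dplyr::bind_rows(hyper_log),
      folds = folds, mode = mode, k = as.integer(k), seed = as.integer(seed),
      measure = attr(dataset, "measure") %||% "response",
      dataset_name = attr(dataset, "dataset_name") %||% "dataset",
      records = records, train_rows = train_rows,
      models = if (keep_models) fitted_models,
      model_specs = models
    ),
    class = "drb_cv"
  )
}

#' @export
print.drb_cv <- function(x, ...) {
  cat(sprintf(
    "<drb_cv: %s, k = %d, %d model(s), %d predictions on '%s' (%s)>\n",
    x$mode, x$k, length(unique(x$predictions$model)), nrow(x$predictions),
    x$dataset_name, x$measure
  ))
  invisible(x)
}

#' Tidy a benchmark run into its prediction table
#'
#' @param x A `drb_cv`.
#' @param ... Unused.
#' @return The predictions tibble.
#' @method tidy drb_cv
#' @export
tidy.drb_cv <- function(x, ...) x$predictions

#' @rdname tidy.drb_cv
#' @return For `glance`: one row per model with mean per-fold MSE and R2.
#' @method glance drb_cv
#' @export
glance.drb_cv <- function(x, ...) {
  fold_metrics(x$predictions) %>%
    dplyr::filter(!.data$normalized) %>%
    dplyr::group_by(.data$model) %>%
    dplyr::summarise(
      mse = mean(.data$mse), rmse = mean(.data$rmse), r2 = mean(.data$r2),
      n_folds = dplyr::n(), .groups = "drop"
    )
}
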