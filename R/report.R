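# One-command benchmark execution from a YAML configuration, with CSV
# outputs and a self-describing output directory (resolved config + seeds
# + package version are echoed next to the results).

builtin_model_registry <- function() {
  list(
    naive_overall = function(opts) naive_model("overall"),
    naive_drug_mean = function(opts) naive_model("drug_mean"),
    naive_cell_line_mean = function(opts) naive_model("cell_line_mean"),
    naive_tissue_mean = function(opts) naive_model("tissue_mean"),
    naive_mean_effects = function(opts) naive_model("mean_effects"),
    linear = function(opts) do.call(linear_model, opts),
    random_forest = function(opts) do.call(forest_model, opts),
    per_drug_linear = function(opts) do.call(per_drug_linear_model, opts)
  )
}

resolve_models <- function(entries) {
  registry <- builtin_model_registry()
  lapply(entries, function(entry) {
    if (is.character(entry)) {
      name <- entry
      opts <- list()
    } else {
      name <- entry$name
      opts <- entry[setdiff(names(entry), "name")]
    }
    builder <- registry[[name]]
    if (is.null(builder)) {
      abort(sprintf("Unknown model '%s'. Known models: %s.", name,
                    paste(names(registry), collapse = ", ")))
    }
    builder(opts)
  })
}

validate_config <- function(config) {
  violations <- character(0)
  need <- function(cond, msg) if (!isTRUE(cond)) violations <<- c(violations, msg)
  need(is.list(config$dataset), "config needs a `dataset` block (path or synthetic)")
  if (is.list(config$dataset)) {
    need(!is.null(config$dataset$path) || is.list(config$dataset$synthetic),
         "`dataset` needs either `path` or a `synthetic` block")
    if (!is.null(config$dataset$path)) {
      need(is.character(config$dataset$measure %||% NULL),
           "`dataset.measure` is required when loading from a file")
    }
  }
  need(length(config$models %||% list()) >= 1, "config needs at least one model")
  mode <- config$mode %||% "LPO"
  need(mode %in% c("LPO", "LCO", "LTO", "LDO"),
       sprintf("`mode` must be LPO, LCO, LTO or LDO (got '%s')", mode))
  k <- config$k %||% 10
  need(is.numeric(k) && k >= 2, "`k` must be an integer >= 2")
  registry <- names(builtin_model_registry())
  for (entry in config$models %||% list()) {
    nm <- if (is.character(entry)) entry else entry$name %||% "<unnamed>"
    need(nm %in% registry, sprintf("unknown model '%s'", nm))
  }
  if (length(violations) > 0) {
    abort(paste0("Invalid configuration:\n", paste("-", violations, collapse = "\n")))
  }
  invisible(TRUE)
}

#' Run a benchmark from a configuration file
#'
#' Reads a YAML configuration (or takes an equivalent named list), validates
#' it fully before any compute, executes splitting, tuning, prediction,
#' metrics and rank statistics (plus ablation and cross-study blocks when
#' requested), and writes all outputs to the output directory. The resolved
#' configuration, seed and package version are echoed into the directory so
#' a run is reproducible from its outputs alone.
#'
#' @param config Path to a YAML file, or a named list.
#' @param out_dir Output directory (created if absent); overrides
#'   `config$out`.
#' @return The output directory path, invisibly; the in-memory results as
#'   attribute `"results"`.
#' @export
run_from_config <- function(config, out_dir = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) abort(sprintf("Config file not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  validate_config(config)
  out_dir <- out_dir %||% config$out %||% "drbench_run"
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  log_line <- function(fmt, ...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                   sprintf(fmt, ...))
    cat(msg, "\n", sep = "")
    cat(msg, "\n", sep = "", file = log_path, append = TRUE)
  }

  seed <- as.integer(config$seed %||% 1)
  mode <- config$mode %||% "LPO"
  k <- as.integer(config$k %||% 10)

  # Dataset (and features for synthetic runs)
  features <- list()
  truth <- NULL
  if (!is.null(config$dataset$path)) {
    dataset <- read_response_table(config$dataset$path, config$dataset$measure)
    log_line("Loaded %d records from %s.", nrow(dataset), config$dataset$path)
    for (feat in config$features %||% list()) {
      fs <- if (identical(feat$kind, "graph")) {
        read_edge_list(feat$path, feat$modality, feat$entity_kind)
      } else {
        read_feature_matrix(feat$path, feat$modality, feat$entity_kind)
      }
      features[[feat$modality]] <- fs
    }
  } else {
    syn_args <- config$dataset$synthetic
    syn_args$seed <- syn_args$seed %||% seed
    cfg <- do.call(synthetic_config, syn_args)
    sim <- generate_response_dataset(cfg)
    dataset <- sim$dataset
    truth <- sim$truth
    features <- generate_features(cfg)
    log_line("Generated synthetic dataset: %d records (%d cell lines x %d drugs).",
             nrow(dataset), cfg$n_cell_lines, cfg$n_drugs)
  }
  alpha_q <- config$dataset$quality_alpha %||% NULL
  if (!is.null(alpha_q)) {
    n_before <- nrow(dataset)
    dataset <- filter_by_curve_quality(dataset, alpha_q)
    log_line("Quality filter (alpha = %g) removed %d record(s).",
             alpha_q, n_before - nrow(dataset))
  }

  models <- resolve_models(config$models)
  need_cross_study <- is.list(config$cross_study)
  log_line("Running %s benchmark: k = %d, seed = %d, %d model(s).",
           mode, k, seed, length(models))
  cv <- run_cross_validation(
    dataset, models, mode = mode, k = k, seed = seed, features = features,
    val_fraction = config$val_fraction %||% 0.1,
    keep_models = need_cross_study
  )
  metrics <- fold_metrics(cv$predictions)
  strat <- dplyr::bind_rows(
    stratified_metrics(cv$predictions, "drug"),
    stratified_metrics(cv$predictions, "cell_line")
  )
  rank_stats <- if (length(unique(cv$predictions$model)) >= 2) {
    compare_models(metrics, alpha = config$alpha %||% 0.05)
  }

  results <- list(cv = cv, metrics = metrics, stratified = strat,
                  rank_stats = rank_stats)

  if (is.list(config$ablation)) {
    ab <- config$ablation
    model <- resolve_models(list(ab$model))[[1]]
    results$ablation <- run_ablation(
      dataset, model, features,
      modalities = ab$modalities %||% model$required_modalities,
      method = ab$method %||% "permute",
      mode = mode, k = k, seed = seed
    )
    log_line("Ablation (%s) done for %d modality(ies).",
             ab$method %||% "permute", nrow(results$ablation))
  }
  if (need_cross_study) {
    externals <- lapply(config$cross_study$paths, function(p) {
      read_response_table(p, config$dataset$measure %||% response_measure(dataset))
    })
    results$cross_study <- cross_study_evaluate(cv, externals, features)
    log_line("Cross-study evaluation done for %d dataset(s).",
             length(externals))
  }

  write_benchmark_outputs(results, out_dir)
  resolved <- config
  resolved$seed <- seed
  resolved$mode <- mode
  resolved$k <- k
  resolved$drbench_version <- as.character(utils::packageVersion("drbench"))
  yaml::write_yaml(resolved, file.path(out_dir, "resolved_config.yaml"))
  log_line("Outputs written to %s.", out_dir)
  out <- invisible(out_dir)
  attr(out, "results") <- results
  out
}

#' Write benchmark results as CSV files plus a static summary
#'
#' Emits `predictions.csv`, `metrics_per_fold.csv`, `metrics_stratified.csv`,
#' `friedman_conover.csv`, `cd_groups.csv`, and `ablation.csv` /
#' `cross_study.csv` when present. CSVs always carry unclipped values;
#' negative normalized R2 is clipped at zero only in the rendered
#' `summary.md`.
#'
#' @param results A list as assembled by [run_from_config()] (at minimum
#'   `cv` and `metrics`).
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_benchmark_outputs <- function(results, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(results$cv$predictions, file.path(dir, "predictions.csv"),
                   progress = FALSE)
  readr::write_csv(results$metrics, file.path(dir, "metrics_per_fold.csv"),
                   progress = FALSE)
  if (!is.null(results$stratified)) {
    readr::write_csv(results$stratified, file.path(dir, "metrics_stratified.csv"),
                     progress = FALSE)
  }
  if (!is.null(results$rank_stats)) {
    rs <- results$rank_stats
    fr <- glance(rs$friedman)
    pairwise <- tidy(rs$conover)
    readr::write_csv(
      dplyr::bind_rows(
        dplyr::mutate(fr, test = "friedman", .before = 1),
        dplyr::mutate(pairwise, test = "conover", .before = 1)
      ),
      file.path(dir, "friedman_conover.csv"), progress = FALSE
    )
    readr::write_csv(tidy(rs$cd), file.path(dir, "cd_groups.csv"),
                     progress = FALSE)
  }
  if (!is.null(results$ablation)) {
    ab <- dplyr::select(results$ablation, -dplyr::any_of(c("unperturbed", "ablated")))
    readr::write_csv(ab, file.path(dir, "ablation.csv"), progress = FALSE)
  }
  if (!is.null(results$cross_study)) {
    readr::write_csv(results$cross_study, file.path(dir, "cross_study.csv"),
                     progress = FALSE)
  }
  render_summary(results, file.path(dir, "summary.md"))
  invisible(dir)
}

# Static summary: mean per-fold metrics per model, with negative
# (normalized) R2 clipped at zero for display only.
render_summary <- function(results, path) {
  m <- results$metrics %>%
    dplyr::group_by(.data$model, .data$normalized) %>%
    dplyr::summarise(
      r2 = mean(pmax(.data$r2, 0), na.rm = TRUE),
      pearson = mean(.data$pearson, na.rm = TRUE),
      mse = mean(.data$mse), .groups = "drop"
    ) %>%
    dplyr::arrange(.data$normalized, dplyr::desc(.data$r2))
  lines <- c(
    "# Benchmark summary",
    "",
    sprintf("Mode: %s, folds: %d, seed: %d, measure: %s",
            results$cv$mode, results$cv$k, results$cv$seed, results$cv$measure),
    "",
    "Mean per-fold metrics (negative R2 clipped at zero for display;",
    "see metrics_per_fold.csv for unclipped values):",
    "",
    "| model | normalized | R2 | Pearson | MSE |",
    "|---|---|---|---|---|",
    sprintf("| %s | %s | %.3f | %.3f | %.3f |",
            m$model, m$normalized, m$r2, m$pearson, m$mse)
  )
  if (!is.null(results$rank_stats)) {
    fr <- results$rank_stats$friedman
    lines <- c(lines, "",
               sprintf("Friedman rank test: Q = %.3f, p = %.3g%s",
                       fr$statistic, fr$p_value,
                       if (fr$p_value >= results$rank_stats$alpha) {
                         " (omnibus non-significant)"
                       } else ""))
    for (i in seq_along(results$rank_stats$cd$bars)) {
      lines <- c(lines, sprintf("- group %d: %s", i,
                                paste(results$rank_stats$cd$bars[[i]], collapse = ", ")))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
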