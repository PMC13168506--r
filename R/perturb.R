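# Ablation randomizers. Each operator destroys a specific kind of
# information in one feature modality while preserving a stated invariant,
# so that re-benchmarking with the randomized modality measures how much
# the model relied on it:
#   permute_modality          - breaks the entity-feature link, keeps the
#                               exact multiset of feature vectors
#   moment_preserving_randomize - destroys all structure except per-column
#                               mean and sd (does the model learn more than
#                               summary statistics?)
#   degree_preserving_shuffle - rewires graph edges, keeps every node degree

#' Permute a feature modality across entities
#'
#' Reassigns feature vectors (or per-entity graphs) to entities by a
#' uniformly random permutation. The multiset of vectors is unchanged; only
#' the link between entity and features is destroyed.
#'
#' @param features A [feature_set()].
#' @param seed Integer seed.
#' @return A `drb_features` of the same kind.
#' @export
permute_modality <- function(features, seed = 1) {
  stopifnot(inherits(features, "drb_features"))
  if (features$kind == "graph" && igraph::is_igraph(features$data)) {
    abort("A shared graph has no per-entity assignment to permute; use degree_preserving_shuffle().")
  }
  n <- if (features$kind == "tabular") nrow(features$data) else length(features$data)
  if (n < 2) abort("Permutation needs at least two entities in the modality.")
  perm <- with_seed(derive_seed(seed, "permute", features$modality), sample.int(n))
  out <- features
  if (features$kind == "tabular") {
    ids <- rownames(features$data)
    out$data <- features$data[perm, , drop = FALSE]
    rownames(out$data) <- ids
  } else {
    ids <- names(features$data)
    out$data <- features$data[perm]
    names(out$data) <- ids
  }
  out
}

#' Replace a tabular modality by moment-matched Gaussian noise
#'
#' Each feature column is replaced by independent Gaussian draws with that
#' column's sample mean and standard deviation (across entities). Zero-
#' variance columns are reproduced exactly. Destroys every signal except
#' the per-column summary statistics.
#'
#' @inheritParams permute_modality
#' @param per_entity If `TRUE`, match moments per entity row instead of per
#'   feature column.
#' @return A `drb_features` of kind `"tabular"`.
#' @export
moment_preserving_randomize <- function(features, seed = 1, per_entity = FALSE) {
  stopifnot(inherits(features, "drb_features"))
  if (features$kind != "tabular") {
    abort("Moment-preserving randomization applies to tabular modalities; use degree_preserving_shuffle() for graphs.")
  }
  mat <- features$data
  if (nrow(mat) < 2) abort("Randomization needs at least two entities.")
  if (per_entity) {
    return(moment_preserving_randomize(
      within_transpose(features), seed = seed, per_entity = FALSE
    ) |> within_transpose())
  }
  out <- with_seed(derive_seed(seed, "moments", features$modality), {
    apply(mat, 2, function(col) {
      s <- sd(col)
      if (s == 0) col else rnorm(length(col), mean = mean(col), sd = s)
    })
  })
  dimnames(out) <- dimnames(mat)
  res <- features
  res$data <- out
  res
}

within_transpose <- function(features) {
  res <- features
  res$data <- t(features$data)
  res
}

#' Degree-preserving edge shuffle of a simple graph
#'
#' Randomizes a graph by repeated double-edge swaps that reject self-loops
#' and multi-edges (via [igraph::rewire()] with `keeping_degseq`). The
#' degree sequence and edge count are exactly preserved; graphs admitting
#' no legal swap (paths of two edges, stars) come back unchanged.
#'
#' @param graph An [igraph::graph] (simple, undirected), or a
#'   [feature_set()] of kind `"graph"`.
#' @param seed Integer seed.
#' @param n_swaps Number of attempted swaps; defaults to 10x the edge count
#'   (a standard mixing heuristic).
#' @return Same type as the input.
#' @export
degree_preserving_shuffle <- function(graph, seed = 1, n_swaps = NULL) {
  if (inherits(graph, "drb_features")) {
    if (graph$kind != "graph") abort("degree_preserving_shuffle() needs a graph modality.")
    out <- graph
    if (igraph::is_igraph(graph$data)) {
      out$data <- degree_preserving_shuffle(graph$data, seed = seed, n_swaps = n_swaps)
    } else {
      out$data <- purrr::imap(graph$data, function(g, id) {
        degree_preserving_shuffle(g, seed = derive_seed(seed, id), n_swaps = n_swaps)
      })
    }
    return(out)
  }
  stopifnot(igraph::is_igraph(graph))
  m <- igraph::ecount(graph)
  if (m < 2) return(graph)
  n_swaps <- n_swaps %||% (10 * m)
  with_seed(derive_seed(seed, "edge_shuffle"), {
    igraph::rewire(graph, igraph::keeping_degseq(loops = FALSE, niter = n_swaps))
  })
}

#' Summarize an ablation as per-fold performance deltas
#'
#' Pairs per-fold metric values of the unperturbed and ablated runs,
#' reports the mean delta (ablated - unperturbed) with a 1.96 x SEM
#' confidence band. Negative deltas mean the perturbation hurt the model,
#' i.e. the randomized modality carried signal. The ablated values must
#' come from models *retrained* on the randomized features, not merely
#' re-predicted.
#'
#' @param unperturbed_r2,ablated_r2 Per-fold metric values, paired by fold.
#' @param model,mode,modality Labels carried into the result.
#' @return A one-row tibble of class `drb_ablation`: labels, `n_folds`,
#'   `delta_mean`, `ci_low`, `ci_high`, and list-columns of the paired
#'   values.
#' @export
ablation_delta <- function(unperturbed_r2, ablated_r2, model = NA_character_,
                           mode = NA_character_, modality = NA_character_) {
  if (length(unperturbed_r2) != length(ablated_r2)) {
    abort("Unperturbed and ablated per-fold values must be paired (equal length).")
  }
  if (length(unperturbed_r2) < 2) abort("Ablation deltas need >= 2 folds.")
  d <- ablated_r2 - unperturbed_r2
  sem <- sd(d) / sqrt(length(d))
  out <- tibble::tibble(
    model = model, mode = mode, modality = modality,
    n_folds = length(d), delta_mean = mean(d),
    ci_low = mean(d) - 1.96 * sem, ci_high = mean(d) + 1.96 * sem,
    unperturbed = list(unperturbed_r2), ablated = list(ablated_r2)
  )
  class(out) <- c("drb_ablation", class(out))
  out
}

randomize_modality <- function(features, modality, method, seed) {
  fs <- features[[modality]]
  if (is.null(fs)) abort(sprintf("Feature modality '%s' not supplied.", modality))
  features[[modality]] <- switch(method,
    permute = permute_modality(fs, seed = seed),
    moment = moment_preserving_randomize(fs, seed = seed),
    degree = degree_preserving_shuffle(fs, seed = seed),
    abort(sprintf("Unknown ablation method '%s'.", method))
  )
  features
}

#' Run a feature-ablation study
#'
#' Benchmarks the model with its features intact, then once per requested
#' modality with that modality randomized, and reports per-fold R2 deltas
#' (see [ablation_delta()]). The ablated runs retrain the model from
#' scratch on the randomized features, reusing the fold assignment and the
#' hyperparameter configurations chosen in the unperturbed run (no
#' re-tuning), so the delta isolates the feature signal.
#'
#' @param dataset A [response_dataset()].
#' @param model A [model_spec()].
#' @param features Named list of [feature_set()]s.
#' @param modalities Modalities to ablate (default: the model's declared
#'   modalities).
#' @param method `"permute"`, `"moment"` or `"degree"`.
#' @param mode,k,seed,val_fraction As in [run_cross_validation()].
#' @param normalized Report deltas on normalized R2 (default) or plain R2.
#' @return A `drb_ablation` tibble, one row per ablated modality, plus the
#'   unperturbed run in attribute `"cv"`.
#' @export
run_ablation <- function(dataset, model, features,
                         modalities = model$required_modalities,
                         method = c("permute", "moment", "degree"),
                         mode = "LCO", k = 5, seed = 1, val_fraction = 0.1,
                         normalized = TRUE) {
  method <- match.arg(method)
  if (length(modalities) == 0) {
    abort("No modalities to ablate: the model declares no required modalities.")
  }
  base_cv <- run_cross_validation(dataset, list(model), mode = mode, k = k,
                                  seed = seed, features = features,
                                  val_fraction = val_fraction)
  # Freeze the unperturbed run's chosen hyperparameters per fold.
  frozen <- freeze_hyper(model, base_cv)
  base_r2 <- per_fold_r2(base_cv$predictions, normalized)

  rows <- purrr::map_dfr(modalities, function(mod) {
    pert <- randomize_modality(features, mod, method,
                               seed = derive_seed(seed, "ablate", mod))
    cv <- run_cross_validation(dataset, list(frozen), mode = mode, k = k,
                               seed = seed, features = pert,
                               val_fraction = val_fraction)
    ablation_delta(base_r2, per_fold_r2(cv$predictions, normalized),
                   model = model$name, mode = mode, modality = mod)
  })
  attr(rows, "cv") <- base_cv
  attr(rows, "method") <- method
  class(rows) <- c("drb_ablation", class(tibble::tibble()))
  rows
}

freeze_hyper <- function(model, cv) {
  hyper_by_fold <- cv$hyper[cv$hyper$model == model$name, ]
  frozen <- model
  if (length(model$grid) > 1) {
    # Replace the grid by each fold's winning configuration; the harness
    # indexes grids of length one directly, so wrap fit to look up by fold.
    chosen <- hyper_by_fold$hyper
    frozen$grid <- list()
    orig_fit <- model$fit
    fold_counter <- new.env()
    fold_counter$i <- 0L
    frozen$fit <- function(train, features, hyper, seed, ctx) {
      # folds are visited in order within each run; wrap so the frozen model
      # can be reused across several retraining runs
      fold_counter$i <- fold_counter$i %% length(chosen) + 1L
      orig_fit(train, features, chosen[[fold_counter$i]], seed, ctx)
    }
  }
  frozen
}

per_fold_r2 <- function(predictions, normalized) {
  fm <- fold_metrics(predictions)
  fm <- fm[fm$normalized == normalized, ]
  fm$r2[order(fm$fold)]
}

#' Refit a model with different initializations
#'
#' Measures performance stability under the model's own stochasticity:
#' fits the model `n_inits` times on the same training records with
#' different seeds, predicts the same test records, and reports the metric
#' spread. Deterministic models yield zero spread.
#'
#' @param spec A [model_spec()].
#' @param train,test Response record tibbles.
#' @param features Named list of [feature_set()]s.
#' @param hyper Hyperparameter configuration (one grid entry).
#' @param n_inits Number of refits.
#' @param seed Root seed; initialization seeds derive from it.
#' @return A tibble with one metric-suite row per initialization, plus a
#'   `summary` attribute (min/max/sd of each metric).
#' @export
robustness_refit <- function(spec, train, test, features = list(),
                             hyper = list(), n_inits = 3, seed = 1) {
  stopifnot(inherits(spec, "drb_model_spec"))
  assert_scalar_int(n_inits, "n_inits", min = 1)
  rows <- purrr::map_dfr(seq_len(n_inits), function(i) {
    fit <- spec$fit(train, features, hyper, derive_seed(seed, "init", i),
                    list(es_validation = NULL))
    pred <- spec$predict(fit, test, features)
    dplyr::mutate(compute_metric_suite(test$response, pred), init = i,
                  .before = 1)
  })
  summary <- rows %>%
    tidyr::pivot_longer(-c("init", "n"), names_to = "metric") %>%
    dplyr::group_by(.data$metric) %>%
    dplyr::summarise(min = min(.data$value), max = max(.data$value),
                     sd = sd(.data$value), .groups = "drop")
  attr(rows, "summary") <- summary
  rows
}
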