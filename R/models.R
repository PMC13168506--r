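#' Define a model under the benchmark's train/predict contract
#'
#' A model is anything that can be fit on training response records (plus
#' declared feature modalities) and predict a continuous response for
#' (cell line, drug) pairs. The harness owns splitting, tuning, and
#' evaluation; the model only ever sees its training fold, which is what
#' makes the comparison leakage-free.
#'
#' @param name Model name (unique within a benchmark run).
#' @param fit `function(train, features, hyper, seed, ctx)` returning an
#'   opaque fitted object. `train` is a tibble of response records,
#'   `features` a named list of [feature_set()]s, `hyper` a named list (one
#'   grid configuration), `ctx` a list that may carry `es_validation`
#'   records for early-stopping models.
#' @param predict `function(object, newdata, features)` returning a numeric
#'   vector of predictions for the rows of `newdata`.
#' @param grid A list of named lists, one per hyperparameter configuration.
#'   An empty list means the model has no tunable hyperparameters.
#' @param required_modalities Names of feature modalities the model
#'   consumes; records whose entities lack a required modality are dropped
#'   for this model (with counts reported).
#' @param single_drug If `TRUE`, the model fits one learner per training
#'   drug and never predicts drugs absent from training.
#' @param needs_early_stopping If `TRUE`, the harness carves an
#'   early-stopping validation set out of the training part and passes it in
#'   `ctx`.
#' @param predicts_unseen_drugs If `FALSE`, the model is excluded from LDO
#'   runs (it cannot predict drugs it has not seen).
#' @return A list of class `drb_model_spec`.
#' @export
model_spec <- function(name, fit, predict, grid = list(),
                       required_modalities = character(),
                       single_drug = FALSE, needs_early_stopping = FALSE,
                       predicts_unseen_drugs = TRUE) {
  stopifnot(is.function(fit), is.function(predict))
  if (!is.list(grid)) abort("`grid` must be a list of named lists.")
  structure(
    list(name = name, fit = fit, predict = predict, grid = grid,
         required_modalities = required_modalities,
         single_drug = single_drug,
         needs_early_stopping = needs_early_stopping,
         predicts_unseen_drugs = predicts_unseen_drugs),
    class = "drb_model_spec"
  )
}

#' @export
print.drb_model_spec <- function(x, ...) {
  cat(sprintf(
    "<drb_model_spec '%s': %d grid configuration(s), modalities [%s]>\n",
    x$name, max(1L, length(x$grid)),
    paste(x$required_modalities, collapse = ", ")
  ))
  invisible(x)
}

# Naive mean-effect family ---------------------------------------------------

naive_variants <- c("overall", "drug_mean", "cell_line_mean", "tissue_mean",
                    "mean_effects")

#' Fit the naive mean-effect parameters
#'
#' Computes, from training records only: the overall mean response, per-drug
#' and per-cell-line means, and per-tissue means (when tissue is annotated).
#' These parameterize the whole naive predictor family, including the
#' mean-effects predictor \eqn{\hat{y}_{ij} = \mu_i^c + \mu_j^d - \mu}.
#'
#' @param train A tibble of training response records (columns
#'   `cell_line_id`, `drug_id`, `response`, optionally `tissue`).
#' @param variant One of `"overall"`, `"drug_mean"`, `"cell_line_mean"`,
#'   `"tissue_mean"`, `"mean_effects"`; only checked for feasibility
#'   (tissue_mean needs tissue), the returned parameters serve any variant.
#' @return A list of class `drb_naive` with `mu`, `cell_means`,
#'   `drug_means`, `tissue_means`.
#' @export
#' @examples
#' train <- tibble::tibble(
#'   cell_line_id = c("c1", "c1", "c2"),
#'   drug_id = c("dX", "dY", "dX"),
#'   response = c(1, 3, 2)
#' )
#' fit_naive(train, "mean_effects")
fit_naive <- function(train, variant = naive_variants) {
  variant <- match.arg(variant)
  train <- tibble::as_tibble(train)
  if (nrow(train) == 0) abort("Cannot fit a naive predictor on an empty training set.")
  has_tissue <- "tissue" %in% names(train) && any(!is.na(train$tissue))
  if (variant == "tissue_mean" && !has_tissue) {
    abort("The tissue_mean variant requires tissue annotation in training records.")
  }
  group_mean <- function(key) {
    means <- tapply(train$response, train[[key]], mean)
    setNames(as.numeric(means), names(means))
  }
  structure(
    list(
      mu = mean(train$response),
      cell_means = group_mean("cell_line_id"),
      drug_means = group_mean("drug_id"),
      tissue_means = if (has_tissue) {
        keep <- !is.na(train$tissue)
        means <- tapply(train$response[keep], train$tissue[keep], mean)
        setNames(as.numeric(means), names(means))
      }
    ),
    class = "drb_naive"
  )
}

#' Predict with a naive mean-effect variant
#'
#' The mean-effects variant predicts
#' \eqn{\hat{y}_{ij} = \mu_i^c + \mu_j^d - \mu}; for a drug or cell line
#' unseen in training the corresponding group mean falls back to the overall
#' mean \eqn{\mu} (so under leave-drug-out the prediction reduces to the
#' cell-line mean). The single-factor variants predict their group mean with
#' the same \eqn{\mu} fallback; `overall` always predicts \eqn{\mu}.
#'
#' @param params A `drb_naive` from [fit_naive()].
#' @param variant Which naive predictor to use.
#' @param pairs A tibble with `cell_line_id`, `drug_id` and (for
#'   tissue_mean) `tissue`.
#' @return Numeric predictions, one per row of `pairs`.
#' @export
predict_naive <- function(params, variant = naive_variants, pairs) {
  variant <- match.arg(variant)
  stopifnot(inherits(params, "drb_naive"))
  lookup <- function(means, ids) {
    if (is.null(means)) return(rep(params$mu, length(ids)))
    out <- unname(means[ids])
    out[is.na(out)] <- params$mu
    out
  }
  switch(variant,
    overall = rep(params$mu, nrow(pairs)),
    drug_mean = lookup(params$drug_means, pairs$drug_id),
    cell_line_mean = lookup(params$cell_means, pairs$cell_line_id),
    tissue_mean = {
      if (is.null(params$tissue_means)) {
        abort("No tissue means fitted; was training tissue annotation missing?")
      }
      lookup(params$tissue_means, pairs$tissue)
    },
    mean_effects = lookup(params$cell_means, pairs$cell_line_id) +
      lookup(params$drug_means, pairs$drug_id) - params$mu
  )
}

#' Naive predictors as benchmark models
#'
#' Wraps [fit_naive()] / [predict_naive()] in the model contract. These
#' baselines use no molecular features at all; they quantify how much
#' apparent performance comes from memorizing drug and cell-line mean
#' effects rather than learning differential response.
#'
#' @param variant One of the naive variants (see [fit_naive()]).
#' @return A [model_spec()].
#' @export
naive_model <- function(variant = naive_variants) {
  variant <- match.arg(variant)
  model_spec(
    name = paste0("naive_", variant),
    fit = function(train, features, hyper, seed, ctx) fit_naive(train, variant),
    predict = function(object, newdata, features) {
      predict_naive(object, variant, newdata)
    },
    grid = list(),
    predicts_unseen_drugs = TRUE
  )
}

# Reference learners ---------------------------------------------------------

# Design matrix: concatenated tabular feature rows for the record's cell
# line and drug, plus (optionally) drug indicator columns with levels fixed
# at training time. Unseen drugs get an all-zero indicator block, so the
# learner falls back to its feature-driven part.
build_design <- function(records, features, modalities, drug_levels = NULL) {
  blocks <- list()
  for (mod in modalities) {
    fs <- features[[mod]]
    if (is.null(fs)) abort(sprintf("Feature modality '%s' not supplied.", mod))
    if (fs$kind != "tabular") next # graph modalities need a graph-aware learner
    ids <- if (fs$entity_kind == "cell_line") records$cell_line_id else records$drug_id
    block <- feature_rows(fs, ids)
    colnames(block) <- paste(mod, colnames(block), sep = ".")
    blocks[[mod]] <- block
  }
  if (!is.null(drug_levels)) {
    ind <- matrix(0, nrow(records), length(drug_levels),
                  dimnames = list(NULL, paste0("drug.", drug_levels)))
    hit <- match(records$drug_id, drug_levels)
    ok <- !is.na(hit)
    ind[cbind(which(ok), hit[ok])] <- 1
    blocks[["drug_indicator"]] <- ind
  }
  do.call(cbind, blocks)
}

#' Penalized linear reference learner
#'
#' Ridge/elastic-net regression (via glmnet) on concatenated tabular
#' feature modalities, with optional per-drug indicator columns so drug
#' mean effects are modelled alongside the molecular features. A reference
#' learner for exercising the harness, not a literature model.
#'
#' @param modalities Tabular feature modalities to use.
#' @param drug_intercepts Include per-drug indicator columns.
#' @param lambda Candidate penalty values (the tuning grid).
#' @param alpha Elastic-net mixing parameter (0 = ridge).
#' @return A [model_spec()].
#' @export
linear_model <- function(modalities = c("gene_expression"),
                         drug_intercepts = TRUE,
                         lambda = c(0.01, 0.1, 1), alpha = 0) {
  model_spec(
    name = "linear",
    fit = function(train, features, hyper, seed, ctx) {
      drug_levels <- if (drug_intercepts) sort(unique(train$drug_id))
      x <- build_design(train, features, modalities, drug_levels)
      fit <- glmnet::glmnet(x, train$response, alpha = alpha,
                            lambda = hyper$lambda, standardize = TRUE)
      list(fit = fit, drug_levels = drug_levels, lambda = hyper$lambda)
    },
    predict = function(object, newdata, features) {
      x <- build_design(newdata, features, modalities, object$drug_levels)
      as.numeric(stats::predict(object$fit, newx = x, s = object$lambda))
    },
    grid = lapply(lambda, function(l) list(lambda = l)),
    required_modalities = modalities
  )
}

#' Random-forest reference learner
#'
#' A ranger random forest on concatenated tabular modalities plus drug
#' indicators. Stochastic (bootstrap and feature subsampling); the harness
#' threads a deterministic seed into every fit.
#'
#' @inheritParams linear_model
#' @param num_trees Candidate forest sizes (the tuning grid).
#' @return A [model_spec()].
#' @export
forest_model <- function(modalities = c("gene_expression"),
                         drug_intercepts = TRUE, num_trees = c(200)) {
  model_spec(
    name = "random_forest",
    fit = function(train, features, hyper, seed, ctx) {
      drug_levels <- if (drug_intercepts) sort(unique(train$drug_id))
      x <- build_design(train, features, modalities, drug_levels)
      dat <- data.frame(.y = train$response, x, check.names = TRUE)
      fit <- ranger::ranger(
        .y ~ ., data = dat, num.trees = hyper$num_trees, seed = seed,
        num.threads = 1
      )
      list(fit = fit, drug_levels = drug_levels)
    },
    predict = function(object, newdata, features) {
      x <- build_design(newdata, features, modalities, object$drug_levels)
      dat <- data.frame(x, check.names = TRUE)
      stats::predict(object$fit, data = dat, num.threads = 1)$predictions
    },
    grid = lapply(num_trees, function(nt) list(num_trees = nt)),
    required_modalities = modalities
  )
}

#' Per-drug linear reference learner
#'
#' Fits one ridge regression per training drug on cell-line features (the
#' `single_drug` path of the model contract). Cannot predict drugs absent
#' from training, so it is excluded from LDO runs.
#'
#' @inheritParams linear_model
#' @return A [model_spec()].
#' @export
per_drug_linear_model <- function(modalities = c("gene_expression"),
                                  lambda = c(0.1, 1)) {
  model_spec(
    name = "per_drug_linear",
    fit = function(train, features, hyper, seed, ctx) {
      fits <- lapply(split(train, train$drug_id), function(df) {
        x <- build_design(df, features, modalities)
        if (nrow(df) < 3 || var(df$response) == 0) {
          list(mean = mean(df$response))
        } else {
          list(fit = glmnet::glmnet(x, df$response, alpha = 0,
                                    lambda = hyper$lambda),
               lambda = hyper$lambda)
        }
      })
      list(fits = fits)
    },
    predict = function(object, newdata, features) {
      out <- rep(NA_real_, nrow(newdata))
      for (drug in unique(newdata$drug_id)) {
        m <- object$fits[[drug]]
        if (is.null(m)) next # drug unseen in training: no prediction
        rows <- which(newdata$drug_id == drug)
        if (!is.null(m$mean)) {
          out[rows] <- m$mean
        } else {
          x <- build_design(newdata[rows, , drop = FALSE], features, modalities)
          out[rows] <- as.numeric(stats::predict(m$fit, newx = x, s = m$lambda))
        }
      }
      out
    },
    grid = lapply(lambda, function(l) list(lambda = l)),
    required_modalities = modalities,
    single_drug = TRUE,
    predicts_unseen_drugs = FALSE
  )
}
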