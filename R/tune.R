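#' Grid-search hyperparameter tuning on an inner holdout
#'
#' Trains every grid configuration on the inner-train part, scores it by
#' RMSE on the inner validation part, and keeps the minimizer (ties broken
#' by grid order). Following the harness's holdout discipline the winning
#' fit is the one trained on the inner-train part: the validation records
#' stay untouched by the returned model, which keeps grid-searched models
#' comparable with early-stopping models that also never train on
#' validation data.
#'
#' @param spec A [model_spec()] with a non-empty grid.
#' @param train Outer-training response records (tibble).
#' @param mode Split mode, used for group-disjoint inner splitting.
#' @param features Named list of [feature_set()]s.
#' @param val_fraction Fraction of training groups held out for validation.
#' @param seed Integer seed.
#' @return A list of class `drb_tuned`: `spec`, `hyper` (chosen
#'   configuration), `fitted`, `val_rmse` (per configuration), `chosen`
#'   (index into the grid).
#' @export
grid_search_tune <- function(spec, train, mode, features = list(),
                             val_fraction = 0.1, seed = 1) {
  stopifnot(inherits(spec, "drb_model_spec"))
  if (length(spec$grid) == 0) {
    abort(sprintf("Model '%s' has an empty hyperparameter grid.", spec$name))
  }
  parts <- make_inner_split(train, mode, val_fraction = val_fraction,
                            seed = seed,
                            early_stopping = spec$needs_early_stopping)
  ctx <- list(es_validation = parts$es_validation)

  fits <- vector("list", length(spec$grid))
  rmses <- rep(NA_real_, length(spec$grid))
  for (g in seq_along(spec$grid)) {
    fit <- spec$fit(parts$train, features, spec$grid[[g]],
                    derive_seed(seed, "tune", spec$name, g), ctx)
    pred <- spec$predict(fit, parts$validation, features)
    ok <- is.finite(pred) & is.finite(parts$validation$response)
    rmses[g] <- sqrt(mean((parts$validation$response[ok] - pred[ok])^2))
    fits[[g]] <- fit
  }
  chosen <- which.min(rmses) # which.min takes the first minimum: grid order
  structure(
    list(spec = spec, hyper = spec$grid[[chosen]], fitted = fits[[chosen]],
         val_rmse = rmses, chosen = chosen),
    class = "drb_tuned"
  )
}
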