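# Evaluation metrics. Correlations are undefined (NA, never 0) when either
# argument has zero variance; undefined values are excluded from averages
# with a count, never silently coerced.

safe_cor <- function(a, b, method) {
  if (length(a) < 2 || sd(a) == 0 || sd(b) == 0) return(NA_real_)
  suppressWarnings(cor(a, b, method = method))
}

#' Compute the standard metric suite
#'
#' MSE, RMSE, MAE, coefficient of determination
#' \eqn{R^2 = 1 - \sum(y-\hat y)^2 / \sum(y-\bar y)^2}, and Pearson,
#' Spearman and Kendall correlations (average-rank tie handling, via
#' [stats::cor()]). With fewer than two points the error metrics are still
#' defined but R2 and the correlations are `NA`.
#'
#' @param y_true,y_pred Numeric vectors of equal length.
#' @return A one-row tibble: `n`, `mse`, `rmse`, `mae`, `r2`, `pearson`,
#'   `spearman`, `kendall`.
#' @export
#' @examples
#' compute_metric_suite(c(1, 2, 3), c(1.1, 1.9, 3.2))
compute_metric_suite <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    abort("`y_true` and `y_pred` must have equal length.")
  }
  ok <- is.finite(y_true) & is.finite(y_pred)
  y <- y_true[ok]
  p <- y_pred[ok]
  n <- length(y)
  if (n == 0) {
    return(tibble::tibble(n = 0L, mse = NA_real_, rmse = NA_real_,
                          mae = NA_real_, r2 = NA_real_, pearson = NA_real_,
                          spearman = NA_real_, kendall = NA_real_))
  }
  err <- y - p
  mse <- mean(err^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (n < 2 || sst == 0) NA_real_ else 1 - sum(err^2) / sst
  tibble::tibble(
    n = n, mse = mse, rmse = sqrt(mse), mae = mean(abs(err)), r2 = r2,
    pearson = safe_cor(y, p, "pearson"),
    spearman = safe_cor(y, p, "spearman"),
    kendall = safe_cor(y, p, "kendall")
  )
}

#' Mean-effects-normalized metric suite
#'
#' Subtracts the mean-effects naive predictions from both truth and
#' prediction before computing the suite. This removes the variance that any
#' model can capture by memorizing average drug and cell-line responses;
#' what remains measures differential drug response. Values are stored
#' unclipped (negative normalized R2 is informative); clipping at zero is a
#' rendering choice only.
#'
#' @inheritParams compute_metric_suite
#' @param naive_pred Predictions of a mean-effects naive model fitted on the
#'   same training records as the evaluated model.
#' @return A one-row tibble as in [compute_metric_suite()].
#' @export
normalized_metric_suite <- function(y_true, y_pred, naive_pred) {
  if (length(naive_pred) != length(y_true)) {
    abort("`naive_pred` must match the length of `y_true`.")
  }
  compute_metric_suite(y_true - naive_pred, y_pred - naive_pred)
}

#' Per-fold metrics for a benchmark prediction table
#'
#' Computes the plain and normalized metric suites separately per model and
#' fold, the granularity at which rank statistics and SSMD effect sizes
#' operate.
#'
#' @param predictions A prediction tibble with columns `model`, `fold`,
#'   `y_true`, `y_pred` and (for normalized metrics) `y_naive`.
#' @return A tibble with one row per model x fold x normalization, columns
#'   `model`, `fold`, `normalized`, then the suite columns.
#' @export
fold_metrics <- function(predictions) {
  plain <- predictions %>%
    dplyr::group_by(.data$model, .data$fold) %>%
    dplyr::reframe(compute_metric_suite(.data$y_true, .data$y_pred)) %>%
    dplyr::mutate(normalized = FALSE)
  if (!"y_naive" %in% names(predictions)) {
    return(plain)
  }
  norm <- predictions %>%
    dplyr::group_by(.data$model, .data$fold) %>%
    dplyr::reframe(
      normalized_metric_suite(.data$y_true, .data$y_pred, .data$y_naive)
    ) %>%
    dplyr::mutate(normalized = TRUE)
  dplyr::bind_rows(plain, norm)
}

#' Metrics stratified by drug or by cell line
#'
#' Pools predictions across all folds, then computes R2 and the correlation
#' metrics within each stratum (each drug, or each cell line). Strata with
#' fewer than `min_n` points are reported with `NA` metrics and their size,
#' not silently dropped. Comparing these per-stratum values with the global
#' suite exposes Simpson's-paradox inflation: a model can have a high global
#' correlation driven entirely by between-drug mean differences while
#' per-drug correlations are near zero.
#'
#' @param predictions A prediction tibble (see [fold_metrics()]).
#' @param by `"drug"` or `"cell_line"`.
#' @param min_n Minimum stratum size for defined metrics.
#' @return A tibble with one row per model x stratum.
#' @export
stratified_metrics <- function(predictions, by = c("drug", "cell_line"), min_n = 3) {
  by <- match.arg(by)
  key <- if (by == "drug") "drug_id" else "cell_line_id"
  predictions %>%
    dplyr::group_by(.data$model, stratum = .data[[key]]) %>%
    dplyr::reframe({
      if (dplyr::n() < min_n) {
        tibble::tibble(n = dplyr::n(), mse = NA_real_, rmse = NA_real_,
                       mae = NA_real_, r2 = NA_real_, pearson = NA_real_,
                       spearman = NA_real_, kendall = NA_real_)
      } else {
        compute_metric_suite(.data$y_true, .data$y_pred)
      }
    }) %>%
    dplyr::mutate(stratified_by = by, .after = "stratum")
}

#' Strictly standardized mean difference between two models' fold metrics
#'
#' Paired form (cross-validation folds pair the values):
#' \eqn{SSMD = mean(a - b) / sd(a - b)}. Conventions for degenerate cases:
#' if `a` and `b` are elementwise equal the SSMD is 0; if the paired
#' differences are constant but nonzero, the sd is 0 and a signed infinity
#' is returned. An unpaired variant
#' \eqn{(\bar a - \bar b)/\sqrt{s_a^2 + s_b^2}} is available.
#'
#' @param values_a,values_b Per-fold metric values for two models, paired by
#'   fold, length >= 2.
#' @param paired Use the paired-difference form (default).
#' @return A single number (possibly `Inf`/`-Inf`).
#' @export
#' @examples
#' ssmd_effect_size(c(0.5, 0.6, 0.7), c(0.4, 0.4, 0.6))
ssmd_effect_size <- function(values_a, values_b, paired = TRUE) {
  if (length(values_a) != length(values_b)) {
    abort("`values_a` and `values_b` must be paired (equal length).")
  }
  if (length(values_a) < 2) abort("SSMD needs at least two paired values.")
  if (paired) {
    d <- values_a - values_b
    m <- mean(d)
    if (m == 0) return(0)
    s <- sd(d)
    # constant nonzero differences (up to rounding) have no spread to
    # standardize by: report a signed infinity
    if (s <= abs(m) * 1e-12) return(sign(m) * Inf)
    m / s
  } else {
    num <- mean(values_a) - mean(values_b)
    if (num == 0) return(0)
    den <- sqrt(var(values_a) + var(values_b))
    if (den == 0) return(sign(num) * Inf)
    num / den
  }
}
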