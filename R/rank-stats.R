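# Rank-based model comparison: models are ranked by MSE within each
# cross-validation fold (rank 1 = lowest MSE, average ranks for ties), the
# Friedman test asks whether any model ranks systematically better, and the
# Conover-Iman post-hoc (BH-adjusted) localizes which pairs differ.

#' Build the fold x model rank matrix from per-fold metrics
#'
#' @param metrics A per-fold metric tibble (from [fold_metrics()]) or any
#'   tibble with columns `model`, `fold` and the ranking column.
#' @param metric Column to rank by (lower is better); default `"mse"`.
#' @param normalized Use the normalized rows when a `normalized` column is
#'   present.
#' @return A numeric matrix (folds x models) of within-fold ranks; each row
#'   sums to k(k+1)/2.
#' @export
rank_matrix <- function(metrics, metric = "mse", normalized = FALSE) {
  if ("normalized" %in% names(metrics)) {
    metrics <- metrics[metrics$normalized == normalized, , drop = FALSE]
  }
  wide <- metrics %>%
    dplyr::select("model", "fold", dplyr::all_of(metric)) %>%
    tidyr::pivot_wider(names_from = "model", values_from = dplyr::all_of(metric)) %>%
    dplyr::arrange(.data$fold)
  mat <- as.matrix(wide[, setdiff(names(wide), "fold"), drop = FALSE])
  rownames(mat) <- wide$fold
  if (anyNA(mat)) abort("Rank matrix input has missing metric values.")
  t(apply(mat, 1, rank)) # average ranks for ties
}

#' Friedman omnibus test on within-fold model ranks
#'
#' Tie-corrected Friedman statistic over `n` folds (blocks) and `k` models
#' (treatments):
#' \deqn{Q = (k-1) \sum_j (R_j - n(k+1)/2)^2 / (A - C)}
#' with \eqn{R_j} the rank sums, \eqn{A} the sum of squared ranks and
#' \eqn{C = nk(k+1)^2/4}; without ties this reduces to the classical
#' \eqn{12 \sum_j (R_j - n(k+1)/2)^2 / (nk(k+1))}. The p-value is the upper
#' tail of the \eqn{\chi^2} distribution with `k - 1` degrees of freedom.
#'
#' @param ranks A fold x model rank matrix (see [rank_matrix()]).
#' @return A list of class `drb_friedman`: `statistic`, `p_value`, `df`,
#'   `n`, `k`, `mean_ranks`.
#' @export
friedman_rank_test <- function(ranks) {
  ranks <- as.matrix(ranks)
  n <- nrow(ranks)
  k <- ncol(ranks)
  if (n < 2 || k < 2) abort("Friedman test needs >= 2 folds and >= 2 models.")
  R <- colSums(ranks)
  A <- sum(ranks^2)
  C <- n * k * (k + 1)^2 / 4
  denom <- A - C
  Q <- if (denom <= 0) 0 else (k - 1) * sum((R - n * (k + 1) / 2)^2) / denom
  structure(
    list(
      statistic = Q, p_value = pchisq(Q, df = k - 1, lower.tail = FALSE),
      df = k - 1, n = n, k = k,
      mean_ranks = sort(colMeans(ranks))
    ),
    class = "drb_friedman"
  )
}

#' @export
print.drb_friedman <- function(x, ...) {
  cat(sprintf(
    "Friedman rank test: Q = %.4g, df = %d, p = %.4g (n = %d folds, k = %d models)\n",
    x$statistic, x$df, x$p_value, x$n, x$k
  ))
  invisible(x)
}

#' @rdname friedman_rank_test
#' @param x A `drb_friedman`.
#' @param ... Unused.
#' @method tidy drb_friedman
#' @export
tidy.drb_friedman <- function(x, ...) {
  tibble::tibble(model = names(x$mean_ranks), mean_rank = unname(x$mean_ranks))
}

#' @rdname friedman_rank_test
#' @method glance drb_friedman
#' @export
glance.drb_friedman <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p_value = x$p_value, df = x$df,
                 n_folds = x$n, n_models = x$k)
}

#' Conover-Iman post-hoc test after a Friedman test
#'
#' Pairwise comparisons driven by the Friedman rank sums. For models `i`,
#' `j` the statistic
#' \deqn{t = (R_i - R_j) / \sqrt{ 2n (A - B) / ((n-1)(k-1)) }}
#' with \eqn{A} the sum of squared ranks and \eqn{B = \sum_j R_j^2 / n},
#' follows a t-distribution with `(n-1)(k-1)` degrees of freedom under the
#' null. Two-sided raw p-values are Benjamini-Hochberg adjusted over the
#' k(k-1)/2 distinct pairs. If every fold ranks all models identically
#' (zero within-block rank variance) all p-values are 1.
#'
#' @inheritParams friedman_rank_test
#' @return A list of class `drb_conover`: `p_raw`, `p_adjusted` (symmetric
#'   k x k matrices with unit diagonal), `statistic` matrix, `df`,
#'   `mean_ranks`.
#' @export
conover_posthoc <- function(ranks) {
  ranks <- as.matrix(ranks)
  n <- nrow(ranks)
  k <- ncol(ranks)
  if (n < 2 || k < 2) abort("Conover post-hoc needs >= 2 folds and >= 2 models.")
  R <- colSums(ranks)
  A <- sum(ranks^2)
  B <- sum(R^2) / n
  df <- (n - 1) * (k - 1)
  models <- colnames(ranks) %||% paste0("model", seq_len(k))

  tmat <- matrix(0, k, k, dimnames = list(models, models))
  p_raw <- matrix(1, k, k, dimnames = list(models, models))
  scale2 <- 2 * n * (A - B) / df
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      diff_ij <- R[i] - R[j]
      if (scale2 > 1e-12) {
        t_ij <- diff_ij / sqrt(scale2)
      } else if (diff_ij == 0) {
        # all models tied in every fold: no evidence of any difference
        t_ij <- 0
      } else {
        # zero residual rank variance but distinct rank sums: rankings are
        # perfectly consistent across folds, the t statistic diverges
        t_ij <- sign(diff_ij) * Inf
      }
      tmat[i, j] <- tmat[j, i] <- t_ij
      p <- 2 * pt(abs(t_ij), df = df, lower.tail = FALSE)
      p_raw[i, j] <- p_raw[j, i] <- min(1, p)
    }
  }
  upper <- upper.tri(p_raw)
  p_adj <- p_raw
  p_adj[upper] <- p.adjust(p_raw[upper], method = "BH")
  p_adj[lower.tri(p_adj)] <- t(p_adj)[lower.tri(p_adj)]
  structure(
    list(p_raw = p_raw, p_adjusted = p_adj, statistic = tmat, df = df,
         mean_ranks = colMeans(ranks)),
    class = "drb_conover"
  )
}

#' @export
print.drb_conover <- function(x, ...) {
  cat(sprintf("Conover post-hoc (df = %d), BH-adjusted p-values:\n", x$df))
  print(round(x$p_adjusted, 4))
  invisible(x)
}

#' @rdname conover_posthoc
#' @param x A `drb_conover`.
#' @param ... Unused.
#' @method tidy drb_conover
#' @export
tidy.drb_conover <- function(x, ...) {
  models <- rownames(x$p_raw)
  pairs <- which(upper.tri(x$p_raw), arr.ind = TRUE)
  tibble::tibble(
    model_a = models[pairs[, 1]], model_b = models[pairs[, 2]],
    statistic = x$statistic[pairs], p_raw = x$p_raw[pairs],
    p_adjusted = x$p_adjusted[pairs]
  )
}

#' Critical-difference grouping of models by mean rank
#'
#' Orders models by mean rank and, for each model, finds the maximal
#' contiguous run containing it in which every pair is non-significant
#' (adjusted p >= alpha). Duplicate and nested runs are merged. These are
#' the horizontal bars of a critical-difference diagram: models joined by a
#' bar do not differ significantly.
#'
#' @param mean_ranks Named numeric vector of mean ranks.
#' @param p_adjusted Symmetric matrix of BH-adjusted pairwise p-values
#'   (dimnames matching `mean_ranks` names).
#' @param alpha Significance level (default 0.05).
#' @return A list of class `drb_cd`: `mean_ranks` (sorted), `bars` (list of
#'   model-name vectors), `alpha`.
#' @export
cd_groups <- function(mean_ranks, p_adjusted, alpha = 0.05) {
  ord <- names(sort(mean_ranks))
  k <- length(ord)
  bars <- list()
  for (i in seq_len(k)) {
    lo <- i
    hi <- i
    # grow the run right as long as every pair inside stays non-significant
    for (j in seq_len(k)) {
      if (hi == k) break
      cand <- seq(lo, hi + 1)
      ok <- all(p_adjusted[ord[cand], ord[cand]][upper.tri(diag(length(cand)))] >= alpha)
      if (ok) hi <- hi + 1 else break
    }
    for (j in seq_len(k)) {
      if (lo == 1) break
      cand <- seq(lo - 1, hi)
      ok <- all(p_adjusted[ord[cand], ord[cand]][upper.tri(diag(length(cand)))] >= alpha)
      if (ok) lo <- lo - 1 else break
    }
    bars[[i]] <- ord[seq(lo, hi)]
  }
  # drop bars nested inside another bar, and duplicates
  keep <- rep(TRUE, length(bars))
  for (i in seq_along(bars)) {
    for (j in seq_along(bars)) {
      if (i != j && keep[i] &&
          all(bars[[i]] %in% bars[[j]]) &&
          (length(bars[[j]]) > length(bars[[i]]) || j < i)) {
        keep[i] <- FALSE
      }
    }
  }
  structure(
    list(mean_ranks = sort(mean_ranks), bars = unique(bars[keep]), alpha = alpha),
    class = "drb_cd"
  )
}

#' @export
print.drb_cd <- function(x, ...) {
  cat(sprintf("Critical-difference groups (alpha = %g):\n", x$alpha))
  for (i in seq_along(x$bars)) {
    cat(sprintf("  bar %d: %s\n", i, paste(x$bars[[i]], collapse = " - ")))
  }
  invisible(x)
}

#' @rdname cd_groups
#' @param x A `drb_cd`.
#' @param ... Unused.
#' @method tidy drb_cd
#' @export
tidy.drb_cd <- function(x, ...) {
  purrr::imap_dfr(x$bars, function(models, bar) {
    tibble::tibble(bar = bar, model = models,
                   mean_rank = unname(x$mean_ranks[models]))
  })
}

#' Rank-statistics pipeline for a benchmark run
#'
#' Ranks models by per-fold MSE, runs the Friedman omnibus test and the
#' Conover post-hoc with BH correction, and computes critical-difference
#' groups. When the omnibus test is non-significant at `alpha` the result
#' carries a flag (post-hoc results are still reported, with the caveat
#' that they then localize no real differences).
#'
#' @param metrics Per-fold metrics from [fold_metrics()].
#' @param metric Metric to rank by (lower = better); default `"mse"`.
#' @param alpha Significance level.
#' @param normalized Rank on normalized metrics instead of plain ones.
#' @return A list of class `drb_rank_stats`: `ranks`, `friedman`,
#'   `conover`, `cd`, `omnibus_significant`.
#' @export
compare_models <- function(metrics, metric = "mse", alpha = 0.05,
                           normalized = FALSE) {
  ranks <- rank_matrix(metrics, metric = metric, normalized = normalized)
  fr <- friedman_rank_test(ranks)
  co <- conover_posthoc(ranks)
  cd <- cd_groups(colMeans(ranks), co$p_adjusted, alpha = alpha)
  if (fr$p_value >= alpha) {
    inform(sprintf(
      "Omnibus Friedman test non-significant (p = %.3g): pairwise groupings localize no real differences.",
      fr$p_value
    ))
  }
  structure(
    list(ranks = ranks, friedman = fr, conover = co, cd = cd,
         omnibus_significant = fr$p_value < alpha, alpha = alpha,
         metric = metric),
    class = "drb_rank_stats"
  )
}

#' @export
print.drb_rank_stats <- function(x, ...) {
  print(x$friedman)
  print(x$cd)
  invisible(x)
}
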