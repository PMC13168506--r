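#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot predicted versus true responses for a benchmark run
#'
#' Scatter of predictions against ground truth, faceted by model. Colouring
#' by drug makes Simpson's-paradox structure visible: a global trend made
#' of per-drug clouds with little within-drug slope.
#'
#' @param object A `drb_cv`.
#' @param colour_by `"drug"`, `"cell_line"` or `"none"`.
#' @param max_groups Colour at most this many groups (the largest ones);
#'   the rest are grey.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot drb_cv
#' @export
autoplot.drb_cv <- function(object, colour_by = c("drug", "cell_line", "none"),
                            max_groups = 9, ...) {
  colour_by <- match.arg(colour_by)
  df <- object$predictions
  p <- if (colour_by == "none") {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$y_true, y = .data$y_pred))
  } else {
    key <- if (colour_by == "drug") "drug_id" else "cell_line_id"
    top <- names(sort(table(df[[key]]), decreasing = TRUE))[seq_len(min(max_groups, dplyr::n_distinct(df[[key]])))]
    df$group <- ifelse(df[[key]] %in% top, df[[key]], "other")
    ggplot2::ggplot(df, ggplot2::aes(x = .data$y_true, y = .data$y_pred,
                                     colour = .data$group))
  }
  p +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_smooth(ggplot2::aes(group = 1), method = "lm",
                         formula = y ~ x, se = FALSE, colour = "black",
                         linewidth = 0.5) +
    ggplot2::facet_wrap(~model) +
    ggplot2::labs(x = sprintf("true %s", object$measure),
                  y = sprintf("predicted %s", object$measure),
                  colour = colour_by)
}

#' Critical-difference diagram
#'
#' Models on a mean-rank axis with horizontal bars joining groups whose
#' pairwise differences are non-significant.
#'
#' @param object A `drb_cd` from [cd_groups()] or
#'   `compare_models()$cd`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot drb_cd
#' @export
autoplot.drb_cd <- function(object, ...) {
  mr <- object$mean_ranks
  labels <- tibble::tibble(model = names(mr), rank = unname(mr),
                           y = seq_along(mr))
  bars <- purrr::imap_dfr(object$bars, function(models, i) {
    tibble::tibble(bar = i,
                   xmin = min(mr[models]), xmax = max(mr[models]),
                   y = max(labels$y) + i * 0.6)
  })
  ggplot2::ggplot(labels, ggplot2::aes(x = .data$rank, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%s (%.2f)", .data$model, .data$rank)),
                       hjust = -0.05, vjust = -0.6, size = 3) +
    ggplot2::geom_segment(
      data = bars,
      ggplot2::aes(x = .data$xmin, xend = .data$xmax, y = .data$y, yend = .data$y),
      linewidth = 2, colour = "grey40", inherit.aes = FALSE
    ) +
    ggplot2::labs(x = "mean rank (lower = better MSE)", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Ablation deltas with confidence bands
#'
#' Mean change in R2 caused by randomizing each modality (ablated minus
#' unperturbed), with 1.96 x SEM error bars. Bars below zero mean the
#' modality carried signal.
#'
#' @param object A `drb_ablation` from [run_ablation()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot drb_ablation
#' @export
autoplot.drb_ablation <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$modality, y = .data$delta_mean)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
                           width = 0.2) +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::labs(x = "randomized modality", y = "delta R2 (ablated - unperturbed)")
}

#' Plot a fitted dose-response curve over its data
#'
#' @param fit A `drb_curve`.
#' @param log10_dose,viability The fitted points (pooled replicates).
#' @return A ggplot.
#' @export
plot_dose_response <- function(fit, log10_dose, viability) {
  stopifnot(inherits(fit, "drb_curve"))
  grid <- tibble::tibble(x = seq(min(log10_dose), max(log10_dose), length.out = 200))
  grid$v <- four_pl(grid$x, fit$front, fit$back, fit$slope, fit$log10_ec50)
  ggplot2::ggplot(tibble::tibble(x = log10_dose, v = viability),
                  ggplot2::aes(x = .data$x, y = .data$v)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::labs(x = "log10 dose (uM)", y = "viability")
}
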