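# Four-parameter log-logistic response in log10-dose:
#   v(x) = back + (front - back) / (1 + 10^(slope * (x - log10 EC50)))
# Positive slope => viability decreases with dose (the usual inhibition
# case); front is the zero-dose plateau, back the infinite-dose plateau.

#' Evaluate the four-parameter log-logistic curve
#'
#' @param x log10 dose (doses in micromolar).
#' @param front,back Viability plateaus at zero and infinite dose.
#' @param slope Hill coefficient; positive means viability decreases with
#'   dose.
#' @param log10_ec50 log10 of the EC50 in micromolar.
#' @return Fitted viability, same length as `x`.
#' @export
four_pl <- function(x, front, back, slope, log10_ec50) {
  back + (front - back) / (1 + 10^(slope * (x - log10_ec50)))
}

# log(1 + 10^t), stable for large |t|
log1p10 <- function(t) {
  ifelse(t > 0, t * log(10) + log1p(10^(-t)), log1p(10^t))
}

#' Normalize raw viability signals per replicate
#'
#' Divides each raw signal by the control (no-drug) signal of the same
#' replicate. Values above 1 (growth stimulation) are retained, not clipped.
#'
#' @param table A data frame with columns `cell_line_id`, `drug_id`,
#'   `replicate_id`, `dose` (micromolar, > 0), `signal` (>= 0) and
#'   `control_signal` (> 0).
#' @return The table as a tibble with an added `viability` column.
#' @export
normalize_viability <- function(table) {
  required <- c("cell_line_id", "drug_id", "replicate_id", "dose",
                "signal", "control_signal")
  missing_cols <- setdiff(required, names(table))
  if (length(missing_cols) > 0) {
    abort(sprintf("Viability table lacks column(s): %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  table <- tibble::as_tibble(table)
  if (any(table$dose <= 0)) abort("All doses must be positive.")
  bad <- table$control_signal <= 0
  if (any(bad)) {
    offender <- table[which(bad)[1], ]
    abort(sprintf(
      "Nonpositive control signal for replicate '%s' of pair (%s, %s).",
      offender$replicate_id, offender$cell_line_id, offender$drug_id
    ))
  }
  dplyr::mutate(table, viability = .data$signal / .data$control_signal)
}

#' Fit a dose-response curve to pooled replicate points
#'
#' Least-squares fit of the four-parameter log-logistic model over all
#' replicate points of one drug-cell-line pair jointly (replicates are not
#' aggregated first, so replicate disagreement inflates the residual and is
#' reflected in the fit's p-value). Significance is a nested-model F-test of
#' the sigmoid against the flat constant-mean model. With fewer than four
#' distinct doses a reduced three-parameter fit is used (front fixed at 1).
#'
#' Optimization is multi-start Levenberg-Marquardt: EC50 initialized at dose
#' quantiles, plateaus at the viability extremes, with a small seeded jitter.
#' If no start converges the curve is flagged unfit and its p-value set to 1.
#'
#' @param log10_dose Numeric vector, log10 of dose in micromolar.
#' @param viability Numeric vector of normalized viabilities, same length.
#' @param seed Seed for the start jitter.
#' @param n_starts Number of optimizer starts.
#' @return An object of class `drb_curve`: fitted `front`, `back`, `slope`,
#'   `log10_ec50`, `pec50` (= -log10 EC50 in micromolar), `ec50`, `p_value`,
#'   `rss`, `n`, `n_params`, `converged`, and placeholders for `ic50`,
#'   `auc`, `ec50_valid` filled by [derive_ic50()], [compute_auc()] and
#'   [apply_validity_filters()].
#' @export
fit_dose_response <- function(log10_dose, viability, seed = 1, n_starts = 5) {
  if (length(log10_dose) != length(viability)) {
    abort("`log10_dose` and `viability` must have equal length.")
  }
  keep <- is.finite(log10_dose) & is.finite(viability)
  x <- log10_dose[keep]
  v <- viability[keep]
  n_doses <- length(unique(x))
  if (n_doses < 2) abort("At least two distinct doses are required for fitting.")
  n <- length(v)

  unfit <- function() {
    structure(
      list(front = NA_real_, back = NA_real_, slope = NA_real_,
           log10_ec50 = NA_real_, pec50 = NA_real_, ec50 = NA_real_,
           p_value = 1, rss = NA_real_, n = n, n_params = NA_integer_,
           converged = FALSE, ic50 = NA_real_, ln_ic50 = NA_real_,
           auc = NA_real_, ec50_valid = FALSE),
      class = "drb_curve"
    )
  }

  rss0 <- sum((v - mean(v))^2)
  if (rss0 < 1e-12) {
    # Exactly flat data: the constant model is the whole story.
    out <- unfit()
    out$front <- out$back <- mean(v)
    out$slope <- 0
    out$rss <- 0
    out$converged <- TRUE
    out$n_params <- 1L
    return(out)
  }

  fix_front <- n_doses < 4
  slope0 <- if (cor(x, v) < 0) 1 else -1
  dat <- data.frame(x = x, v = v)
  qs <- quantile(x, probs = seq(0.1, 0.9, length.out = n_starts), names = FALSE)
  jitter_m <- with_seed(derive_seed(seed, "curve_starts"),
                        rnorm(n_starts, sd = 0.05))

  best <- NULL
  for (s in seq_len(n_starts)) {
    start <- list(
      back = min(v), slope = slope0, m = qs[s] + jitter_m[s]
    )
    lower <- c(back = -0.5, slope = -50, m = min(x) - 3)
    upper <- c(back = 1.5, slope = 50, m = max(x) + 3)
    if (!fix_front) {
      start <- c(list(front = max(v)), start)
      lower <- c(front = -0.5, lower)
      upper <- c(front = 2.5, upper)
    }
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        if (fix_front) v ~ four_pl(x, 1, back, slope, m)
        else v ~ four_pl(x, front, back, slope, m),
        data = dat, start = start, lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200)
      )),
      error = function(e) NULL
    )
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss - 1e-12) {
        best <- list(fit = fit, rss = rss)
      }
    }
  }
  if (is.null(best)) return(unfit())

  cf <- coef(best$fit)
  front <- if (fix_front) 1 else unname(cf["front"])
  back <- unname(cf["back"])
  slope <- unname(cf["slope"])
  m <- unname(cf["m"])
  p1 <- length(cf) + fix_front * 0L # fitted parameter count
  rss1 <- best$rss

  p_value <- if (n - p1 <= 0) {
    1
  } else {
    f_stat <- ((rss0 - rss1) / (p1 - 1)) / (rss1 / (n - p1))
    if (!is.finite(f_stat) || f_stat <= 0) 1 else pf(f_stat, p1 - 1, n - p1, lower.tail = FALSE)
  }

  structure(
    list(front = front, back = back, slope = slope,
         log10_ec50 = m, pec50 = -m, ec50 = 10^m,
         p_value = p_value, rss = rss1, n = n, n_params = as.integer(p1),
         converged = TRUE, ic50 = NA_real_, ln_ic50 = NA_real_,
         auc = NA_real_, ec50_valid = NA),
    class = "drb_curve"
  )
}

#' @export
print.drb_curve <- function(x, ...) {
  if (!x$converged) {
    cat("<drb_curve: unfit (optimizer did not converge)>\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<drb_curve: front %.3f, back %.3f, slope %.3f, pEC50 %.3f, p %.3g>\n",
    x$front, x$back, x$slope, x$pec50, x$p_value
  ))
  invisible(x)
}

#' Derive the absolute IC50 from a fitted curve
#'
#' IC50 is the dose at which the fitted curve crosses viability 0.5. It
#' exists only when the plateaus bracket 0.5 (closed-form inversion of the
#' 4PL); otherwise `NA`.
#'
#' @param fit A `drb_curve`.
#' @return The IC50 in micromolar, or `NA`.
#' @export
derive_ic50 <- function(fit) {
  stopifnot(inherits(fit, "drb_curve"))
  if (!fit$converged || is.na(fit$slope) || fit$slope == 0) return(NA_real_)
  ratio <- (fit$front - 0.5) / (0.5 - fit$back)
  if (!is.finite(ratio) || ratio <= 0) return(NA_real_)
  10^(fit$log10_ec50 + log10(ratio) / fit$slope)
}

#' Mean fitted viability over the dosed range (AUC)
#'
#' The area under the fitted viability curve over log10 dose in
#' `[log10 dmin, log10 dmax]`, divided by the width of that range: a
#' dimensionless sensitivity summary where lower means more sensitive. Uses
#' the closed-form antiderivative of the 4PL.
#'
#' @param fit A `drb_curve`.
#' @param dosed_range Length-2 vector `c(dmin, dmax)` in micromolar.
#' @return The normalized AUC, or `NA` for unfit curves.
#' @export
compute_auc <- function(fit, dosed_range) {
  stopifnot(inherits(fit, "drb_curve"), length(dosed_range) == 2)
  if (!fit$converged || is.na(fit$front)) return(NA_real_)
  a <- log10(dosed_range[1])
  b <- log10(dosed_range[2])
  if (!(a < b)) abort("`dosed_range` must satisfy 0 < dmin < dmax.")
  if (is.na(fit$slope) || fit$slope == 0 || is.na(fit$log10_ec50)) {
    return(fit$back + (fit$front - fit$back) / 2)
  }
  antideriv <- function(x) {
    fit$back * x + (fit$front - fit$back) *
      (x - log1p10(fit$slope * (x - fit$log10_ec50)) / (fit$slope * log(10)))
  }
  (antideriv(b) - antideriv(a)) / (b - a)
}

#' Apply range-based validity filters to a fitted curve
#'
#' EC50 estimates outside the measured dose range are flagged invalid;
#' IC50 estimates deviating by more than one order of magnitude from the
#' measured range (outside `[dmin/10, dmax*10]`) are set to missing.
#'
#' @param fit A `drb_curve` (with `ic50` already derived, or not).
#' @param dosed_range Length-2 vector `c(dmin, dmax)` in micromolar.
#' @return The curve with `ec50_valid` set, out-of-range `ic50` removed,
#'   and `ln_ic50` (natural log) updated.
#' @export
apply_validity_filters <- function(fit, dosed_range) {
  stopifnot(inherits(fit, "drb_curve"), length(dosed_range) == 2)
  dmin <- dosed_range[1]
  dmax <- dosed_range[2]
  if (!(dmin > 0 && dmin < dmax)) abort("`dosed_range` must satisfy 0 < dmin < dmax.")
  fit$ec50_valid <- !is.na(fit$ec50) && fit$ec50 >= dmin && fit$ec50 <= dmax
  if (!is.na(fit$ic50) && (fit$ic50 < dmin / 10 || fit$ic50 > dmax * 10)) {
    fit$ic50 <- NA_real_
  }
  fit$ln_ic50 <- if (is.na(fit$ic50)) NA_real_ else log(fit$ic50)
  fit
}

#' Fit curves for every drug-cell-line pair of a raw viability table
#'
#' Normalizes per replicate, pools replicate points per pair, fits the
#' log-logistic model, derives IC50 and AUC, and applies the validity
#' filters using each pair's own dosed range. Pairs sharing a dosed range
#' share a `dosage_group` label; fit p-values should only be compared within
#' one dosage group.
#'
#' @inheritParams normalize_viability
#' @param seed Seed for optimizer start jitter.
#' @return A tibble with one row per pair: `cell_line_id`, `drug_id`,
#'   `front`, `back`, `slope`, `pEC50`, `EC50`, `IC50`, `LN_IC50`, `AUC`,
#'   `p_value`, `ec50_valid`, `converged`, `dosage_group`.
#' @export
fit_viability_curves <- function(table, seed = 1) {
  norm <- normalize_viability(table)
  norm %>%
    dplyr::group_by(.data$cell_line_id, .data$drug_id) %>%
    dplyr::group_modify(function(df, key) {
      rng <- range(df$dose)
      fit <- fit_dose_response(log10(df$dose), df$viability, seed = seed)
      fit$ic50 <- derive_ic50(fit)
      fit$auc <- compute_auc(fit, rng)
      fit <- apply_validity_filters(fit, rng)
      tibble::tibble(
        front = fit$front, back = fit$back, slope = fit$slope,
        pEC50 = fit$pec50, EC50 = fit$ec50, IC50 = fit$ic50,
        LN_IC50 = fit$ln_ic50, AUC = fit$auc, p_value = fit$p_value,
        ec50_valid = fit$ec50_valid, converged = fit$converged,
        dosage_group = sprintf("%g-%g", rng[1], rng[2])
      )
    }) %>%
    dplyr::ungroup()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted dose-response curve
#'
#' @param x A `drb_curve`.
#' @param ... Unused.
#' @return One row per parameter (`term`, `estimate`).
#' @method tidy drb_curve
#' @export
tidy.drb_curve <- function(x, ...) {
  tibble::tibble(
    term = c("front", "back", "slope", "pec50"),
    estimate = c(x$front, x$back, x$slope, x$pec50)
  )
}

#' @rdname tidy.drb_curve
#' @return For `glance`: a one-row tibble of fit-level summaries.
#' @method glance drb_curve
#' @export
glance.drb_curve <- function(x, ...) {
  tibble::tibble(
    n = x$n, n_params = x$n_params, rss = x$rss, p_value = x$p_value,
    ec50 = x$ec50, ic50 = x$ic50, auc = x$auc, converged = x$converged,
    ec50_valid = x$ec50_valid
  )
}
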