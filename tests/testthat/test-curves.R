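doses8 <- c(0.01, 0.03, 0.1, 0.3, 1, 3, 10, 100)

test_that("viability normalization divides by the per-replicate control, unclipped", {
  tab <- tibble::tibble(
    cell_line_id = "c1", drug_id = "d1", replicate_id = c("r1", "r1", "r2"),
    dose = c(1, 10, 1), signal = c(500, 1200, 0),
    control_signal = c(1000, 1000, 800)
  )
  out <- normalize_viability(tab)
  expect_equal(out$viability, c(0.5, 1.2, 0))

  tab$control_signal[2] <- 0
  expect_error(normalize_viability(tab), "r1")
})

test_that("noiseless curves are recovered and duplication leaves the fit invariant", {
  x <- log10(rep(doses8, 2))
  v <- four_pl(x, front = 1, back = 0, slope = 1, log10_ec50 = 0)
  fit <- fit_dose_response(x, v)
  expect_true(fit$converged)
  expect_lt(abs(fit$pec50 - 0), 1e-3)
  expect_lt(abs(fit$front - 1), 1e-3)
  expect_lt(abs(fit$back - 0), 1e-3)
  # decreasing viability => positive reported slope
  expect_gt(fit$slope, 0)

  # duplicating every point (identical replicates) changes nothing
  fit2 <- fit_dose_response(c(x, x), c(v, v))
  expect_equal(fit2$pec50, fit$pec50, tolerance = 1e-6)
  expect_equal(fit2$slope, fit$slope, tolerance = 1e-6)
})

test_that("exactly flat data yields p = 1 and an invalid EC50", {
  x <- log10(doses8)
  fit <- fit_dose_response(x, rep(1, length(x)))
  expect_equal(fit$p_value, 1)
  fit <- apply_validity_filters(fit, range(doses8))
  expect_false(fit$ec50_valid)
})

test_that("pEC50 recovery holds across 100 random noiseless curves", {
  sim <- generate_raw_viability(100, doses8, n_replicates = 2, noise_sd = 0,
                               seed = 21)
  norm <- normalize_viability(sim$table)
  errs <- vapply(seq_len(100), function(i) {
    df <- norm[norm$cell_line_id == sim$truth$cell_line_id[i], ]
    fit <- fit_dose_response(log10(df$dose), df$viability, seed = 1)
    abs(fit$pec50 - (-log10(sim$truth$ec50[i])))
  }, numeric(1))
  expect_lt(max(errs), 1e-3)
})

test_that("fit p-values are near-uniform under a flat truth with noise", {
  sim <- generate_raw_viability(1000, doses8, n_replicates = 2,
                               noise_sd = 0.05, seed = 31, flat_fraction = 1)
  norm <- normalize_viability(sim$table)
  ps <- vapply(split(norm, norm$cell_line_id), function(df) {
    fit_dose_response(log10(df$dose), df$viability, seed = 1)$p_value
  }, numeric(1))
  expect_lte(mean(ps < 0.05), 0.07)
})

test_that("IC50 derivation inverts the curve only when the plateaus bracket 0.5", {
  # symmetric curve: IC50 = EC50
  expect_equal(derive_ic50(curve_from_params(1, 0, 1, 1)), 1, tolerance = 1e-12)
  # closed-form inversion with slope 2
  expect_equal(derive_ic50(curve_from_params(1, 0, 2, 1)), 1, tolerance = 1e-12)
  # asymmetric: (front - 0.5)/(0.5 - back) = 0.5/0.3
  fit <- curve_from_params(1, 0.2, 1, 1)
  ic50 <- derive_ic50(fit)
  expect_equal(four_pl(log10(ic50), 1, 0.2, 1, 0), 0.5, tolerance = 1e-10)
  # never crosses 0.5
  expect_true(is.na(derive_ic50(curve_from_params(1, 0.8, 1, 1))))
})

test_that("validity filters implement the in-range EC50 and 10x IC50 rules", {
  rng <- c(0.01, 10)
  f <- curve_from_params(1, 0, 1, 20)
  f <- apply_validity_filters(f, rng)
  expect_false(f$ec50_valid)

  f2 <- curve_from_params(1, 0, 1, 1)
  f2$ic50 <- 200
  f2 <- apply_validity_filters(f2, rng)
  expect_true(is.na(f2$ic50))

  f3 <- curve_from_params(1, 0, 1, 1)
  f3$ic50 <- 50 # within one order of magnitude of dmax = 10
  f3 <- apply_validity_filters(f3, rng)
  expect_equal(f3$ic50, 50)
  expect_equal(f3$ln_ic50, log(50))
  expect_true(f3$ec50_valid)
})

test_that("AUC is the mean fitted viability over the log dose range", {
  rng <- c(0.01, 100)
  flat1 <- curve_from_params(1, 1, 0, 1)
  expect_equal(compute_auc(flat1, rng), 1)
  flat0 <- curve_from_params(0, 0, 0, 1)
  expect_equal(compute_auc(flat0, rng), 0)
  # step-function limit with EC50 at the log-midpoint -> 0.5
  step <- curve_from_params(1, 0, 1000, 1) # midpoint of [0.01, 100] in log10
  expect_equal(compute_auc(step, rng), 0.5, tolerance = 1e-4)
  # closed form agrees with numerical quadrature on a generic curve
  f <- curve_from_params(1, 0.1, 1.7, 0.4)
  num <- integrate(function(x) four_pl(x, f$front, f$back, f$slope, f$log10_ec50),
                   log10(rng[1]), log10(rng[2]))$value / diff(log10(rng))
  expect_equal(compute_auc(f, rng), num, tolerance = 1e-6)
})

test_that("the curve table pipeline derives measures and flags per pair", {
  sim <- generate_raw_viability(6, doses8, n_replicates = 2, noise_sd = 0,
                               seed = 5)
  curves <- fit_viability_curves(sim$table, seed = 1)
  expect_equal(nrow(curves), 6)
  expect_true(all(curves$converged))
  expect_true(all(curves$ec50_valid)) # true EC50s are drawn inside the range
  expect_equal(curves$EC50, 10^(-curves$pEC50), tolerance = 1e-10)
  expect_true(all(abs(sort(curves$pEC50) - sort(-log10(sim$truth$ec50))) < 1e-3))
  # AUC bounded by the plateaus
  expect_true(all(curves$AUC >= pmin(curves$back, curves$front) - 1e-6))
  expect_true(all(curves$AUC <= pmax(curves$back, curves$front) + 1e-6))
  expect_equal(unique(curves$dosage_group), "0.01-100")
})

test_that("tidy and glance expose curve parameters and fit summaries", {
  x <- log10(rep(doses8, 2))
  fit <- fit_dose_response(x, four_pl(x, 1, 0, 1, 0))
  td <- tidy(fit)
  expect_equal(td$term, c("front", "back", "slope", "pec50"))
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_lt(gl$p_value, 1e-6)
})
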