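make_ds <- function(cells, drugs, tissues = NULL, seed = 1) {
  grid <- expand.grid(cell_line_id = cells, drug_id = drugs,
                      stringsAsFactors = FALSE)
  if (!is.null(tissues)) {
    grid$tissue <- tissues[match(grid$cell_line_id, cells)]
  }
  grid$response <- withr::with_seed(seed, rnorm(nrow(grid)))
  response_dataset(grid, measure = "LN_IC50")
}

test_that("overlap exclusion matches set arithmetic in all four modes", {
  train <- make_ds(c("c1", "c2"), c("d1", "d2"), tissues = c("lung", "skin"))
  external <- make_ds(c("c2", "c3"), c("d2", "d3"),
                      tissues = c("skin", "brain"), seed = 2)

  lco <- cross_study_filter(train, external, "LCO")
  expect_equal(unique(lco$cell_line_id), "c3")
  expect_equal(attr(lco, "n_removed"), sum(external$cell_line_id == "c2"))

  ldo <- cross_study_filter(train, external, "LDO")
  expect_equal(unique(ldo$drug_id), "d3")

  lto <- cross_study_filter(train, external, "LTO")
  expect_equal(unique(lto$tissue), "brain")

  lpo <- cross_study_filter(train, external, "LPO")
  expect_false(any(lpo$cell_line_id == "c2" & lpo$drug_id == "d2"))
  expect_equal(attr(lpo, "n_removed"), 1) # exactly the one overlapping pair

  # disjoint external: unchanged
  far <- make_ds(c("x1", "x2"), c("z1"), tissues = c("bone", "bone"), seed = 3)
  expect_equal(nrow(cross_study_filter(train, far, "LCO")), nrow(far))
})

test_that("filtering is monotone and idempotent", {
  train <- make_ds(paste0("c", 1:5), paste0("d", 1:4))
  external <- make_ds(paste0("c", 3:8), paste0("d", 3:6), seed = 4)
  once <- cross_study_filter(train, external, "LCO")
  expect_true(nrow(once) <= nrow(external))
  twice <- cross_study_filter(train, once, "LCO")
  expect_equal(nrow(twice), nrow(once))
  expect_equal(twice$response, once$response)
  expect_equal(attr(twice, "n_removed"), 0)
})

test_that("measure mismatch is rejected", {
  train <- make_ds("c1", "d1")
  ext <- make_ds("c9", "d9", seed = 5)
  attr(ext, "measure") <- "AUC"
  expect_error(cross_study_filter(train, ext, "LCO"), "Measure mismatch")
})

test_that("a same-distribution external control matches within-study metrics", {
  cfg <- synthetic_config(n_cell_lines = 250, n_drugs = 60, completeness = 0.5,
                          seed = 50)
  sim <- generate_response_dataset(cfg)
  d <- tibble::as_tibble(sim$dataset)
  cells <- unique(d$cell_line_id)
  ext_cells <- withr::with_seed(51, sample(cells, 50))
  external <- response_dataset(
    d[d$cell_line_id %in% ext_cells,
      c("cell_line_id", "drug_id", "tissue", "response")],
    measure = "LN_IC50", name = "external_slice"
  )
  main <- response_dataset(
    d[!d$cell_line_id %in% ext_cells,
      c("cell_line_id", "drug_id", "tissue", "response")],
    measure = "LN_IC50", name = "main"
  )
  cv <- run_cross_validation(main, list(naive_model("drug_mean")),
                             mode = "LCO", k = 5, seed = 50,
                             keep_models = TRUE)
  within_r2 <- glance(cv)$r2
  cs <- cross_study_evaluate(cv, list(slice = external))
  ext_r2 <- mean(cs$r2[cs$model == "naive_drug_mean" & !cs$normalized])
  expect_lt(abs(within_r2 - ext_r2), 0.05)
})

test_that("an assay shift leaves Pearson intact while degrading MSE", {
  cfg <- synthetic_config(n_cell_lines = 120, n_drugs = 30, completeness = 0.6,
                          seed = 52)
  sim <- generate_response_dataset(cfg)
  d <- tibble::as_tibble(sim$dataset)
  cells <- unique(d$cell_line_id)
  ext_cells <- withr::with_seed(53, sample(cells, 30))
  base_cols <- c("cell_line_id", "drug_id", "tissue", "response")
  ext_plain <- d[d$cell_line_id %in% ext_cells, base_cols]
  ext_shift <- ext_plain
  ext_shift$response <- 1.5 * ext_shift$response + 2 # a != 1 scale + offset
  main <- response_dataset(d[!d$cell_line_id %in% ext_cells, base_cols],
                           "LN_IC50")
  cv <- run_cross_validation(main, list(naive_model("drug_mean")),
                             mode = "LCO", k = 4, seed = 52,
                             keep_models = TRUE)
  cs <- cross_study_evaluate(cv, list(
    plain = response_dataset(ext_plain, "LN_IC50"),
    shifted = response_dataset(ext_shift, "LN_IC50")
  ))
  cs <- cs[cs$model == "naive_drug_mean" & !cs$normalized, ]
  plain <- cs[cs$dataset == "plain", ]
  shifted <- cs[cs$dataset == "shifted", ]
  expect_equal(shifted$pearson, plain$pearson, tolerance = 1e-10)
  expect_true(all(shifted$mse > plain$mse))
})

test_that("folds whose training data covers the whole external set are skipped", {
  d <- make_ds(paste0("c", 1:6), paste0("d", 1:4), seed = 6)
  cv <- run_cross_validation(d, list(naive_model("overall")), mode = "LCO",
                             k = 3, seed = 6, keep_models = TRUE)
  # a single-cell external: that cell is in training for k - 1 of the folds,
  # which must skip; only the fold that held it out evaluates it
  solo <- make_ds("c1", paste0("d", 1:4), seed = 7)
  w <- testthat::capture_warnings(
    res <- cross_study_evaluate(cv, list(solo = solo))
  )
  expect_true(any(grepl("skipped", w)))
  held_out_fold <- cv$folds$fold[cv$records$cell_line_id == "c1"][1]
  expect_equal(unique(res$fold), held_out_fold)
})
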