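test_that("naive parameters are the training group means", {
  p <- fit_naive(toy_train(), "mean_effects")
  expect_equal(p$mu, 2)
  expect_equal(p$drug_means, c(dX = 1.5, dY = 3))
  expect_equal(p$cell_means, c(c1 = 2, c2 = 2))
  expect_error(fit_naive(toy_train()[0, ], "overall"), "empty")
})

test_that("mean-effects predictions follow mu_c + mu_d - mu with mu fallback", {
  p <- fit_naive(toy_train(), "mean_effects")
  pairs <- tibble::tibble(cell_line_id = "c2", drug_id = "dY")
  expect_equal(predict_naive(p, "mean_effects", pairs), 2 + 3 - 2)
  # unseen drug: mu_d falls back to mu, prediction reduces to the cell mean
  unseen <- tibble::tibble(cell_line_id = "c1", drug_id = "dZ")
  expect_equal(predict_naive(p, "mean_effects", unseen), 2)
  # unseen cell line and drug: prediction is mu
  expect_equal(
    predict_naive(p, "mean_effects",
                  tibble::tibble(cell_line_id = "cX", drug_id = "dZ")),
    2
  )
})

test_that("every naive variant predicts the constant on constant training data", {
  const <- toy_train()
  const$response <- 7
  p <- fit_naive(const, "mean_effects")
  pairs <- tibble::tibble(cell_line_id = c("c1", "cNew"),
                          drug_id = c("dX", "dNew"),
                          tissue = c("lung", "unknown"))
  for (v in c("overall", "drug_mean", "cell_line_mean", "tissue_mean",
              "mean_effects")) {
    expect_equal(predict_naive(p, v, pairs), c(7, 7), info = v)
  }
})

test_that("tissue means are the means of that tissue's training cell lines", {
  p <- fit_naive(toy_train(), "tissue_mean")
  expect_equal(p$tissue_means, c(lung = 2, skin = 2))
  pairs <- tibble::tibble(cell_line_id = "c9", drug_id = "dX",
                          tissue = c("lung", "unmapped"))
  expect_equal(predict_naive(p, "tissue_mean", pairs), c(2, 2))
  no_tissue <- toy_train()
  no_tissue$tissue <- NULL
  expect_error(fit_naive(no_tissue, "tissue_mean"), "tissue")
})

test_that("mean effects reproduce a complete noiseless additive table exactly", {
  withr::with_seed(9, {
    a <- rnorm(12)
    b <- rnorm(7)
  })
  grid <- expand.grid(i = 1:12, j = 1:7)
  d <- tibble::tibble(
    cell_line_id = paste0("c", grid$i), drug_id = paste0("d", grid$j),
    response = 5 + a[grid$i] + b[grid$j]
  )
  p <- fit_naive(d, "mean_effects")
  pred <- predict_naive(p, "mean_effects", d)
  expect_equal(pred, d$response, tolerance = 1e-12)
})

test_that("mean effects agree with a brute-force two-way group-mean oracle", {
  for (i in 1:100) {
    d <- random_response(n_cells = sample(3:6, 1), n_drugs = sample(3:5, 1),
                         replicate_frac = 0.3, seed = 5000 + i)
    p <- fit_naive(d, "mean_effects")
    pred <- predict_naive(p, "mean_effects", d)
    # oracle: explicit per-record arithmetic over raw vectors
    oracle <- vapply(seq_len(nrow(d)), function(r) {
      mean(d$response[d$cell_line_id == d$cell_line_id[r]]) +
        mean(d$response[d$drug_id == d$drug_id[r]]) -
        mean(d$response)
    }, numeric(1))
    expect_lt(max(abs(pred - oracle)), 1e-12)
  }
})

test_that("grid search minimizes validation RMSE with grid-order tie-breaking", {
  # learner that predicts the constant `c`: validation RMSE is a known
  # function of the hyperparameter when the response is 0 everywhere
  const_learner <- function(grid) {
    model_spec(
      name = "const",
      fit = function(train, features, hyper, seed, ctx) hyper$c,
      predict = function(object, newdata, features) rep(object, nrow(newdata)),
      grid = grid
    )
  }
  d <- random_response(n_cells = 10, n_drugs = 4, seed = 10)
  d$response <- 0

  spec <- const_learner(list(list(c = 1), list(c = 0.1), list(c = 0.5)))
  tuned <- grid_search_tune(spec, d, "LCO", seed = 3)
  expect_equal(tuned$chosen, 2L)
  expect_equal(tuned$hyper$c, 0.1)
  expect_equal(tuned$val_rmse, c(1, 0.1, 0.5))

  # exact tie: first configuration in grid order wins
  tie <- const_learner(list(list(c = 0.2), list(c = -0.2)))
  expect_equal(grid_search_tune(tie, d, "LCO", seed = 3)$chosen, 1L)

  empty <- const_learner(list())
  expect_error(grid_search_tune(empty, d, "LCO", seed = 3), "empty")

  # single configuration: returned as-is
  single <- const_learner(list(list(c = 2)))
  expect_equal(grid_search_tune(single, d, "LCO", seed = 3)$hyper$c, 2)
})

test_that("feature-based reference learners recover a linear cell-line signal", {
  cfg <- synthetic_config(
    n_cell_lines = 80, n_drugs = 10, n_tissues = 4, sd_drug = 1, sd_cell = 1,
    sd_tissue = 0, sd_interaction = 0, sd_noise = 0.3, completeness = 0.8,
    feature_dim = 8, informative_fraction = 0.5, seed = 12
  )
  sim <- generate_response_dataset(cfg)
  feats <- generate_features(cfg)
  cv <- run_cross_validation(
    sim$dataset,
    list(naive_model("mean_effects"),
         linear_model(modalities = "gene_expression", lambda = c(0.01, 0.1))),
    mode = "LCO", k = 3, seed = 12, features = feats
  )
  g <- glance(cv)
  # under LCO the naive model cannot predict cell effects; the linear model
  # reads them from gene expression and must beat it clearly
  expect_gt(
    g$r2[g$model == "linear"],
    g$r2[g$model == "naive_mean_effects"] + 0.1
  )
})
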