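test_that("the metric suite matches hand computations", {
  perfect <- compute_metric_suite(c(1, 2, 3), c(1, 2, 3))
  expect_equal(perfect$mse, 0)
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$pearson, 1)
  expect_equal(perfect$spearman, 1)
  expect_equal(perfect$kendall, 1)

  const <- compute_metric_suite(c(1, 2, 3), c(2, 2, 2))
  expect_equal(const$mse, 2 / 3)
  expect_equal(const$r2, 0)
  expect_true(is.na(const$pearson)) # zero-variance prediction: undefined, not 0

  anti <- compute_metric_suite(c(1, 2, 3), c(3, 2, 1))
  expect_equal(anti$pearson, -1)
  expect_equal(anti$r2, 1 - 8 / 2)
})

test_that("rmse and mae relate to mse as required", {
  for (i in 1:20) {
    y <- withr::with_seed(i, rnorm(30))
    p <- withr::with_seed(i + 100, rnorm(30))
    s <- compute_metric_suite(y, p)
    expect_equal(s$rmse^2, s$mse, tolerance = 1e-12)
    expect_lte(s$mae, s$rmse)
  }
})

test_that("correlations respect affine and monotone invariance", {
  for (i in 1:20) {
    y <- withr::with_seed(200 + i, rnorm(25))
    p <- y + withr::with_seed(300 + i, rnorm(25, sd = 0.5))
    base <- compute_metric_suite(y, p)
    aff <- compute_metric_suite(y, 3 * p + 2)
    expect_equal(aff$pearson, base$pearson, tolerance = 1e-12)
    mono <- compute_metric_suite(y, exp(p))
    expect_equal(mono$spearman, base$spearman, tolerance = 1e-12)
    expect_equal(mono$kendall, base$kendall, tolerance = 1e-12)
  }
})

test_that("the overall-mean predictor has r2 exactly 0 on its own training data", {
  y <- withr::with_seed(4, rnorm(50))
  s <- compute_metric_suite(y, rep(mean(y), 50))
  expect_equal(s$r2, 0, tolerance = 1e-14)
})

test_that("normalized metrics quantify residual (differential) signal", {
  naive <- c(1, 2, 3, 4)
  # identical residual structure: perfect normalized prediction
  s1 <- normalized_metric_suite(naive + c(0.5, -0.5, 0.5, -0.5),
                                naive + c(0.5, -0.5, 0.5, -0.5), naive)
  expect_equal(s1$r2, 1)
  # attenuated residual prediction: pearson 1, r2 = 1 - 0.125/0.5
  s2 <- normalized_metric_suite(naive[1:2] + c(0.5, -0.5),
                                naive[1:2] + c(0.25, -0.25), naive[1:2])
  expect_equal(s2$pearson, 1)
  expect_equal(s2$r2, 1 - 0.125 / 0.5)
  # model identical to the naive reference: degenerate residual
  s3 <- normalized_metric_suite(naive + c(0.5, -0.5, 0.5, -0.5), naive, naive)
  expect_true(is.na(s3$pearson))
  expect_lte(s3$r2, 0)
  # naive reference identically zero: normalized equals plain
  y <- withr::with_seed(5, rnorm(20))
  p <- withr::with_seed(6, rnorm(20))
  expect_equal(normalized_metric_suite(y, p, rep(0, 20)),
               compute_metric_suite(y, p))
  expect_error(normalized_metric_suite(y, p, rep(0, 3)), "length")
})

test_that("stratified metrics pool folds and respect the minimum stratum size", {
  preds <- tibble::tibble(
    model = "m", fold = rep(1:2, each = 4),
    cell_line_id = rep(c("c1", "c2"), 4),
    drug_id = c(rep("dA", 6), "dB", "dB"),
    y_true = c(1, 2, 3, 4, 5, 6, 1, 2),
    y_pred = c(1.1, 2.2, 2.9, 4.2, 4.8, 6.1, 1.5, 1.9)
  )
  by_drug <- stratified_metrics(preds, "drug")
  dA <- by_drug[by_drug$stratum == "dA", ]
  expect_equal(dA$n, 6)
  manual <- compute_metric_suite(preds$y_true[preds$drug_id == "dA"],
                                 preds$y_pred[preds$drug_id == "dA"])
  expect_equal(dA$pearson, manual$pearson)
  # stratum of size 2: undefined metrics, size recorded
  dB <- by_drug[by_drug$stratum == "dB", ]
  expect_equal(dB$n, 2)
  expect_true(is.na(dB$r2))
})

test_that("SSMD follows the paired-difference form with documented conventions", {
  a <- c(0.5, 0.6, 0.7)
  b <- c(0.4, 0.4, 0.6)
  d <- a - b
  expect_equal(ssmd_effect_size(a, b), mean(d) / sd(d))
  expect_equal(ssmd_effect_size(a, b), 2.3094, tolerance = 1e-4)
  # equal vectors: 0 by convention
  expect_equal(ssmd_effect_size(a, a), 0)
  # constant nonzero difference: signed infinity
  expect_equal(ssmd_effect_size(c(0.5, 0.7), c(0.3, 0.5)), Inf)
  expect_equal(ssmd_effect_size(c(0.3, 0.5), c(0.5, 0.7)), -Inf)
  expect_error(ssmd_effect_size(1, 1), "two")
  expect_error(ssmd_effect_size(c(1, 2), c(1, 2, 3)), "paired")
  # unpaired variant
  expect_equal(ssmd_effect_size(a, b, paired = FALSE),
               (mean(a) - mean(b)) / sqrt(var(a) + var(b)))
})
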