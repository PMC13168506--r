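toy_features <- function(n = 6, d = 3, seed = 1, modality = "gene_expression") {
  mat <- withr::with_seed(seed, matrix(rnorm(n * d), n, d))
  rownames(mat) <- paste0("e", seq_len(n))
  colnames(mat) <- paste0("f", seq_len(d))
  feature_set(mat, modality, "cell_line")
}

test_that("permutation preserves the feature-vector multiset exactly", {
  fs <- toy_features(seed = 41)
  perm <- permute_modality(fs, seed = 1)
  expect_equal(rownames(perm$data), rownames(fs$data))
  # same rows, different assignment
  sorted <- function(m) m[do.call(order, as.data.frame(m)), ]
  expect_equal(unname(sorted(perm$data)), unname(sorted(fs$data)))
  expect_identical(permute_modality(fs, seed = 1)$data, perm$data)

  two <- feature_set(matrix(c(1, 3, 2, 4), 2, 2,
                            dimnames = list(c("A", "B"), c("f1", "f2"))),
                     "m", "cell_line")
  swapped <- NULL
  for (s in 1:20) {
    cand <- permute_modality(two, seed = s)
    if (!identical(cand$data, two$data)) {
      swapped <- cand
      break
    }
  }
  expect_equal(unname(swapped$data["A", ]), unname(two$data["B", ]))
  expect_error(permute_modality(toy_features(n = 1), 1), "two entities")
})

test_that("moment-matched randomization preserves column moments within CLT bounds", {
  n <- 10000
  mat <- cbind(const = rep(5, n),
               x = withr::with_seed(42, rnorm(n, mean = 5, sd = 2)))
  rownames(mat) <- paste0("e", seq_len(n))
  fs <- feature_set(mat, "ge", "cell_line")
  rnd <- moment_preserving_randomize(fs, seed = 3)
  # zero-variance column reproduced exactly
  expect_equal(unname(rnd$data[, "const"]), rep(5, n))
  # moments match within 4 sd / sqrt(n)
  expect_lt(abs(mean(rnd$data[, "x"]) - mean(mat[, "x"])), 4 * 2 / sqrt(n))
  expect_lt(abs(sd(rnd$data[, "x"]) - sd(mat[, "x"])), 4 * 2 / sqrt(n))
  # the values themselves change
  expect_gt(mean(rnd$data[, "x"] != mat[, "x"]), 0.99)
  expect_identical(moment_preserving_randomize(fs, seed = 3)$data, rnd$data)
  graph <- feature_set(igraph::make_ring(4), "g", "drug", kind = "graph")
  expect_error(moment_preserving_randomize(graph, 1), "tabular")
})

test_that("edge shuffling preserves degrees and leaves rigid graphs unchanged", {
  path <- igraph::graph_from_edgelist(rbind(c("a", "b"), c("b", "c")),
                                      directed = FALSE)
  shuffled <- degree_preserving_shuffle(path, seed = 1)
  expect_true(igraph::identical_graphs(path, shuffled) ||
                setequal(apply(igraph::as_edgelist(shuffled), 1,
                               function(e) paste(sort(e), collapse = "-")),
                         c("a-b", "b-c")))

  star <- igraph::make_star(5, mode = "undirected")
  star_s <- degree_preserving_shuffle(star, seed = 2)
  expect_equal(igraph::degree(star_s), igraph::degree(star))

  # two disjoint edges: any outcome keeps the all-ones degree sequence
  disjoint <- igraph::graph_from_edgelist(rbind(c("a", "b"), c("c", "d")),
                                          directed = FALSE)
  for (s in 1:10) {
    out <- degree_preserving_shuffle(disjoint, seed = s)
    expect_equal(sort(unname(igraph::degree(out))), c(1, 1, 1, 1))
    expect_equal(igraph::ecount(out), 2)
    expect_false(igraph::any_loop(out) || igraph::any_multiple(out))
  }

  # a mixable graph: degrees preserved, edges actually move for some seed
  ring <- igraph::make_ring(10)
  moved <- FALSE
  for (s in 1:10) {
    out <- degree_preserving_shuffle(ring, seed = s)
    expect_equal(unname(igraph::degree(out)), rep(2, 10))
    if (!igraph::identical_graphs(out, ring)) moved <- TRUE
  }
  expect_true(moved)
})

test_that("ablation deltas report mean difference with a 1.96 SEM band", {
  res <- ablation_delta(c(0.5, 0.6), c(0.3, 0.4), model = "m", mode = "LCO",
                        modality = "ge")
  expect_equal(res$delta_mean, -0.2)
  expect_equal(res$ci_low, -0.2)
  expect_equal(res$ci_high, -0.2)
  same <- ablation_delta(c(0.5, 0.6), c(0.5, 0.6))
  expect_equal(same$delta_mean, 0)
  expect_error(ablation_delta(c(1, 2), c(1, 2, 3)), "paired")

  spread <- ablation_delta(c(0.5, 0.6, 0.7), c(0.4, 0.35, 0.65))
  d <- c(-0.1, -0.25, -0.05)
  expect_equal(spread$delta_mean, mean(d))
  expect_equal(spread$ci_high - spread$ci_low,
               2 * 1.96 * sd(d) / sqrt(3))
})

test_that("randomizing features a model never uses changes nothing", {
  cfg <- synthetic_config(n_cell_lines = 30, n_drugs = 8, completeness = 0.8,
                          seed = 44)
  sim <- generate_response_dataset(cfg)
  feats <- generate_features(cfg)
  res <- run_ablation(sim$dataset, naive_model("mean_effects"), feats,
                      modalities = "gene_expression", method = "permute",
                      mode = "LCO", k = 3, seed = 44)
  expect_equal(res$delta_mean, 0)
  expect_equal(res$ci_low, 0)
})

test_that("only the informative modality carries signal for a feature learner", {
  cfg <- synthetic_config(
    n_cell_lines = 150, n_drugs = 20, n_tissues = 5, sd_drug = 1, sd_cell = 1,
    sd_tissue = 0, sd_interaction = 0, sd_noise = 0.3, completeness = 0.5,
    feature_dim = 10, informative_fraction = 0.5, seed = 7
  )
  sim <- generate_response_dataset(cfg)
  feats <- generate_features(cfg)
  model <- linear_model(modalities = c("gene_expression", "mutation"),
                        lambda = c(0.01, 0.1))
  res <- run_ablation(sim$dataset, model, feats,
                      modalities = c("gene_expression", "mutation"),
                      method = "permute", mode = "LCO", k = 5, seed = 7)
  informative <- res[res$modality == "gene_expression", ]
  noise <- res[res$modality == "mutation", ]
  # destroying the informative modality wipes out the differential signal
  expect_lt(mean(informative$ablated[[1]]), 0.1)
  expect_lt(informative$delta_mean, -0.5)
  # the pure-noise modality contributes nothing
  expect_lt(abs(noise$delta_mean), 0.05)
})

test_that("robustness refits expose (absence of) initialization noise", {
  d <- random_response(n_cells = 8, n_drugs = 4, seed = 45)
  parts <- make_inner_split(d, "LCO", val_fraction = 0.25, seed = 1)
  det <- robustness_refit(naive_model("mean_effects"), parts$train,
                          parts$validation, n_inits = 3, seed = 9)
  s <- attr(det, "summary")
  expect_true(all(s$sd == 0))

  noisy_learner <- function(noise_sd) {
    model_spec(
      name = "noisy",
      fit = function(train, features, hyper, seed, ctx) {
        list(mu = mean(train$response) +
               withr::with_seed(seed, rnorm(1, sd = noise_sd)))
      },
      predict = function(object, newdata, features) rep(object$mu, nrow(newdata))
    )
  }
  run_spread <- function(noise_sd) {
    r <- robustness_refit(noisy_learner(noise_sd), parts$train,
                          parts$validation, n_inits = 5, seed = 9)
    attr(r, "summary")
  }
  loud <- run_spread(1)
  quiet <- run_spread(0.01)
  expect_gt(loud$sd[loud$metric == "mse"], quiet$sd[quiet$metric == "mse"])
  # fixed seed list: reproducible spread
  expect_equal(run_spread(1), loud)
})
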