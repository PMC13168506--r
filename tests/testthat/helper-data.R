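# Shared fixture builders: everything is generated in code at test time.

# The three-record toy training set used throughout the naive-model checks:
# mu = 2, drug means {dX: 1.5, dY: 3}, cell means {c1: 2, c2: 2}.
toy_train <- function() {
  tibble::tibble(
    cell_line_id = c("c1", "c1", "c2"),
    drug_id = c("dX", "dY", "dX"),
    tissue = c("lung", "lung", "skin"),
    response = c(1, 3, 2)
  )
}

# A small random response dataset with tissues and optional replicates.
random_response <- function(n_cells = 8, n_drugs = 5, n_tissues = 3,
                            replicate_frac = 0, seed = 1) {
  withr::with_seed(seed, {
    grid <- expand.grid(
      cell_line_id = sprintf("c%02d", seq_len(n_cells)),
      drug_id = sprintf("d%02d", seq_len(n_drugs)),
      stringsAsFactors = FALSE
    )
    grid$tissue <- sprintf("t%d", (match(grid$cell_line_id, unique(grid$cell_line_id)) - 1) %% n_tissues + 1)
    grid$response <- rnorm(nrow(grid))
    if (replicate_frac > 0) {
      extra <- grid[sample.int(nrow(grid), ceiling(replicate_frac * nrow(grid))), ]
      extra$response <- rnorm(nrow(extra))
      grid <- rbind(grid, extra)
    }
    response_dataset(grid, measure = "LN_IC50", name = "random")
  })
}

write_temp_csv <- function(df) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  readr::write_csv(df, path, progress = FALSE)
  path
}

# Build a drb_curve object directly from known parameters (for closed-form
# checks of IC50/AUC/validity that do not involve the optimizer).
curve_from_params <- function(front, back, slope, ec50) {
  structure(
    list(front = front, back = back, slope = slope,
         log10_ec50 = log10(ec50), pec50 = -log10(ec50), ec50 = ec50,
         p_value = 0, rss = 0, n = 8L, n_params = 4L, converged = TRUE,
         ic50 = NA_real_, ln_ic50 = NA_real_, auc = NA_real_,
         ec50_valid = NA),
    class = "drb_curve"
  )
}
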