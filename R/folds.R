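# Cross-validation split designs. The grouping key decides what the model
# never sees at test time and therefore which application the split
# emulates:
#   LPO - random drug-cell-line pairs held out (missing-value imputation)
#   LCO - whole cell lines held out (personalized medicine)
#   LTO - whole tissues held out (generalization to new tissue types)
#   LDO - whole drugs held out (drug repurposing / design)
# Replicates of one pair always share a fold, so no record of a test pair
# leaks into training.

split_groups <- function(records, mode) {
  col <- group_column(mode)
  if (mode == "LPO") {
    pair_key(records$cell_line_id, records$drug_id)
  } else {
    if (mode == "LTO" && any(is.na(records$tissue))) {
      abort("LTO split requires tissue annotation for every record.")
    }
    records[[col]]
  }
}

#' Assign records to cross-validation folds
#'
#' Groups records by the split mode's grouping key (pair, cell line, tissue
#' or drug), shuffles the groups with the seed, and deals them round-robin
#' to `k` folds. Grouping-key sets of distinct folds are disjoint by
#' construction, and identical inputs plus seed reproduce the identical
#' assignment.
#'
#' @param dataset A [response_dataset()] (or any tibble with the response
#'   record columns).
#' @param mode `"LPO"`, `"LCO"`, `"LTO"` or `"LDO"`.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed.
#' @return A tibble of class `drb_folds` with columns `.row_id` and `fold`
#'   (integers in `1..k`), and attributes `mode`, `k`, `seed`.
#' @export
#' @examples
#' sim <- generate_response_dataset(synthetic_config(
#'   n_cell_lines = 10, n_drugs = 4, completeness = 1, seed = 1
#' ))
#' make_folds(sim$dataset, mode = "LCO", k = 5, seed = 1)
make_folds <- function(dataset, mode = c("LPO", "LCO", "LTO", "LDO"), k, seed) {
  mode <- match.arg(mode)
  assert_scalar_int(k, "k", min = 2)
  assert_scalar_int(seed, "seed")
  records <- tibble::as_tibble(dataset)
  if (!".row_id" %in% names(records)) records$.row_id <- seq_len(nrow(records))

  keys <- split_groups(records, mode)
  groups <- unique(keys)
  if (length(groups) < k) {
    abort(sprintf(
      "Mode %s has %d distinct group(s) but k = %d folds were requested.",
      mode, length(groups), k
    ))
  }
  shuffled <- with_seed(derive_seed(seed, "folds", mode, k), sample(groups))
  fold_of_group <- setNames(rep(seq_len(k), length.out = length(shuffled)), shuffled)

  out <- tibble::tibble(
    .row_id = records$.row_id,
    fold = unname(fold_of_group[keys])
  )
  structure(out, mode = mode, k = as.integer(k), seed = as.integer(seed),
            class = c("drb_folds", class(tibble::tibble())))
}

#' Split training records into train / validation (/ early-stopping) parts
#'
#' Holds out a fraction of the training *groups* (per the split mode) as an
#' inner validation set for hyperparameter tuning, and optionally a second
#' disjoint fraction as an early-stopping validation set. Parts partition
#' the input; under LCO/LTO/LDO the validation parts are group-disjoint
#' from train, under LPO pair-disjoint.
#'
#' @param train_records A tibble of training response records.
#' @param mode Split mode (see [make_folds()]).
#' @param val_fraction Fraction of training groups held out for validation.
#' @param seed Integer seed.
#' @param early_stopping If `TRUE`, also carve out an early-stopping
#'   validation part (same fraction, from the remaining train groups).
#' @param es_fraction Fraction of remaining train groups for early stopping.
#' @return A named list of tibbles: `train`, `validation`, and
#'   `es_validation` when requested.
#' @export
make_inner_split <- function(train_records, mode = c("LPO", "LCO", "LTO", "LDO"),
                             val_fraction = 0.1, seed = 1,
                             early_stopping = FALSE, es_fraction = 0.1) {
  mode <- match.arg(mode)
  if (val_fraction <= 0 || val_fraction >= 1) abort("`val_fraction` must be in (0, 1).")
  records <- tibble::as_tibble(train_records)
  keys <- split_groups(records, mode)
  groups <- unique(keys)

  take <- function(pool, fraction, label) {
    n_take <- max(1L, round(fraction * length(pool)))
    if (n_take >= length(pool)) {
      abort(sprintf(
        "Cannot hold out %d of %d group(s) for %s: a part would be empty.",
        n_take, length(pool), label
      ))
    }
    with_seed(derive_seed(seed, "inner", label), sample(pool, n_take))
  }

  val_groups <- take(groups, val_fraction, "validation")
  remaining <- setdiff(groups, val_groups)
  parts <- list(
    train = records[keys %in% remaining, , drop = FALSE],
    validation = records[keys %in% val_groups, , drop = FALSE]
  )
  if (early_stopping) {
    es_groups <- take(remaining, es_fraction, "early_stopping")
    train_groups <- setdiff(remaining, es_groups)
    parts$train <- records[keys %in% train_groups, , drop = FALSE]
    parts$es_validation <- records[keys %in% es_groups, , drop = FALSE]
  }
  parts
}
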