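# Seed stream-splitting: every stochastic step derives its own sub-seed from
# the run seed plus a label, so components are independently reproducible and
# inserting a new stochastic step does not shift the draws of later ones.

#' Derive a reproducible sub-seed from a root seed and a label
#'
#' All randomness in drbench flows from one root seed through labelled
#' sub-streams. The derivation is a small deterministic integer hash; it is
#' not cryptographic, it only decorrelates streams.
#'
#' @param seed Integer root seed.
#' @param ... Labels (strings or integers) identifying the sub-stream.
#' @return An integer in `[0, 2^31)` usable with [set.seed()].
#' @export
#' @examples
#' derive_seed(42, "folds", 3)
derive_seed <- function(seed, ...) {
  labels <- paste(c(seed, ...), collapse = "/")
  h <- 5381
  for (ch in utf8ToInt(labels)) {
    h <- (h * 33 + ch) %% 2147483647
  }
  as.integer(h)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Shared argument checks -----------------------------------------------------

assert_scalar_int <- function(x, name, min = NULL) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x)) {
    abort(sprintf("`%s` must be a single integer.", name))
  }
  if (!is.null(min) && x < min) {
    abort(sprintf("`%s` must be >= %s (got %s).", name, min, x))
  }
  invisible(as.integer(x))
}

group_column <- function(mode) {
  switch(mode,
    LPO = "pair_id",
    LCO = "cell_line_id",
    LTO = "tissue",
    LDO = "drug_id",
    abort(sprintf("Unknown split mode '%s' (use LPO, LCO, LTO or LDO).", mode))
  )
}

pair_key <- function(cell_line_id, drug_id) {
  paste(cell_line_id, drug_id, sep = "\r")
}
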