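# Independent Conover oracle: literal transcription of the textbook
# formulation, which scales the rank-sum difference by
# sqrt(2n (A1 - C1) (1 - T1 / (n(k-1))) / ((n-1)(k-1))) with T1 the
# Friedman statistic -- algebraically distinct from the package's
# sum-of-squared-rank-sums form.
conover_oracle_p <- function(ranks) {
  n <- nrow(ranks)
  k <- ncol(ranks)
  R <- colSums(ranks)
  A1 <- sum(ranks^2)
  C1 <- n * k * (k + 1)^2 / 4
  T1 <- (k - 1) * sum((R - n * (k + 1) / 2)^2) / (A1 - C1)
  df <- (n - 1) * (k - 1)
  denom <- sqrt(2 * n * (A1 - C1) * (1 - T1 / (n * (k - 1))) / df)
  p <- matrix(1, k, k)
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      t_ij <- abs(R[i] - R[j]) / denom
      p[i, j] <- p[j, i] <- min(1, 2 * pt(t_ij, df, lower.tail = FALSE))
    }
  }
  p
}

permutations_of_3 <- function() {
  list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
}

random_rank_matrix <- function(n, k, seed, ties = FALSE) {
  withr::with_seed(seed, {
    mse <- matrix(rnorm(n * k), n, k)
    if (ties) mse <- round(mse, 1) # quantized metrics produce ties
    out <- t(apply(mse, 1, rank))
    colnames(out) <- paste0("m", seq_len(k))
    out
  })
}
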