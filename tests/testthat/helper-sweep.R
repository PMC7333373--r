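# Exhaustive enumeration of small 2x2x2 contingency tables and an
# independent, probability-based entropy-expansion oracle for the
# pairwise information gain. Used by the oracle-equivalence check.

# All weak compositions of n into k nonnegative parts.
compositions_of <- function(n, k) {
  if (k == 1L) return(matrix(as.integer(n), 1L, 1L))
  do.call(rbind, lapply(0:n, function(j) {
    cbind(as.integer(j), compositions_of(n - j, k - 1L))
  }))
}

# Oracle: pairwise IG from rows of an 8-column table (cell order
# 1 + x1 + 2 x2 + 4 c), computed from normalized probabilities and
# explicit marginal entropies -- a different numerical path from the
# package's count-based kernel.
oracle_ig2_rows <- function(m) {
  N <- rowSums(m)
  P <- m / N
  Hrow <- function(pm) {
    x <- pm * log2(pm)
    x[pm == 0] <- 0
    -rowSums(x)
  }
  HJ <- Hrow(P)
  H1C <- Hrow(cbind(P[, 1] + P[, 3], P[, 2] + P[, 4],
                    P[, 5] + P[, 7], P[, 6] + P[, 8]))
  H2C <- Hrow(cbind(P[, 1] + P[, 2], P[, 3] + P[, 4],
                    P[, 5] + P[, 6], P[, 7] + P[, 8]))
  p12 <- cbind(P[, 1] + P[, 5], P[, 2] + P[, 6],
               P[, 3] + P[, 7], P[, 4] + P[, 8])
  H12 <- Hrow(p12)
  H1 <- Hrow(cbind(p12[, 1] + p12[, 3], p12[, 2] + p12[, 4]))
  H2 <- Hrow(cbind(p12[, 1] + p12[, 2], p12[, 3] + p12[, 4]))
  HC <- Hrow(cbind(rowSums(P[, 1:4, drop = FALSE]),
                   rowSums(P[, 5:8, drop = FALSE])))
  (H12 + HC - HJ) - (H1 + HC - H1C) - (H2 + HC - H2C)
}

# Largest |kernel - oracle| discrepancy over every 2x2x2 table with
# total count <= total_max (empty table excluded), plus the table count.
ig2_sweep_max_gap <- function(total_max = 30L) {
  c4 <- lapply(0:total_max, function(n) compositions_of(n, 4L))
  max_gap <- 0
  n_tables <- 0
  for (n0 in 0:total_max) {
    A <- c4[[n0 + 1L]]
    for (n1 in 0:(total_max - n0)) {
      if (n0 + n1 == 0L) next
      B <- c4[[n1 + 1L]]
      ia <- rep(seq_len(nrow(A)), times = nrow(B))
      ib <- rep(seq_len(nrow(B)), each = nrow(A))
      m <- cbind(A[ia, , drop = FALSE], B[ib, , drop = FALSE])
      gap <- max(abs(ig_pairwise_counts(m) - oracle_ig2_rows(m)))
      if (gap > max_gap) max_gap <- gap
      n_tables <- n_tables + nrow(m)
    }
  }
  list(max_gap = max_gap, n_tables = n_tables)
}
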