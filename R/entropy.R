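# Entropy, mutual information and information-gain statistics.
#
# All quantities are in bits (base-2 logarithms) so that, for a binary
# class, mutual information and information gain are bounded by
# H(C) <= 1 and IG ranges over [-1, 1].

# n * log2(n) with the 0 * log(0) := 0 convention; works elementwise.
.nlog2n <- function(n) {
  out <- numeric(length(n))
  pos <- n > 0
  out[pos] <- n[pos] * log2(n[pos])
  out
}

# Entropy in bits from a vector of nonnegative counts (or probabilities).
.entropy_counts <- function(counts) {
  N <- sum(counts)
  log2(N) - sum(.nlog2n(counts)) / N
}

#' Shannon entropy of a discrete distribution
#'
#' Computes \eqn{H = -\sum_k p_k \log_2 p_k} (bits) from category counts,
#' using plug-in (maximum-likelihood) probability estimates and the
#' convention \eqn{0 \log 0 = 0}.
#'
#' @param counts Nonnegative counts (or unnormalized weights), one per
#'   category. Must sum to a positive value.
#' @return Entropy in bits (a single number).
#' @examples
#' entropy(c(50, 50))   # 1 bit, uniform binary
#' entropy(c(100, 0))   # 0 bits, degenerate
#' @export
entropy <- function(counts) {
  if (length(counts) == 0L || anyNA(counts)) {
    stop("'counts' must be non-missing and nonempty")
  }
  if (any(counts < 0)) stop("'counts' must be nonnegative")
  if (sum(counts) <= 0) stop("'counts' must have a positive total")
  .entropy_counts(as.numeric(counts))
}

# Map one or more discrete vectors to a single 1-based integer coding of
# their Cartesian product. Returns list(code, nlevels).
.cross_code <- function(...) {
  vars <- list(...)
  vars <- lapply(vars, function(v) {
    f <- factor(v)
    list(i = as.integer(f) - 1L, k = nlevels(f))
  })
  code <- 0L
  mult <- 1L
  for (v in vars) {
    code <- code + v$i * mult
    mult <- mult * v$k
  }
  list(code = code + 1L, nlevels = mult)
}

# MI(X; C) in bits from 1-based integer codes.
.mi_codes <- function(xc, xk, cc, ck) {
  joint <- tabulate(xc + xk * (cc - 1L), nbins = xk * ck)
  .entropy_counts(tabulate(xc, xk)) + .entropy_counts(tabulate(cc, ck)) -
    .entropy_counts(joint)
}

# Construct the result record shared by the information statistics.
.information_value <- function(bits, class_entropy, basis, variables, n) {
  structure(
    list(
      bits = bits,
      pct = if (class_entropy > 0) 100 * bits / class_entropy else NA_real_,
      basis = basis,
      variables = variables,
      class_entropy = class_entropy,
      n = n
    ),
    class = "information_value"
  )
}

#' @export
print.information_value <- function(x, ...) {
  cat(sprintf(
    "%s(%s): %.6f bits (%s of class entropy), n = %d\n",
    x$basis, paste(x$variables, collapse = ", "), x$bits,
    if (is.na(x$pct)) "NA%" else sprintf("%.3f%%", x$pct), x$n
  ))
  invisible(x)
}

.check_same_length <- function(...) {
  lens <- vapply(list(...), length, integer(1))
  if (length(unique(lens)) != 1L) stop("input sequences differ in length")
  if (lens[1] == 0L) stop("input sequences are empty")
}

#' Mutual information between a discrete variable and a class
#'
#' Plug-in mutual information \eqn{MI(X;C) = H(X) + H(C) - H(X,C)} in
#' bits. In a case-control setting this is the entropy-based main effect
#' of a single predictor on case status.
#'
#' @param x Discrete sequence (any coding; treated as categorical).
#' @param c Class labels, same length as `x` (binary in the intended use,
#'   but any discrete coding is accepted).
#' @param variables Optional names used for reporting.
#' @return An object of class `information_value` with fields `bits`,
#'   `pct` (100 x bits / H(C); `NA` when H(C) = 0), `basis`, `variables`
#'   and `n`.
#' @export
mutual_information <- function(x, c, variables = c("x", "c")) {
  .check_same_length(x, c)
  if (anyNA(x) || anyNA(c)) stop("missing values are not allowed")
  xf <- .cross_code(x)
  cf <- .cross_code(c)
  bits <- .mi_codes(xf$code, xf$nlevels, cf$code, cf$nlevels)
  # plug-in MI is nonnegative; clip tiny negative rounding noise
  if (bits < 0 && bits > -1e-12) bits <- 0
  hc <- .entropy_counts(tabulate(cf$code, cf$nlevels))
  .information_value(bits, hc, "MI", variables[1], length(x))
}

#' Joint mutual information of 2-3 predictors with a class
#'
#' Mutual information between the Cartesian product of up to three
#' discrete variables and the class: \eqn{MI(\{X_1,...,X_k\}; C)}.
#'
#' @param vars A list of 1-3 discrete sequences of equal length.
#' @param c Class labels.
#' @return Joint mutual information in bits (a single number).
#' @export
joint_mutual_information <- function(vars, c) {
  if (!is.list(vars) || length(vars) < 1L) {
    stop("'vars' must be a list of 1-3 sequences")
  }
  if (length(vars) > 3L) stop("orders above 3 are not supported")
  do.call(.check_same_length, c(vars, list(c)))
  xf <- do.call(.cross_code, vars)
  cf <- .cross_code(c)
  bits <- .mi_codes(xf$code, xf$nlevels, cf$code, cf$nlevels)
  if (bits < 0 && bits > -1e-12) bits <- 0
  bits
}

.check_class_informative <- function(c) {
  if (length(unique(c[!is.na(c)])) < 2L) {
    stop("class is constant: H(C) = 0, information gain undefined")
  }
}

#' Pairwise information gain
#'
#' The synergy statistic for a pair of predictors:
#' \deqn{IG(P_1;P_2;C) = MI(\{P_1,P_2\};C) - MI(P_1;C) - MI(P_2;C).}
#' Positive values indicate synergy between the two predictors with
#' respect to the class (an epistatic interaction); negative values
#' indicate redundancy. For a binary class the statistic lies in
#' \eqn{[-1, 1]} bits.
#'
#' @param x1,x2 Discrete predictor sequences.
#' @param c Class labels; must not be constant.
#' @param variables Optional predictor names for reporting.
#' @return An `information_value` with basis `"IG2"`.
#' @export
information_gain_pairwise <- function(x1, x2, c, variables = c("x1", "x2")) {
  .check_same_length(x1, x2, c)
  .check_class_informative(c)
  bits <- joint_mutual_information(list(x1, x2), c) -
    mutual_information(x1, c)$bits -
    mutual_information(x2, c)$bits
  cf <- .cross_code(c)
  hc <- .entropy_counts(tabulate(cf$code, cf$nlevels))
  .information_value(bits, hc, "IG2", variables, length(c))
}

#' Three-variable information gain with synergy-only subtraction
#'
#' Extends the pairwise information gain to triples:
#' \deqn{IG_3 = MI(\{P_1,P_2,P_3\};C) - \sum_{pairs} IG_2^{+} -
#'   \sum_i MI(P_i;C),}
#' where by default \eqn{IG_2^{+} = \max(IG_2, 0)}: only *synergistic*
#' lower-order interactions are subtracted, so that strongly redundant
#' (correlated) predictors do not inflate the three-way statistic. Set
#' `clamp_synergy = FALSE` to subtract the raw pairwise values instead.
#'
#' @param x1,x2,x3 Discrete predictor sequences.
#' @param c Class labels; must not be constant.
#' @param clamp_synergy Subtract only positive pairwise gains (default
#'   `TRUE`).
#' @param variables Optional predictor names for reporting.
#' @return An `information_value` with basis `"IG3"`.
#' @export
information_gain_threeway <- function(x1, x2, x3, c, clamp_synergy = TRUE,
                                      variables = c("x1", "x2", "x3")) {
  .check_same_length(x1, x2, x3, c)
  .check_class_informative(c)
  ig2 <- c(
    information_gain_pairwise(x1, x2, c)$bits,
    information_gain_pairwise(x2, x3, c)$bits,
    information_gain_pairwise(x1, x3, c)$bits
  )
  if (clamp_synergy) ig2 <- pmax(ig2, 0)
  bits <- joint_mutual_information(list(x1, x2, x3), c) - sum(ig2) -
    mutual_information(x1, c)$bits -
    mutual_information(x2, c)$bits -
    mutual_information(x3, c)$bits
  cf <- .cross_code(c)
  hc <- .entropy_counts(tabulate(cf$code, cf$nlevels))
  .information_value(bits, hc, "IG3", variables, length(c))
}

#' Express an information statistic as a percentage of class entropy
#'
#' @param bits Information in bits.
#' @param class_entropy H(C) in bits; must be positive.
#' @return 100 * bits / class_entropy.
#' @export
to_percent <- function(bits, class_entropy) {
  if (!is.finite(class_entropy) || class_entropy <= 0) {
    stop("'class_entropy' must be positive")
  }
  100 * bits / class_entropy
}

## ---- fast counts-based kernels -------------------------------------------
##
## The permutation screen and the exhaustive small-table checks operate on
## binary predictors and a binary class, where all entropies reduce to sums
## over an 8-cell (pairwise) or 16-cell (three-way) contingency table.
## These kernels are vectorized over rows of a table matrix; the
## sequence-level API above delegates to them implicitly through identical
## plug-in formulas (equality is asserted in the test suite).

#' Pairwise information gain from 2x2x2 contingency counts
#'
#' Vectorized kernel: each row of `counts` holds the 8 cells of the
#' (x1, x2, c) table in the order index \eqn{1 + x1 + 2 x2 + 4 c}.
#' This is the computation the permutation screen runs per model and per
#' permutation.
#'
#' @param counts Numeric vector of length 8, or a matrix with 8 columns
#'   (one table per row).
#' @return Information gain in bits, one value per table.
#' @export
ig_pairwise_counts <- function(counts) {
  m <- if (is.matrix(counts)) counts else matrix(counts, nrow = 1L)
  if (ncol(m) != 8L) stop("'counts' must have 8 cells per table")
  N <- rowSums(m)
  nl <- function(v) {
    out <- numeric(length(v))
    pos <- v > 0
    out[pos] <- v[pos] * log2(v[pos])
    out
  }
  SJ  <- nl(m[, 1]) + nl(m[, 2]) + nl(m[, 3]) + nl(m[, 4]) +
         nl(m[, 5]) + nl(m[, 6]) + nl(m[, 7]) + nl(m[, 8])
  S1C <- nl(m[, 1] + m[, 3]) + nl(m[, 2] + m[, 4]) +
         nl(m[, 5] + m[, 7]) + nl(m[, 6] + m[, 8])
  S2C <- nl(m[, 1] + m[, 2]) + nl(m[, 3] + m[, 4]) +
         nl(m[, 5] + m[, 6]) + nl(m[, 7] + m[, 8])
  x12 <- cbind(m[, 1] + m[, 5], m[, 2] + m[, 6],
               m[, 3] + m[, 7], m[, 4] + m[, 8])
  S12 <- nl(x12[, 1]) + nl(x12[, 2]) + nl(x12[, 3]) + nl(x12[, 4])
  S1  <- nl(x12[, 1] + x12[, 3]) + nl(x12[, 2] + x12[, 4])
  S2  <- nl(x12[, 1] + x12[, 2]) + nl(x12[, 3] + x12[, 4])
  SC  <- nl(m[, 1] + m[, 2] + m[, 3] + m[, 4]) +
         nl(m[, 5] + m[, 6] + m[, 7] + m[, 8])
  # H(V) = log2(N) - S_V / N; MI/IG terms assembled as
  # IG = [H12 + HC - HJ] - [H1 + HC - H1C] - [H2 + HC - H2C]
  out <- (SJ - S12 + S1 - S1C + S2 - S2C + SC) / N - log2(N)
  out[N == 0] <- NA_real_
  out
}

# Marginalize a 16-cell (x1,x2,x3,c) table (index 1 + x1 + 2 x2 + 4 x3 + 8 c)
# onto the 8-cell table of a chosen predictor pair and c.
.pair_margin16 <- function(m, i, j) {
  idx <- 0:15
  x <- list(idx %% 2L, (idx %/% 2L) %% 2L, (idx %/% 4L) %% 2L)
  cc <- idx %/% 8L
  tgt <- 1L + x[[i]] + 2L * x[[j]] + 4L * cc
  out <- matrix(0, nrow(m), 8L)
  for (cell in 1:16) out[, tgt[cell]] <- out[, tgt[cell]] + m[, cell]
  out
}

# Marginalize a 16-cell table to the 4-cell (x_i, c) table, order 1+x+2c.
.single_margin16 <- function(m, i) {
  idx <- 0:15
  x <- list(idx %% 2L, (idx %/% 2L) %% 2L, (idx %/% 4L) %% 2L)[[i]]
  cc <- idx %/% 8L
  tgt <- 1L + x + 2L * cc
  out <- matrix(0, nrow(m), 4L)
  for (cell in 1:16) out[, tgt[cell]] <- out[, tgt[cell]] + m[, cell]
  out
}

# MI(X;C) from 4-cell (x,c) tables, order 1 + x + 2c, vectorized by row.
.mi_counts4 <- function(m) {
  if (!is.matrix(m)) m <- matrix(m, nrow = 1L)
  N <- rowSums(m)
  nl <- function(v) {
    out <- numeric(length(v))
    pos <- v > 0
    out[pos] <- v[pos] * log2(v[pos])
    out
  }
  SJ <- nl(m[, 1]) + nl(m[, 2]) + nl(m[, 3]) + nl(m[, 4])
  SX <- nl(m[, 1] + m[, 3]) + nl(m[, 2] + m[, 4])
  SC <- nl(m[, 1] + m[, 2]) + nl(m[, 3] + m[, 4])
  out <- (SJ - SX - SC) / N + log2(N)
  out[N == 0] <- NA_real_
  out
}

#' Three-way information gain from 2x2x2x2 contingency counts
#'
#' Vectorized kernel over rows of a 16-column matrix; cell order index is
#' \eqn{1 + x_1 + 2 x_2 + 4 x_3 + 8 c}.
#'
#' @param counts Numeric vector of length 16 or matrix with 16 columns.
#' @param clamp_synergy Subtract only positive pairwise gains (default
#'   `TRUE`).
#' @return Three-way information gain in bits, one value per table.
#' @export
ig_threeway_counts <- function(counts, clamp_synergy = TRUE) {
  m <- if (is.matrix(counts)) counts else matrix(counts, nrow = 1L)
  if (ncol(m) != 16L) stop("'counts' must have 16 cells per table")
  N <- rowSums(m)
  nl <- function(v) {
    out <- numeric(length(v))
    pos <- v > 0
    out[pos] <- v[pos] * log2(v[pos])
    out
  }
  # joint MI({x1,x2,x3}; C) = H(X) + H(C) - H(X,C)
  SJ <- rowSums(matrix(nl(m), nrow(m), 16L))
  X <- m[, 1:8] + m[, 9:16]
  SX <- rowSums(matrix(nl(X), nrow(m), 8L))
  SC <- nl(rowSums(m[, 1:8, drop = FALSE])) +
        nl(rowSums(m[, 9:16, drop = FALSE]))
  mi_joint <- (SJ - SX - SC) / N + log2(N)
  ig12 <- ig_pairwise_counts(.pair_margin16(m, 1L, 2L))
  ig23 <- ig_pairwise_counts(.pair_margin16(m, 2L, 3L))
  ig13 <- ig_pairwise_counts(.pair_margin16(m, 1L, 3L))
  if (clamp_synergy) {
    ig12 <- pmax(ig12, 0); ig23 <- pmax(ig23, 0); ig13 <- pmax(ig13, 0)
  }
  mi1 <- .mi_counts4(.single_margin16(m, 1L))
  mi2 <- .mi_counts4(.single_margin16(m, 2L))
  mi3 <- .mi_counts4(.single_margin16(m, 3L))
  out <- mi_joint - ig12 - ig23 - ig13 - mi1 - mi2 - mi3
  out[N == 0] <- NA_real_
  out
}
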