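# Permutation null distributions, p-values and Bonferroni familywise
# thresholds for the entropy statistics, plus the interaction screen
# that ties them together.

#' Enumerate interaction models
#'
#' All unordered combinations of the predictor names at the requested
#' order; with the eight study predictors this yields 28 pairwise and
#' 56 three-variable models.
#'
#' @param variables Predictor names.
#' @param order 2 or 3 (use [run_screen()] with `order = 1` for main
#'   effects).
#' @return data.frame with columns `v1`, `v2` (and `v3`), one row per
#'   model.
#' @export
enumerate_models <- function(variables, order) {
  if (!order %in% 2:3) stop("'order' must be 2 or 3")
  if (length(variables) < order) stop("need at least ", order, " variables")
  combos <- utils::combn(variables, order)
  out <- as.data.frame(t(combos), stringsAsFactors = FALSE)
  names(out) <- paste0("v", seq_len(order))
  out
}

#' Generate shared permutations of the outcome
#'
#' Uniformly random reorderings of the outcome vector. The same
#' permutation set is reused for every model within a testing family so
#' that Monte-Carlo noise is shared rather than independent across
#' models.
#'
#' @param c Outcome vector.
#' @param B Number of permutations (default 1000).
#' @param seed Integer seed.
#' @return Integer matrix, `length(c)` rows by `B` columns.
#' @export
permute_outcomes <- function(c, B = 1000, seed = 1) {
  if (B < 1) stop("'B' must be >= 1")
  .with_stream(seed, "permute_outcomes")
  matrix(vapply(seq_len(B), function(b) c[sample.int(length(c))], c),
         ncol = B)
}

#' One-sided permutation p-value
#'
#' Add-one estimator \eqn{p = (1 + \#\{null \ge obs\}) / (B + 1)}; ties
#' count toward the null, and the smallest attainable p-value at
#' B = 1000 is 1/1001 (reported as 0.001).
#'
#' @param observed Observed statistic.
#' @param null_values Vector of permutation statistics.
#' @return p-value in (0, 1].
#' @export
permutation_pvalue <- function(observed, null_values) {
  if (length(null_values) < 1L) stop("empty permutation null")
  # >= with a tiny tolerance so exact ties computed in floating point count
  (1 + sum(null_values >= observed - 1e-12)) / (length(null_values) + 1)
}

#' Bonferroni familywise significance verdict
#'
#' Two familywise error budgets are controlled at once: `fwer_sig`
#' (default 0.05) defines *significant* associations and `fwer_sug`
#' (default 0.1) *suggestive* ones; each is divided by the number of
#' tests in the family. Printed-style thresholds rounded to one
#' significant digit are reported alongside the exact values (0.05/28
#' prints as 0.002, 0.1/28 as 0.004, 0.05/56 as 0.0009).
#'
#' @param p Unadjusted p-value (vectorized).
#' @param m Number of tests in the family.
#' @param fwer_sig,fwer_sug Familywise error budgets.
#' @return List with `class` (character: `"significant"`,
#'   `"suggestive"` or `"null"`), `m`, exact thresholds and their
#'   printed (1-significant-digit) forms.
#' @export
bonferroni_class <- function(p, m, fwer_sig = 0.05, fwer_sug = 0.1) {
  if (m < 1) stop("'m' must be >= 1")
  thr_sig <- fwer_sig / m
  thr_sug <- fwer_sug / m
  cls <- ifelse(p <= thr_sig, "significant",
                ifelse(p <= thr_sug, "suggestive", "null"))
  list(class = cls, m = m,
       threshold_significant = thr_sig,
       threshold_suggestive = thr_sug,
       printed_significant = signif(thr_sig, 1),
       printed_suggestive = signif(thr_sug, 1))
}

# Observed + permuted statistics for one model given precomputed 1-based
# predictor codes. perms is the permutation matrix from permute_outcomes.
.stat_with_null <- function(code, k, y, perms, statfun) {
  obs <- statfun(tabulate(code + k * y, nbins = 2L * k))
  null <- vapply(seq_len(ncol(perms)), function(b) {
    statfun(tabulate(code + k * perms[, b], nbins = 2L * k))
  }, numeric(1))
  list(obs = obs, null = null)
}

#' Permutation screen of main effects or interaction models
#'
#' For every model of the requested order, computes the entropy
#' statistic (mutual information for `order = 1`, pairwise information
#' gain for `order = 2`, three-way information gain with synergy-only
#' subtraction for `order = 3`), a one-sided permutation p-value from a
#' permutation set shared across the family, and a Bonferroni verdict
#' with `m` equal to the family size. Constant predictor columns are
#' degenerate under any dichotomization and are excluded with a
#' warning; negative (redundant) statistics are reported but are never
#' classed significant because the test is one-sided toward synergy.
#'
#' @param cohort A [discrete_cohort()].
#' @param order 1 (main effects), 2 or 3.
#' @param B Number of permutations (default 1000).
#' @param seed Integer seed for the shared permutation set.
#' @param fwer_sig,fwer_sug Familywise error budgets (defaults 0.05 and
#'   0.1).
#' @param clamp_synergy Synergy-only subtraction for `order = 3`
#'   (default `TRUE`).
#' @return data.frame with one row per model: variables, `order`,
#'   `bits`, `pct` (percent of class entropy), `p`, `class`; family
#'   metadata (`m`, `B`, `seed`, thresholds, class entropy, `n`) is
#'   attached as attribute `family`.
#' @export
run_screen <- function(cohort, order = 2, B = 1000, seed = 1,
                       fwer_sig = 0.05, fwer_sug = 0.1,
                       clamp_synergy = TRUE) {
  stopifnot(inherits(cohort, "discrete_cohort"))
  if (!order %in% 1:3) stop("'order' must be 1, 2 or 3")
  P <- predictor_matrix(cohort)
  y <- outcome_vector(cohort)
  if (length(unique(y)) < 2L) stop("outcome is constant")
  constant <- apply(P, 2, function(v) length(unique(v)) < 2L)
  if (any(constant)) {
    warning("excluding degenerate constant predictor(s): ",
            paste(colnames(P)[constant], collapse = ", "))
    P <- P[, !constant, drop = FALSE]
  }
  vars <- colnames(P)
  if (length(vars) < order) stop("fewer usable predictors than 'order'")
  hc <- entropy(tabulate(y + 1L, 2L))
  perms <- permute_outcomes(y, B = B, seed = seed)

  if (order == 1L) {
    models <- data.frame(v1 = vars, stringsAsFactors = FALSE)
    stats_ <- lapply(vars, function(v) {
      .stat_with_null(1L + P[, v], 2L, y, perms, .mi_counts4)
    })
  } else if (order == 2L) {
    models <- enumerate_models(vars, 2L)
    stats_ <- lapply(seq_len(nrow(models)), function(i) {
      code <- 1L + P[, models$v1[i]] + 2L * P[, models$v2[i]]
      .stat_with_null(code, 4L, y, perms, ig_pairwise_counts)
    })
  } else {
    models <- enumerate_models(vars, 3L)
    stats_ <- lapply(seq_len(nrow(models)), function(i) {
      code <- 1L + P[, models$v1[i]] + 2L * P[, models$v2[i]] +
        4L * P[, models$v3[i]]
      .stat_with_null(code, 8L, y, perms, function(counts) {
        ig_threeway_counts(counts, clamp_synergy = clamp_synergy)
      })
    })
  }

  bits <- vapply(stats_, `[[`, numeric(1), "obs")
  p <- vapply(stats_, function(s) permutation_pvalue(s$obs, s$null),
              numeric(1))
  verdict <- bonferroni_class(p, m = nrow(models),
                              fwer_sig = fwer_sig, fwer_sug = fwer_sug)
  cls <- verdict$class
  cls[bits < 0] <- "null"  # one-sided toward synergy: redundancy never called
  out <- cbind(models,
               data.frame(order = order, bits = bits,
                          pct = to_percent(bits, hc), p = p,
                          class = cls,
                          stringsAsFactors = FALSE))
  attr(out, "family") <- list(
    order = order, m = verdict$m, B = B, seed = seed,
    threshold_significant = verdict$threshold_significant,
    threshold_suggestive = verdict$threshold_suggestive,
    printed_significant = verdict$printed_significant,
    printed_suggestive = verdict$printed_suggestive,
    class_entropy = hc, n = length(y),
    fwer_sig = fwer_sig, fwer_sug = fwer_sug,
    clamp_synergy = if (order == 3L) clamp_synergy else NA
  )
  out
}
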