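# Post-hoc characterization of a significant pairwise interaction:
# interaction-group assignment, proportion tests with a Fisher dispatch
# for sparse cells, descriptive statistics, and group summaries.

#' Assign interaction-group membership for a predictor pair
#'
#' Groups follow the published ordering for (v1, v2) = (exposure,
#' status) pairs: group 1 = (0, 0), group 2 = (0, 1), group 3 = (1, 0),
#' group 4 = (1, 1). For the pre-natal smoke x SES interaction this
#' reads: [1] no PSE and low SES, [2] no PSE and med/high SES, [3] PSE
#' and low SES, [4] PSE and med/high SES.
#'
#' @param v1,v2 Binary vectors of equal length.
#' @return Integer group ids in 1..4; the four groups partition the
#'   cohort.
#' @export
assign_groups <- function(v1, v2) {
  if (length(v1) != length(v2)) stop("lengths differ")
  if (!all(c(v1, v2) %in% c(0, 1))) stop("both variables must be binary")
  as.integer(1L + 2L * v1 + v2)
}

#' Two-group test of proportions with Fisher dispatch
#'
#' Pearson's chi-squared statistic of the two-group test of proportions
#' (with continuity correction); when any observed cell count is below
#' 5, Fisher's exact test (two-sided) is used instead and the method is
#' recorded.
#'
#' @param table A 2x2 matrix of counts: rows = groups, columns =
#'   responder / non-responder.
#' @return List: `p`, `method` (`"chisq"` or `"fisher"`), `statistic`
#'   (chi-squared only).
#' @export
two_proportion_test <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == 2L)) stop("'table' must be 2x2")
  if (any(table < 0) || any(table != round(table))) {
    stop("counts must be nonnegative integers")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("zero margin: test undefined")
  }
  if (any(table < 5)) {
    list(p = stats::fisher.test(table)$p.value, method = "fisher",
         statistic = NA_real_)
  } else {
    ht <- stats::prop.test(table, correct = TRUE)
    list(p = ht$p.value, method = "chisq",
         statistic = unname(ht$statistic))
  }
}

#' Chi-squared test of independence for a 2x2 table
#'
#' Pearson chi-squared on 1 degree of freedom *with* Yates continuity
#' correction -- the convention that reproduces the published
#' descriptive-table p-values from their printed counts.
#'
#' @param table 2x2 count matrix with positive margins.
#' @return p-value.
#' @export
chi2_independence <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == 2L)) stop("'table' must be 2x2")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("zero margin: test undefined")
  }
  stats::chisq.test(table, correct = TRUE)$p.value
}

#' Wilcoxon rank-sum test
#'
#' Two-sided rank-sum comparison of two samples; exact for small
#' untied samples, otherwise the normal approximation with continuity
#' and tie corrections.
#'
#' @param a,b Numeric samples (both nonempty).
#' @return p-value.
#' @export
ranksum_test <- function(a, b) {
  if (!length(a) || !length(b)) stop("both samples must be nonempty")
  suppressWarnings(stats::wilcox.test(a, b)$p.value)
}

#' Summaries of continuous BDR by interaction group and sex
#'
#' @param bdr_pct Continuous percent BDR.
#' @param groups Group ids from [assign_groups()].
#' @param sex Binary sex code (1 = female), or `NULL` for pooled
#'   summaries.
#' @return data.frame per group (x sex): `n`, `median`, `q1`, `q3`,
#'   `iqr`, `above_population_median` (group median at/above the
#'   population median), `responder_fraction` (share with BDR >= 12%).
#'   Empty strata are flagged with `n = 0` rows rather than dropped.
#' @export
group_summary <- function(bdr_pct, groups, sex = NULL) {
  pop_med <- stats::median(bdr_pct)
  strata <- if (is.null(sex)) data.frame(group = sort(unique(groups)))
            else expand.grid(group = sort(unique(groups)),
                             sex = sort(unique(sex)))
  rows <- lapply(seq_len(nrow(strata)), function(i) {
    sel <- groups == strata$group[i]
    if (!is.null(sex)) sel <- sel & sex == strata$sex[i]
    v <- bdr_pct[sel]
    if (!length(v)) {
      return(cbind(strata[i, , drop = FALSE],
                   data.frame(n = 0L, median = NA_real_, q1 = NA_real_,
                              q3 = NA_real_, iqr = NA_real_,
                              above_population_median = NA,
                              responder_fraction = NA_real_)))
    }
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    cbind(strata[i, , drop = FALSE],
          data.frame(n = length(v), median = q[2], q1 = q[1], q3 = q[3],
                     iqr = q[3] - q[1],
                     above_population_median = q[2] >= pop_med,
                     responder_fraction =
                       mean(v >= bdr_response_threshold())))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Descriptive summary table of a cohort
#'
#' One row per binary predictor: counts among responders and
#' non-responders, the mutual-information permutation p-value (its own
#' Bonferroni family of m = number of predictors), and the
#' continuity-corrected chi-squared p-value. When `age_years` is
#' present a continuous-age row compares responder and non-responder
#' ages with the Wilcoxon rank-sum test.
#'
#' @param cohort A [discrete_cohort()].
#' @param B Permutations for the MI p-values (default 1000).
#' @param seed Seed for the shared permutation set.
#' @return data.frame with columns `variable`, `responders_1` /
#'   `nonresponders_1` (count coded 1), `responders_0` /
#'   `nonresponders_0`, `mi_p`, `mi_class`, `chi2_p`; the continuous
#'   age row reports the rank-sum p in `chi2_p`. The MI family
#'   metadata is attached as attribute `family`.
#' @export
descriptive_table <- function(cohort, B = 1000, seed = 1) {
  stopifnot(inherits(cohort, "discrete_cohort"))
  y <- outcome_vector(cohort)
  main <- run_screen(cohort, order = 1, B = B, seed = seed)
  P <- predictor_matrix(cohort)
  rows <- lapply(main$v1, function(v) {
    x <- P[, v]
    tab <- matrix(c(sum(x == 1 & y == 1), sum(x == 1 & y == 0),
                    sum(x == 0 & y == 1), sum(x == 0 & y == 0)),
                  2, byrow = TRUE)
    chi2 <- tryCatch(chi2_independence(tab), error = function(e) NA_real_)
    data.frame(variable = v,
               responders_1 = tab[1, 1], nonresponders_1 = tab[1, 2],
               responders_0 = tab[2, 1], nonresponders_0 = tab[2, 2],
               mi_p = main$p[main$v1 == v],
               mi_class = main$class[main$v1 == v],
               chi2_p = chi2, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if ("age_years" %in% names(cohort)) {
    age <- cohort$age_years
    out <- rbind(out, data.frame(
      variable = "age_years (continuous)",
      responders_1 = NA, nonresponders_1 = NA,
      responders_0 = NA, nonresponders_0 = NA,
      mi_p = NA, mi_class = NA,
      chi2_p = ranksum_test(age[y == 1], age[y == 0]),
      stringsAsFactors = FALSE))
  }
  attr(out, "family") <- attr(main, "family")
  out
}

#' Pairwise comparisons of responder proportions between groups
#'
#' Runs [two_proportion_test()] for each requested pair of interaction
#' groups (optionally within or across sex strata) and applies a
#' Bonferroni correction with m = number of comparisons drawn.
#'
#' @param outcome Binary responder status.
#' @param groups Group ids from [assign_groups()].
#' @param comparisons data.frame with columns `g1`, `g2` (group ids);
#'   default all unordered pairs present.
#' @return data.frame: `g1`, `g2`, counts, `p`, `method`,
#'   `p_bonferroni`, `significant` (at familywise 0.05).
#' @export
compare_group_proportions <- function(outcome, groups, comparisons = NULL) {
  gs <- sort(unique(groups))
  if (is.null(comparisons)) {
    cmb <- utils::combn(gs, 2)
    comparisons <- data.frame(g1 = cmb[1, ], g2 = cmb[2, ])
  }
  m <- nrow(comparisons)
  rows <- lapply(seq_len(m), function(i) {
    sel1 <- groups == comparisons$g1[i]
    sel2 <- groups == comparisons$g2[i]
    tab <- matrix(c(sum(outcome[sel1] == 1), sum(outcome[sel1] == 0),
                    sum(outcome[sel2] == 1), sum(outcome[sel2] == 0)),
                  2, byrow = TRUE)
    ht <- two_proportion_test(tab)
    data.frame(g1 = comparisons$g1[i], g2 = comparisons$g2[i],
               n1 = sum(sel1), n2 = sum(sel2),
               responders1 = tab[1, 1], responders2 = tab[2, 1],
               p = ht$p, method = ht$method, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(out$p * m, 1)
  out$significant <- out$p_bonferroni <= 0.05
  out
}
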