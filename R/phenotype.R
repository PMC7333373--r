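# Bronchodilator drug response and the dichotomization rules that turn
# raw clinical/environmental measurements into the binary codes used by
# the entropy screen.

#' Clinical threshold for bronchodilator response (percent)
#'
#' Participants with a percent change in FEV1 at or above this value are
#' classified as responders.
#' @return 12 (percent).
#' @export
bdr_response_threshold <- function() 12

#' Percent bronchodilator drug response
#'
#' BDR is the percent change in forced expiratory volume in one second
#' (FEV1) from before to after albuterol administration, using the
#' post-albuterol measurement with the maximal change:
#' \deqn{BDR = \max_j \; 100 \times (post_j - pre) / pre.}
#'
#' @param pre_fev1 Pre-albuterol FEV1 in liters (> 0).
#' @param post_fev1_values One or more post-albuterol FEV1 values
#'   (liters).
#' @return BDR in percent.
#' @examples
#' compute_bdr(2.0, c(2.1, 2.4))  # 20: the maximal post value is used
#' @export
compute_bdr <- function(pre_fev1, post_fev1_values) {
  if (!is.finite(pre_fev1) || pre_fev1 <= 0) {
    stop("invalid measurement: pre-albuterol FEV1 must be positive")
  }
  if (length(post_fev1_values) < 1L || any(!is.finite(post_fev1_values))) {
    stop("at least one finite post-albuterol FEV1 value is required")
  }
  max(100 * (post_fev1_values - pre_fev1) / pre_fev1)
}

#' Classify responder status from percent BDR
#'
#' @param bdr_pct Percent BDR (finite).
#' @return 1 for a responder (BDR >= 12%), 0 otherwise. Vectorized.
#' @export
classify_responder <- function(bdr_pct) {
  if (any(!is.finite(bdr_pct))) stop("'bdr_pct' must be finite")
  as.integer(bdr_pct >= bdr_response_threshold())
}

#' A stored dichotomization rule
#'
#' Records how a raw variable was converted to its 0/1 code so the same
#' rule re-applied to the same values reproduces identical codes. The
#' resolved threshold (e.g. the sample median actually used) is stored,
#' not the instruction to compute it.
#'
#' @param variable Variable name.
#' @param kind One of `"median_split"`, `"fixed_threshold"`,
#'   `"any_affirmative"`, `"composite_ses"`.
#' @param threshold Resolved numeric threshold (for median/fixed kinds,
#'   and the low-SES cutoff for `composite_ses`).
#' @param direction `"ge1"` (code 1 iff value >= threshold) or
#'   `"lt1"` (code 1 iff value < threshold).
#' @return An object of class `dichotomization_rule`.
#' @export
dichotomization_rule <- function(variable, kind, threshold = NA_real_,
                                 direction = "ge1") {
  kind <- match.arg(kind, c("median_split", "fixed_threshold",
                            "any_affirmative", "composite_ses"))
  direction <- match.arg(direction, c("ge1", "lt1"))
  structure(list(variable = variable, kind = kind,
                 threshold = threshold, direction = direction),
            class = "dichotomization_rule")
}

#' Re-apply a stored dichotomization rule
#'
#' @param rule A `dichotomization_rule` with a resolved threshold.
#' @param values Raw values (a numeric vector; for `composite_ses`, the
#'   already-summed composite score).
#' @return Integer 0/1 codes.
#' @export
apply_rule <- function(rule, values) {
  stopifnot(inherits(rule, "dichotomization_rule"))
  if (rule$kind == "any_affirmative") {
    stop("any_affirmative rules apply to response sets; use eod_any()")
  }
  if (rule$kind == "composite_ses") {
    return(as.integer(values > rule$threshold))
  }
  if (is.na(rule$threshold)) stop("rule threshold is unresolved")
  if (rule$direction == "ge1") as.integer(values >= rule$threshold)
  else as.integer(values < rule$threshold)
}

#' Median-split dichotomization
#'
#' Codes 1 for values at or above the sample median of the analysis
#' population (ties at the median are coded 1), 0 below it.
#'
#' @param values Numeric vector (length >= 2).
#' @return List with `codes` (integer 0/1), `threshold` (the resolved
#'   median) and `rule` (a reusable [dichotomization_rule()]).
#' @export
dichotomize_median <- function(values) {
  if (length(values) < 2L || anyNA(values)) {
    stop("need >= 2 non-missing values to resolve a median split")
  }
  thr <- stats::median(values)
  rule <- dichotomization_rule("value", "median_split", thr, "ge1")
  list(codes = apply_rule(rule, values), threshold = thr, rule = rule)
}

#' Fixed-threshold dichotomization
#'
#' Used for global African ancestry (1 iff proportion >= 0.80) and BMI
#' percentile (1 iff percentile >= 95, the obese classification).
#'
#' @param values Numeric vector.
#' @param cutoff Finite threshold.
#' @param direction `"ge1"` (default; 1 iff value >= cutoff) or `"lt1"`.
#' @return Integer 0/1 codes.
#' @export
dichotomize_threshold <- function(values, cutoff, direction = "ge1") {
  if (!is.finite(cutoff)) stop("'cutoff' must be finite")
  if (any(!is.finite(values))) stop("'values' must be finite")
  apply_rule(dichotomization_rule("value", "fixed_threshold", cutoff,
                                  direction), values)
}

#' Any-affirmative coding of the discrimination questionnaire
#'
#' The experience-of-discrimination item asks about four situations
#' (school, medical care, store/restaurant, public setting); the
#' variable is coded 1 if any answer is affirmative.
#'
#' @param answers Four binary responses (a vector of length 4), or a
#'   4-column 0/1 matrix with one row per participant.
#' @return Integer 0/1 code(s).
#' @export
eod_any <- function(answers) {
  m <- if (is.matrix(answers)) answers else matrix(answers, nrow = 1L)
  if (ncol(m) != 4L) stop("exactly 4 situation responses are required")
  if (anyNA(m)) stop("missing questionnaire response (complete-case)")
  if (!all(m %in% c(0, 1))) stop("responses must be coded 0/1")
  out <- as.integer(rowSums(m) >= 1L)
  if (!is.matrix(answers)) out[1] else out
}

#' Composite socioeconomic status code
#'
#' Three indicators -- mother's educational attainment, insurance status
#' and household income -- are each scored 0 (low), 1 (medium) or
#' 2 (high). The composite is their sum (0-6); participants at or below
#' `low_cutoff` are classified low SES (code 0), all others medium/high
#' (code 1). The aggregation into a composite is a package convention;
#' the cutoff is deliberately configurable.
#'
#' @param mother_edu,insurance,income Component scores in \{0, 1, 2\}
#'   (vectorized).
#' @param low_cutoff Composite scores <= this value are low SES
#'   (default 1).
#' @return List with `codes` (1 = medium/high SES), `composite` (the
#'   0-6 scores) and `rule`.
#' @export
ses_composite <- function(mother_edu, insurance, income, low_cutoff = 1) {
  comps <- cbind(mother_edu, insurance, income)
  if (anyNA(comps)) stop("missing SES component (complete-case)")
  if (!all(comps %in% 0:2)) stop("SES components must be scored 0, 1 or 2")
  composite <- rowSums(comps)
  rule <- dichotomization_rule("ses", "composite_ses", low_cutoff, "ge1")
  list(codes = as.integer(composite > low_cutoff),
       composite = as.numeric(composite), rule = rule)
}

#' Flag BDR outliers by a mean +/- k SD fence
#'
#' @param bdr_values Raw percent BDR values (length >= 3).
#' @param k Fence width in standard deviations (default 4).
#' @return List with `kept` (indices inside the fence), `excluded`
#'   (indices outside), `fence` (lower/upper bounds) and a small
#'   human-readable `log`.
#' @export
exclude_bdr_outliers <- function(bdr_values, k = 4) {
  if (length(bdr_values) < 3L || anyNA(bdr_values)) {
    stop("need >= 3 non-missing BDR values")
  }
  mu <- mean(bdr_values)
  s <- stats::sd(bdr_values)
  fence <- c(lower = mu - k * s, upper = mu + k * s)
  out <- which(bdr_values < fence["lower"] | bdr_values > fence["upper"])
  list(
    kept = setdiff(seq_along(bdr_values), out),
    excluded = out,
    fence = fence,
    log = sprintf("excluded %d of %d values outside mean +/- %g SD [%g, %g]",
                  length(out), length(bdr_values), k,
                  fence["lower"], fence["upper"])
  )
}

#' Serialize dichotomization rules as a codebook
#'
#' @param rules A list of `dichotomization_rule` objects.
#' @param path Output JSON path.
#' @export
write_codebook <- function(rules, path) {
  entries <- lapply(rules, function(r) {
    list(variable = r$variable, kind = r$kind,
         threshold = r$threshold, direction = r$direction)
  })
  jsonlite::write_json(entries, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
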