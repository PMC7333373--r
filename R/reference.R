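# Published demographic reference counts for the age-adjusted
# bronchodilator-response cohort (n = 233: 118 responders, 115
# non-responders). One row per dichotomized predictor: counts of
# participants coded 1 and 0 among responders and non-responders, and
# the p-value printed alongside them (chi-squared test of independence,
# 2 decimals). These counts pin down the package's descriptive-test
# conventions: the continuity-corrected chi-squared reproduces every
# printed p-value, the uncorrected one does not.

#' Reference responder-by-predictor counts (age-adjusted cohort)
#'
#' 2x2 responder/non-responder counts for the six dichotomous
#' demographic variables of the age-adjusted study population of 233
#' youth with asthma, with the p-values printed next to them. Used to
#' validate [chi2_independence()].
#'
#' @return data.frame with columns `variable`, `responders_1`,
#'   `nonresponders_1`, `responders_0`, `nonresponders_0`,
#'   `printed_p`.
#' @export
reference_demographics <- function() {
  path <- system.file("extdata", "bdr_demographics_counts.csv",
                      package = "episcreen", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' 2x2 matrix for one reference demographic variable
#'
#' @param variable Row of [reference_demographics()] to extract.
#' @return 2x2 matrix: rows = coded 1 / coded 0, columns = responders /
#'   non-responders.
#' @export
reference_table <- function(variable) {
  ref <- reference_demographics()
  row <- ref[ref$variable == variable, ]
  if (nrow(row) != 1L) stop("unknown reference variable: ", variable)
  matrix(c(row$responders_1, row$nonresponders_1,
           row$responders_0, row$nonresponders_0),
         2, byrow = TRUE,
         dimnames = list(c("coded1", "coded0"),
                         c("responder", "nonresponder")))
}
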