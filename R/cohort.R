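# Cohort data model: a complete-case participant table with a binary
# outcome (bronchodilator responder status), binary predictors, and
# optional continuous companions (age in years, raw percent BDR).

#' Default predictor set for the BDR analysis
#'
#' The eight dichotomized predictors screened for interactions:
#' sex (1 = female), age at or above the cohort median (`age_hi`),
#' global African ancestry >= 80% (`afr_hi`), obesity by BMI percentile
#' (`bmi_obese`), any reported experience of discrimination (`eod_any`),
#' pre-natal smoke exposure (`pse`), medium/high composite socioeconomic
#' status (`ses_mh`) and first-year NO2 exposure at or above the cohort
#' median (`no2_hi`).
#'
#' @return Character vector of predictor column names.
#' @export
default_predictors <- function() {
  c("sex", "age_hi", "afr_hi", "bmi_obese", "eod_any", "pse", "ses_mh",
    "no2_hi")
}

.is_binary01 <- function(v) {
  is.numeric(v) && !anyNA(v) && all(v %in% c(0, 1))
}

#' Construct a validated discrete cohort
#'
#' @param data A data.frame with one row per participant.
#' @param predictors Names of the binary predictor columns (default
#'   [default_predictors()], intersected with what is present).
#' @param outcome Name of the binary outcome column (1 = responder).
#' @param id Optional name of a participant-id column.
#' @return The data.frame with class `discrete_cohort` and attributes
#'   `predictors` and `outcome`. Validation enforces: no missing values
#'   in outcome or predictors, all coded values in \{0, 1\}, and, when
#'   both `bdr_pct` and the outcome are present, the responder rule
#'   `outcome == (bdr_pct >= 12)`.
#' @export
discrete_cohort <- function(data, predictors = NULL, outcome = "outcome",
                            id = NULL) {
  stopifnot(is.data.frame(data))
  if (is.null(predictors)) {
    predictors <- intersect(default_predictors(), names(data))
  }
  missing_cols <- setdiff(c(predictors, outcome), names(data))
  if (length(missing_cols)) {
    stop("cohort is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  for (col in c(outcome, predictors)) {
    if (!.is_binary01(data[[col]])) {
      stop("column '", col, "' must be coded 0/1 with no missing values")
    }
  }
  if ("bdr_pct" %in% names(data)) {
    if (anyNA(data$bdr_pct) || !is.numeric(data$bdr_pct)) {
      stop("'bdr_pct' must be numeric and complete when present")
    }
    implied <- as.numeric(data$bdr_pct >= bdr_response_threshold())
    if (!all(implied == data[[outcome]])) {
      stop("outcome disagrees with the ", bdr_response_threshold(),
           "% responder rule applied to 'bdr_pct'")
    }
  }
  if ("age_years" %in% names(data)) {
    if (anyNA(data$age_years) || any(data$age_years < 0)) {
      stop("'age_years' must be complete and nonnegative")
    }
  }
  structure(data,
            class = c("discrete_cohort", "data.frame"),
            predictors = predictors, outcome = outcome, id = id)
}

#' @export
print.discrete_cohort <- function(x, ...) {
  p <- attr(x, "predictors")
  y <- x[[attr(x, "outcome")]]
  cat(sprintf(
    "discrete_cohort: %d participants, %d responders (%.1f%%), %d predictors\n",
    nrow(x), sum(y), 100 * mean(y), length(p)))
  cat("  predictors:", paste(p, collapse = ", "), "\n")
  invisible(x)
}

#' Predictor matrix of a cohort
#' @param cohort A `discrete_cohort`.
#' @return Integer matrix (participants x predictors).
#' @export
predictor_matrix <- function(cohort) {
  p <- attr(cohort, "predictors")
  m <- as.matrix(as.data.frame(cohort)[, p, drop = FALSE])
  storage.mode(m) <- "integer"
  m
}

#' Outcome vector of a cohort
#' @param cohort A `discrete_cohort`.
#' @return Integer 0/1 vector.
#' @export
outcome_vector <- function(cohort) {
  as.integer(cohort[[attr(cohort, "outcome")]])
}

#' Load a cohort from a delimited text file
#'
#' Reads a CSV (default) or TSV participant table, drops rows with any
#' missing value in the schema columns (complete-case analysis), and
#' validates the binary coding of outcome and predictors.
#'
#' @param path Path to a delimited text file with a header.
#' @param predictors,outcome,id Schema: column names expected in the
#'   file. Unknown schema columns are an error.
#' @param sep Field separator; inferred from the extension when `NULL`
#'   (`.tsv`/`.txt` are tab, everything else comma).
#' @return A `discrete_cohort`; the number of dropped incomplete rows is
#'   attached as attribute `n_dropped` and reported via a message.
#' @export
load_cohort <- function(path, predictors = default_predictors(),
                        outcome = "outcome", id = NULL, sep = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, na.strings = c("NA", ""))
  needed <- c(predictors, outcome,
              intersect(c("age_years", "bdr_pct", id), names(raw)))
  unknown <- setdiff(c(predictors, outcome, id), names(raw))
  if (length(unknown)) {
    stop("schema columns absent from file: ", paste(unknown, collapse = ", "))
  }
  keep <- stats::complete.cases(raw[, needed, drop = FALSE])
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message("load_cohort: dropped ", n_dropped,
            " incomplete row(s) (complete-case analysis)")
  }
  cohort <- discrete_cohort(raw[keep, , drop = FALSE], predictors = predictors,
                            outcome = outcome, id = id)
  attr(cohort, "n_dropped") <- n_dropped
  cohort
}

#' Write a cohort back to CSV
#' @param cohort A `discrete_cohort`.
#' @param path Output path.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}
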