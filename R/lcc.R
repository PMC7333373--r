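# Local case-control (LCC) subsampling: remove a confounder's effect on
# a binary outcome by keeping each observation with probability
# |y - p_tilde|, where p_tilde is the fitted probability from a pilot
# logistic model containing only the confounders. In the retained
# subsample the pilot's confounder effect is cancelled, so downstream
# analyses that cannot adjust for covariates can run unadjusted.

#' Fit the pilot confounder-only logistic model
#'
#' @param outcome Binary 0/1 outcome vector (non-constant).
#' @param confounders data.frame (or vector) of confounder values; the
#'   intended use is age only, but any set is accepted.
#' @return A `glm` fit of `outcome ~ confounders` (binomial, logit).
#' @export
fit_pilot <- function(outcome, confounders) {
  if (length(unique(outcome)) < 2L) stop("outcome is constant")
  if (!is.data.frame(confounders)) {
    confounders <- data.frame(confounder = confounders)
  }
  df <- cbind(data.frame(.y = outcome), confounders)
  fit <- stats::glm(.y ~ ., data = df, family = stats::binomial())
  if (!fit$converged) {
    stop("pilot logistic fit did not converge (deviance ",
         format(fit$deviance), " after ", fit$iter, " iterations)")
  }
  fit
}

#' Draw a local case-control subsample
#'
#' Each row is kept independently with probability
#' \eqn{|y_i - \tilde p_i|}; the expected subsample size is
#' \eqn{\sum_i |y_i - \tilde p_i|}. One Bernoulli draw is made per call
#' (no re-drawing to hit a target size).
#'
#' @param cohort A [discrete_cohort()].
#' @param confounders Names of confounder columns in the cohort
#'   (default `"age_years"`).
#' @param pilot Optional pre-fitted pilot model; fitted on the cohort
#'   when `NULL`.
#' @param seed Integer seed for the Bernoulli draw.
#' @return An object of class `lcc_draw`: `cohort` (the subsample as a
#'   `discrete_cohort`), `kept` (row indices), `accept_prob`,
#'   `pilot_coefficients`, `expected_size`, `seed`, and `balance` (the
#'   post-subsample diagnostic from [check_balance()], `NULL` when the
#'   subsample is empty).
#' @export
lcc_subsample <- function(cohort, confounders = "age_years", pilot = NULL,
                          seed = 1) {
  stopifnot(inherits(cohort, "discrete_cohort"))
  missing_c <- setdiff(confounders, names(cohort))
  if (length(missing_c)) {
    stop("confounder column(s) absent: ", paste(missing_c, collapse = ", "))
  }
  y <- outcome_vector(cohort)
  cdf <- as.data.frame(cohort)[, confounders, drop = FALSE]
  if (is.null(pilot)) pilot <- fit_pilot(y, cdf)
  ptilde <- as.numeric(stats::predict(pilot, newdata = cdf,
                                      type = "response"))
  accept <- abs(y - ptilde)
  stopifnot(all(accept >= 0 & accept <= 1))
  .with_stream(seed, "lcc_subsample")
  kept <- which(stats::runif(length(accept)) < accept)
  sub <- as.data.frame(cohort)[kept, , drop = FALSE]
  sub_cohort <- if (length(kept)) {
    discrete_cohort(sub, predictors = attr(cohort, "predictors"),
                    outcome = attr(cohort, "outcome"),
                    id = attr(cohort, "id"))
  } else NULL
  balance <- if (length(kept) > 0 &&
                 length(unique(sub[[attr(cohort, "outcome")]])) > 1L) {
    check_balance(sub_cohort, confounders)
  } else NULL
  structure(list(cohort = sub_cohort, kept = kept, accept_prob = accept,
                 pilot_coefficients = stats::coef(pilot),
                 expected_size = sum(accept), seed = seed,
                 balance = balance),
            class = "lcc_draw")
}

#' @export
print.lcc_draw <- function(x, ...) {
  cat(sprintf("lcc_draw: kept %d rows (expected %.1f)\n",
              length(x$kept), x$expected_size))
  if (!is.null(x$balance)) {
    b <- x$balance$diagnostics
    for (i in seq_len(nrow(b))) {
      cat(sprintf("  residual %s slope: %.4f (SE %.4f, Wald p = %.3f)\n",
                  b$confounder[i], b$slope[i], b$se[i], b$p[i]))
    }
  }
  invisible(x)
}

#' Check residual confounding after subsampling
#'
#' Refits the confounder-only logistic model on the subsample; a slope
#' indistinguishable from zero indicates the confounder's effect has
#' been removed.
#'
#' @param subsample A `discrete_cohort` (the retained rows).
#' @param confounders Confounder column names.
#' @return List with `diagnostics` (data.frame: confounder, slope, SE,
#'   Wald p) and `small_sample` (`TRUE` with a warning when fewer than
#'   20 rows).
#' @export
check_balance <- function(subsample, confounders = "age_years") {
  if (is.null(subsample) || nrow(subsample) == 0L) {
    stop("empty subsample: no balance diagnostic possible")
  }
  small <- nrow(subsample) < 20L
  if (small) warning("subsample has fewer than 20 rows; diagnostic unstable")
  y <- outcome_vector(subsample)
  cdf <- as.data.frame(subsample)[, confounders, drop = FALSE]
  fit <- suppressWarnings(fit_pilot(y, cdf))
  sm <- summary(fit)$coefficients
  rows <- rownames(sm) != "(Intercept)"
  list(diagnostics = data.frame(confounder = confounders,
                                slope = sm[rows, 1], se = sm[rows, 2],
                                p = sm[rows, 4], row.names = NULL),
       small_sample = small)
}
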