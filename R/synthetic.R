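# Synthetic cohort generator.
#
# Emulates the statistical structure the downstream analysis assumes:
# marginal predictor frequencies matching the study's descriptive table,
# a continuous age confounder acting on the outcome, and penetrance-table
# interactions whose marginal effects can be tuned to zero ("pure"
# epistasis). Everything is reproducible from a single integer seed.

#' Default predictor prevalences (age-adjusted cohort margins)
#'
#' Marginal frequencies of the seven Bernoulli-sampled predictors in the
#' post-adjustment analysis population of 233 participants (the eighth
#' predictor, `age_hi`, is derived by median-splitting the simulated
#' ages, so its prevalence is 1/2 by construction): 42% female, global
#' African ancestry >= 80% in 149/233, obesity in 86/233, any
#' discrimination experience in 114/233, pre-natal smoke exposure in
#' 40/233, medium/high SES in 154/233, NO2 at/above the median in
#' 116/233.
#'
#' @return Named numeric vector of prevalences.
#' @export
default_prevalences <- function() {
  c(sex = 0.42, afr_hi = 149 / 233, bmi_obese = 86 / 233,
    eod_any = 114 / 233, pse = 40 / 233, ses_mh = 154 / 233,
    no2_hi = 116 / 233)
}

#' Penetrance specification for an embedded interaction
#'
#' Maps every combination of 2 or 3 binary predictors to a probability
#' of the outcome. A pure (zero-marginal-effect) interaction such as XOR
#' is expressed directly, e.g. `c("00" = 0.1, "01" = 0.9, "10" = 0.9,
#' "11" = 0.1)`.
#'
#' @param variables Names of 2 or 3 predictors.
#' @param table Named probability vector covering all `2^k` value
#'   combinations; names are the concatenated 0/1 values of the
#'   predictors in `variables` order (e.g. `"01"`, `"110"`).
#' @return An object of class `penetrance_spec`.
#' @export
penetrance_spec <- function(variables, table) {
  k <- length(variables)
  if (!k %in% 2:3) stop("penetrance specs cover 2 or 3 predictors")
  combos <- apply(expand.grid(rep(list(0:1), k)), 1, paste, collapse = "")
  if (!setequal(names(table), combos)) {
    stop("penetrance table must cover all ", 2^k, " combinations: ",
         paste(combos, collapse = ", "))
  }
  if (any(table < 0 | table > 1)) stop("penetrances must lie in [0, 1]")
  structure(list(variables = variables, table = table[combos]),
            class = "penetrance_spec")
}

#' Specification of a synthetic cohort
#'
#' @param n Cohort size (default 617, the pre-adjustment study size).
#' @param prevalences Named Bernoulli prevalences for the sampled
#'   predictors, each strictly inside (0, 1).
#' @param age_mean,age_sd Mean and SD of the age distribution (years),
#'   truncated to `age_range` (defaults 14 and 3 on [8, 21]).
#' @param age_range Truncation bounds for age.
#' @param beta_age Confounder strength: log-odds of the outcome per year
#'   of age (default 0.2; set 0 for an unconfounded cohort). Age is
#'   centered at `age_mean` so the baseline prevalence is attained at
#'   the mean age.
#' @param baseline Baseline outcome prevalence where no penetrance spec
#'   applies (default 118/233, the responder fraction).
#' @param penetrance A list of [penetrance_spec()] objects; specs may
#'   not share predictors (the generative model would be ambiguous).
#' @param seed Integer seed controlling every random draw.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 617, prevalences = default_prevalences(),
                        age_mean = 14, age_sd = 3, age_range = c(8, 21),
                        beta_age = 0.2, baseline = 118 / 233,
                        penetrance = list(), seed = 1) {
  if (n < 1) stop("'n' must be >= 1")
  if (any(prevalences <= 0 | prevalences >= 1)) {
    stop("prevalences must lie strictly inside (0, 1)")
  }
  if (inherits(penetrance, "penetrance_spec")) penetrance <- list(penetrance)
  vars_used <- unlist(lapply(penetrance, `[[`, "variables"))
  if (anyDuplicated(vars_used)) {
    stop("penetrance specs share predictors: ambiguous generative model")
  }
  unknown <- setdiff(vars_used, c(names(prevalences), "age_hi"))
  if (length(unknown)) {
    stop("penetrance specs reference unknown predictors: ",
         paste(unknown, collapse = ", "))
  }
  structure(list(n = n, prevalences = prevalences, age_mean = age_mean,
                 age_sd = age_sd, age_range = age_range,
                 beta_age = beta_age, baseline = baseline,
                 penetrance = penetrance, seed = seed),
            class = "cohort_spec")
}

# Truncated-normal draws by inverse-CDF on the truncated interval.
.rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Sample the Bernoulli predictor table
#'
#' Independent Bernoulli draws per predictor at the prevalences stated
#' in the spec (the cohort generator adds the derived `age_hi` column
#' separately).
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed (defaults to the spec's seed; every sampler
#'   hashes the seed with its own purpose tag, so the predictor, age,
#'   outcome and BDR draws use distinct reproducible streams).
#' @return data.frame of 0/1 predictor columns.
#' @export
sample_predictors <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  .with_stream(seed, "predictors")
  out <- lapply(spec$prevalences, function(p) {
    as.integer(stats::runif(spec$n) < p)
  })
  as.data.frame(out)
}

#' Sample outcomes from penetrance tables plus an age confounder
#'
#' The outcome probability for a row is assembled on the logit scale:
#' the penetrance implied by the row's predictor combination (or the
#' baseline prevalence when no spec applies; disjoint specs contribute
#' additively as offsets from baseline), shifted by
#' `beta_age * (age - age_mean)`.
#'
#' @param predictors data.frame of binary predictors.
#' @param age Numeric ages (years), same length.
#' @param spec A [cohort_spec()].
#' @param seed Integer seed (defaults to the spec's seed; hashed with a
#'   purpose tag so the outcome draw is decoupled from the predictor
#'   draw).
#' @return Integer 0/1 outcome vector.
#' @export
sample_outcome <- function(predictors, age, spec, seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- nrow(predictors)
  if (length(age) != n) stop("'age' and 'predictors' lengths differ")
  for (ps in spec$penetrance) {
    missing_v <- setdiff(ps$variables, names(predictors))
    if (length(missing_v)) {
      stop("penetrance spec references absent predictors: ",
           paste(missing_v, collapse = ", "))
    }
  }
  eta <- rep(stats::qlogis(spec$baseline), n)
  for (ps in spec$penetrance) {
    key <- do.call(paste0, predictors[ps$variables])
    eta <- eta + stats::qlogis(ps$table[key]) - stats::qlogis(spec$baseline)
  }
  eta <- eta + spec$beta_age * (age - spec$age_mean)
  .with_stream(seed, "outcome")
  as.integer(stats::runif(n) < stats::plogis(eta))
}

#' Exact population information gain of a penetrance spec
#'
#' Enumerates the exact joint distribution of (predictors, outcome)
#' implied by independent Bernoulli predictors at the given prevalences
#' and the penetrance table (no age effect), and evaluates the pairwise
#' or three-way information gain on it analytically. This is the
#' brute-force oracle for parameter-recovery tests of the sampling
#' functions.
#'
#' @param pen A [penetrance_spec()].
#' @param prevalences Named prevalences covering the spec's predictors.
#' @param clamp_synergy Passed through for three-way specs.
#' @return Information gain in bits.
#' @export
population_ig <- function(pen, prevalences, clamp_synergy = TRUE) {
  stopifnot(inherits(pen, "penetrance_spec"))
  k <- length(pen$variables)
  pv <- prevalences[pen$variables]
  if (anyNA(pv)) stop("prevalences must cover the spec's predictors")
  combos <- expand.grid(rep(list(0:1), k))
  pcombo <- apply(combos, 1, function(x) prod(ifelse(x == 1, pv, 1 - pv)))
  pen_p <- pen$table[apply(combos, 1, paste, collapse = "")]
  # cell order matches the counts kernels: index 1 + x1 + 2 x2 (+ 4 x3) + 2^k c
  cells <- c(pcombo * (1 - pen_p), pcombo * pen_p)
  if (k == 2L) ig_pairwise_counts(cells)
  else ig_threeway_counts(cells, clamp_synergy = clamp_synergy)
}

# BDR values consistent with responder status: truncated normals on
# either side of the clinical threshold.
.sample_bdr_given_outcome <- function(outcome) {
  thr <- bdr_response_threshold()
  n <- length(outcome)
  bdr <- numeric(n)
  resp <- outcome == 1L
  bdr[resp] <- .rtruncnorm(sum(resp), mean = 16, sd = 6, lower = thr)
  bdr[!resp] <- .rtruncnorm(sum(!resp), mean = 6, sd = 6,
                            upper = thr - 1e-9)
  bdr
}

#' Generate a complete synthetic cohort
#'
#' Draws ages from a truncated normal, derives the `age_hi` predictor by
#' median-splitting the drawn ages, samples the remaining predictors as
#' independent Bernoullis, samples outcomes from the penetrance tables
#' plus the age confounder, and attaches a continuous `bdr_pct`
#' consistent with responder status.
#'
#' @param spec A [cohort_spec()].
#' @return A [discrete_cohort()] with columns `participant_id`,
#'   `age_years`, `bdr_pct`, the predictors and `outcome`; the spec is
#'   attached as attribute `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  .with_stream(spec$seed, "age")
  age <- .rtruncnorm(spec$n, spec$age_mean, spec$age_sd,
                     spec$age_range[1], spec$age_range[2])
  preds <- sample_predictors(spec)
  preds$age_hi <- if (spec$n >= 2) dichotomize_median(age)$codes
                  else 1L
  outcome <- sample_outcome(preds, age, spec)
  .with_stream(spec$seed, "bdr")
  bdr <- .sample_bdr_given_outcome(outcome)
  df <- data.frame(participant_id = sprintf("S%05d", seq_len(spec$n)),
                   age_years = age, bdr_pct = bdr)
  df <- cbind(df, preds)
  df$outcome <- outcome
  cohort <- discrete_cohort(df,
                            predictors = intersect(default_predictors(),
                                                   names(preds)),
                            outcome = "outcome", id = "participant_id")
  attr(cohort, "spec") <- spec
  cohort
}
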