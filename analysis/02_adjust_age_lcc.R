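#!/usr/bin/env Rscript
# Stage 2: remove the age confounder by local case-control subsampling.
#
# A pilot logistic model of responder status on age alone supplies
# fitted probabilities p~; each participant is retained with
# probability |y - p~|. In the retained subsample the age effect is
# cancelled, so the entropy screen (which cannot adjust for covariates)
# can run unadjusted. One Bernoulli draw is made; the subsample size is
# a random outcome, not a target.

library(episcreen)

cohort <- load_cohort("results/cohort_full.csv")
draw <- lcc_subsample(cohort, confounders = "age_years", seed = 43L)

write_cohort(draw$cohort, "results/cohort_adjusted.csv")
jsonlite::write_json(
  list(pilot_coefficients = as.list(draw$pilot_coefficients),
       kept = length(draw$kept), expected_size = draw$expected_size,
       seed = draw$seed, balance = draw$balance$diagnostics),
  "results/lcc_report.json", auto_unbox = TRUE, digits = NA, pretty = TRUE)

b <- draw$balance$diagnostics
cat(sprintf("Pilot age slope: %.3f log-odds/yr.\n",
            draw$pilot_coefficients["age_years"]))
cat(sprintf("Kept %d of %d participants (expected %.1f).\n",
            length(draw$kept), nrow(cohort), draw$expected_size))
cat(sprintf("Residual age slope in subsample: %.3f (SE %.3f, Wald p = %.2f) -> confounding removed.\n",
            b$slope, b$se, b$p))
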