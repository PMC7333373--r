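#!/usr/bin/env Rscript
# Stage 4: regression benchmark of the screen's selected models.
#
# Every pairwise and three-variable model not classed null is refit as
# a multiplicative-interaction logistic model adjusted for continuous
# age and all lower-order terms. Designs are screened for separation
# (linear-programming test), empty interaction cells and exact
# collinearity; sparse-cell models (< 5 per interaction cell) dispatch
# to Firth's bias-reduced fit with penalized likelihood-ratio p-values.

library(episcreen)

cohort <- load_cohort("results/cohort_adjusted.csv")
pair <- read.csv("results/screen_full_order2.csv")
triple <- read.csv("results/screen_full_order3.csv")

sel2 <- pair[pair$class != "null", , drop = FALSE]
sel3 <- triple[triple$class != "null", , drop = FALSE]
sel <- rbind(
  if (nrow(sel2)) cbind(sel2[, c("v1", "v2")], v3 = NA_character_,
                        sel2[, c("bits", "pct", "p")]),
  if (nrow(sel3)) sel3[, c("v1", "v2", "v3", "bits", "pct", "p")])

if (is.null(sel) || !nrow(sel)) {
  cat("No non-null screen hits to benchmark.\n")
} else {
  bench <- benchmark_models(cohort, sel)
  write.csv(bench, "results/regression_comparison.csv", row.names = FALSE)
  for (i in seq_len(nrow(bench))) {
    if (bench$assessable[i]) {
      cat(sprintf("%s: IG %.2f%% (perm p = %.3f) | OR %.3f, p = %.3f [%s]\n",
                  bench$model[i], bench$ig_pct[i], bench$ig_p[i],
                  bench$odds_ratio[i], bench$p[i], bench$method[i]))
    } else {
      cat(sprintf("%s: IG %.2f%% (perm p = %.3f) | not assessable (%s)\n",
                  bench$model[i], bench$ig_pct[i], bench$ig_p[i],
                  bench$reason[i]))
    }
  }
}
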