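# Shared fixtures: small synthetic cohorts built in code.

# Cohort with a pure XOR interaction between pse and ses_mh: penetrance
# flips around 0.5 so both marginal effects are exactly zero in the
# population.
xor_cohort <- function(n = 500, shift = 0.4, seed = 1, beta_age = 0) {
  pen <- penetrance_spec(
    c("pse", "ses_mh"),
    c("00" = 0.5 - shift, "01" = 0.5 + shift,
      "10" = 0.5 + shift, "11" = 0.5 - shift))
  prev <- default_prevalences()
  prev[c("pse", "ses_mh")] <- 0.5
  generate_cohort(cohort_spec(n = n, prevalences = prev,
                              beta_age = beta_age, baseline = 0.5,
                              penetrance = list(pen), seed = seed))
}

# Cohort with no effects at all: every predictor independent of the
# outcome and no age confounding.
null_cohort <- function(n = 233, seed = 1) {
  generate_cohort(cohort_spec(n = n, beta_age = 0, baseline = 0.5,
                              seed = seed))
}

# Independent entropy oracle used to cross-check the implementation:
# computes MI terms as a Kullback-Leibler double sum over the joint
# probability table rather than via entropy differences.
oracle_mi_kl <- function(joint) {
  joint <- joint / sum(joint)
  px <- rowSums(joint)
  pc <- colSums(joint)
  total <- 0
  for (i in seq_along(px)) for (j in seq_along(pc)) {
    p <- joint[i, j]
    if (p > 0) total <- total + p * log2(p / (px[i] * pc[j]))
  }
  total
}

# Oracle pairwise IG from an 8-cell table (order 1 + x1 + 2 x2 + 4 c),
# assembled from KL-form mutual informations.
oracle_ig2 <- function(cells8) {
  stopifnot(length(cells8) == 8)
  joint <- matrix(cells8, 4, 2)          # rows: (x1,x2) combos, cols: c
  x1 <- (0:3) %% 2
  x2 <- (0:3) %/% 2
  m1 <- rbind(colSums(joint[x1 == 0, ]), colSums(joint[x1 == 1, ]))
  m2 <- rbind(colSums(joint[x2 == 0, ]), colSums(joint[x2 == 1, ]))
  oracle_mi_kl(joint) - oracle_mi_kl(m1) - oracle_mi_kl(m2)
}
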