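# Synthetic cohort generator: reproducibility, marginal calibration,
# penetrance-table interactions, and the exact population oracle.

test_that("generation is bit-reproducible under a fixed seed", {
  s <- cohort_spec(n = 200, seed = 42)
  a <- generate_cohort(s)
  b <- generate_cohort(s)
  expect_identical(as.data.frame(a), as.data.frame(b))
  d <- generate_cohort(cohort_spec(n = 200, seed = 43))
  expect_false(identical(a$outcome, d$outcome))
})

test_that("predictor sampling hits the requested prevalence", {
  s <- cohort_spec(n = 1e5, prevalences = c(x = 0.5), seed = 1)
  tab <- sample_predictors(s)
  expect_lt(abs(mean(tab$x) - 0.5), 0.01)
  expect_identical(sample_predictors(s, seed = 9), sample_predictors(s, seed = 9))
  expect_error(cohort_spec(prevalences = c(x = 1.0)), "strictly inside")
  expect_error(cohort_spec(prevalences = c(x = 0)), "strictly inside")
})

test_that("penetrance tables are validated", {
  expect_error(penetrance_spec("pse", c("0" = 0.5, "1" = 0.5)), "2 or 3")
  expect_error(penetrance_spec(c("a", "b"), c("00" = 0.1, "01" = 0.9)),
               "cover all 4")
  expect_error(penetrance_spec(c("a", "b"),
                               c("00" = -0.1, "01" = 0.9, "10" = 0.9,
                                 "11" = 0.1)), "\\[0, 1\\]")
  pen <- penetrance_spec(c("pse", "ses_mh"),
                         c("00" = 0.1, "01" = 0.9, "10" = 0.9, "11" = 0.1))
  expect_error(cohort_spec(penetrance = list(pen, pen)), "share predictors")
})

test_that("outcome sampling recovers the penetrance cells", {
  pen <- penetrance_spec(c("pse", "ses_mh"),
                         c("00" = 0.1, "01" = 0.9, "10" = 0.9, "11" = 0.1))
  prev <- c(pse = 0.5, ses_mh = 0.5)
  s <- cohort_spec(n = 1e4, prevalences = prev, beta_age = 0,
                   penetrance = list(pen), seed = 4)
  preds <- sample_predictors(s)
  age <- rep(14, s$n)
  y <- sample_outcome(preds, age, s)
  for (a in 0:1) for (b in 0:1) {
    cell <- preds$pse == a & preds$ses_mh == b
    expect_lt(abs(mean(y[cell]) - pen$table[paste0(a, b)]), 0.02)
  }
})

test_that("flat penetrance yields predictor-independent outcomes", {
  pen <- penetrance_spec(c("pse", "ses_mh"),
                         c("00" = 0.5, "01" = 0.5, "10" = 0.5, "11" = 0.5))
  s <- cohort_spec(n = 5e4, prevalences = c(pse = 0.5, ses_mh = 0.5),
                   beta_age = 0, penetrance = list(pen), seed = 5)
  preds <- sample_predictors(s)
  y <- sample_outcome(preds, rep(14, s$n), s)
  expect_lt(mutual_information(preds$pse, y)$bits, 1e-3)
  expect_lt(abs(information_gain_pairwise(preds$pse, preds$ses_mh, y)$bits),
            1e-3)
})

test_that("a positive age coefficient induces positive age-outcome correlation", {
  s <- cohort_spec(n = 1e4, beta_age = 0.3, seed = 6)
  co <- generate_cohort(s)
  expect_gt(cor(co$age_years, co$outcome), 0.1)
})

test_that("population IG oracle matches hand-derivable cases", {
  prev <- c(a = 0.5, b = 0.5)
  fair_xor <- penetrance_spec(c("a", "b"),
                              c("00" = 0, "01" = 1, "10" = 1, "11" = 0))
  expect_equal(population_ig(fair_xor, prev), 1.0)
  flat <- penetrance_spec(c("a", "b"),
                          c("00" = 0.3, "01" = 0.3, "10" = 0.3, "11" = 0.3))
  expect_equal(population_ig(flat, prev), 0.0, tolerance = 1e-12)
  # soft XOR: marginals vanish, so IG = H(C) - H(C|X1,X2) = 1 - h2(0.1)
  soft <- penetrance_spec(c("a", "b"),
                          c("00" = 0.1, "01" = 0.9, "10" = 0.9, "11" = 0.1))
  h2 <- -(0.1 * log2(0.1) + 0.9 * log2(0.9))
  expect_equal(population_ig(soft, prev), 1 - h2, tolerance = 1e-12)
  # and against the independent KL-form oracle on the enumerated joint
  cells <- c(0.25 * (1 - c(0.1, 0.9, 0.9, 0.1)), 0.25 * c(0.1, 0.9, 0.9, 0.1))
  expect_equal(population_ig(soft, prev), oracle_ig2(cells),
               tolerance = 1e-12)
  # three-way parity penetrance: pure triple synergy of 1 - h2(p)
  combos3 <- expand.grid(0:1, 0:1, 0:1)
  tab3 <- stats::setNames(ifelse(rowSums(combos3) %% 2 == 1, 0.9, 0.1),
                          apply(combos3, 1, paste, collapse = ""))
  par3 <- penetrance_spec(c("a", "b", "c"), tab3)
  expect_equal(population_ig(par3, c(a = 0.5, b = 0.5, c = 0.5)),
               1 - h2, tolerance = 1e-12)
})

test_that("sampled IG converges to the population oracle", {
  pen <- penetrance_spec(c("pse", "ses_mh"),
                         c("00" = 0.1, "01" = 0.9, "10" = 0.9, "11" = 0.1))
  prev <- c(pse = 0.5, ses_mh = 0.5)
  s <- cohort_spec(n = 1e5, prevalences = prev, beta_age = 0,
                   penetrance = list(pen), seed = 10)
  preds <- sample_predictors(s)
  y <- sample_outcome(preds, rep(14, s$n), s)
  ig_hat <- information_gain_pairwise(preds$pse, preds$ses_mh, y)$bits
  expect_lt(abs(ig_hat - population_ig(pen, prev)), 0.01)
})

test_that("default cohorts match the study's structure", {
  co <- generate_cohort(cohort_spec(seed = 3))      # default n = 617
  expect_equal(nrow(co), 617)
  expect_lt(abs(mean(co$pse) - 40 / 233), 0.05)
  expect_true(all(co$age_years >= 8 & co$age_years <= 21))
  # age_hi is the median split of the drawn ages
  expect_identical(co$age_hi, dichotomize_median(co$age_years)$codes)
  expect_setequal(attr(co, "predictors"), default_predictors())
  one <- generate_cohort(cohort_spec(n = 1, seed = 1))
  expect_equal(nrow(one), 1)
})
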