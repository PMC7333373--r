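# BDR computation, dichotomization rules and cohort loading.

test_that("percent BDR uses the maximal post-albuterol change", {
  expect_equal(compute_bdr(2.0, 2.3), 15.0)
  expect_equal(compute_bdr(2.0, c(2.1, 2.4)), 20.0)
  expect_equal(compute_bdr(2.5, 2.5), 0.0)
  expect_error(compute_bdr(0, 2.0), "invalid measurement")
  expect_error(compute_bdr(-1, 2.0), "invalid measurement")
  expect_error(compute_bdr(2.0, numeric(0)))
})

test_that("responder classification uses the 12% threshold inclusively", {
  expect_equal(classify_responder(12.0), 1L)
  expect_equal(classify_responder(11.999), 0L)
  expect_equal(classify_responder(-5.0), 0L)
  expect_equal(classify_responder(c(30, 5)), c(1L, 0L))
  expect_error(classify_responder(NaN))
  expect_error(classify_responder(Inf))
})

test_that("responder status is monotone in every post-FEV1 value", {
  set.seed(5)
  for (i in 1:20) {
    pre <- runif(1, 1, 4)
    posts <- runif(3, 0.8, 5)
    base <- classify_responder(compute_bdr(pre, posts))
    j <- sample(3, 1)
    bumped <- posts
    bumped[j] <- bumped[j] + runif(1, 0, 1)
    expect_gte(classify_responder(compute_bdr(pre, bumped)), base)
  }
})

test_that("median split codes ties upward and records its threshold", {
  r <- dichotomize_median(c(1, 2, 3, 4))
  expect_equal(r$codes, c(0L, 0L, 1L, 1L))
  expect_equal(r$threshold, 2.5)
  expect_equal(dichotomize_median(c(10, 20, 30))$codes, c(0L, 1L, 1L))
  # all-equal input degenerates to constant 1 under the >=-median rule
  expect_equal(dichotomize_median(rep(7, 5))$codes, rep(1L, 5))
  expect_error(dichotomize_median(3), ">= 2")
})

test_that("stored rules reproduce identical codes when re-applied", {
  set.seed(8)
  vals <- rnorm(40, 10, 3)
  r <- dichotomize_median(vals)
  expect_identical(apply_rule(r$rule, vals), r$codes)
  expect_identical(apply_rule(r$rule, vals), apply_rule(r$rule, vals))
})

test_that("fixed thresholds are inclusive on the coded-1 side", {
  expect_equal(dichotomize_threshold(0.80, 0.80), 1L)     # ancestry at 80%
  expect_equal(dichotomize_threshold(0.799, 0.80), 0L)
  expect_equal(dichotomize_threshold(95.0, 95), 1L)       # BMI percentile
  expect_equal(dichotomize_threshold(c(0.5, 0.9), 0.8), c(0L, 1L))
  expect_error(dichotomize_threshold(1, NA), "finite")
})

test_that("discrimination experience codes any affirmative answer", {
  expect_equal(eod_any(c(0, 0, 0, 0)), 0L)
  expect_equal(eod_any(c(0, 1, 0, 0)), 1L)
  expect_equal(eod_any(c(1, 1, 1, 1)), 1L)
  expect_equal(eod_any(rbind(c(0, 0, 0, 0), c(1, 0, 0, 0))), c(0L, 1L))
  expect_error(eod_any(c(0, 1, 0)), "4")
  expect_error(eod_any(c(0, NA, 0, 0)), "missing")
})

test_that("SES composite sums three 0-2 components with a low cutoff", {
  expect_equal(ses_composite(0, 0, 0)$codes, 0L)
  expect_equal(ses_composite(2, 2, 2)$codes, 1L)
  expect_equal(ses_composite(1, 0, 0)$codes, 0L)   # sum 1 <= default cutoff
  expect_equal(ses_composite(1, 1, 0)$codes, 1L)   # sum 2 > default cutoff
  expect_equal(ses_composite(1, 0, 0, low_cutoff = 0)$codes, 1L)
  expect_equal(ses_composite(c(0, 2), c(0, 2), c(0, 1))$codes, c(0L, 1L))
  expect_error(ses_composite(3, 0, 0), "0, 1 or 2")
})

test_that("BDR outlier fence is mean +/- k SD with a log", {
  expect_equal(exclude_bdr_outliers(c(10, 11, 12, 13), k = 4)$kept, 1:4)
  vals <- c(10, 11, 12, 500)
  r <- exclude_bdr_outliers(vals, k = 1)
  expect_equal(r$excluded, 4L)                  # hand check: 500 > mean + sd
  expect_true(500 > mean(vals) + sd(vals))
  expect_true(all(vals[1:3] > mean(vals) - sd(vals)))
  expect_equal(exclude_bdr_outliers(vals, k = Inf)$kept, 1:4)
  expect_match(r$log, "excluded 1 of 4")
})

test_that("cohort loader is complete-case and rejects non-binary codes", {
  df <- data.frame(sex = c(0, 1, 0), age_hi = c(1, 0, 1),
                   afr_hi = c(1, 1, 0), bmi_obese = c(0, 0, 1),
                   eod_any = c(1, 0, 0), pse = c(0, 1, NA),
                   ses_mh = c(1, 1, 0), no2_hi = c(0, 0, 1),
                   outcome = c(1, 0, 1))
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  expect_message(co <- load_cohort(path), "dropped 1")
  expect_s3_class(co, "discrete_cohort")
  expect_equal(nrow(co), 2)
  expect_equal(attr(co, "n_dropped"), 1)

  df2 <- df[1:2, ]
  df2$pse <- c(0, 2)                              # non-binary code
  write.csv(df2, path, row.names = FALSE)
  expect_error(load_cohort(path), "coded 0/1")
  expect_error(load_cohort(path, predictors = c("sex", "nonexistent")),
               "absent")
})

test_that("cohort construction enforces outcome/BDR consistency", {
  co <- generate_cohort(cohort_spec(n = 50, seed = 2))
  expect_true(all(co$outcome == (co$bdr_pct >= 12)))
  bad <- as.data.frame(co)
  bad$outcome <- 1 - bad$outcome
  expect_error(discrete_cohort(bad), "responder rule")
})
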