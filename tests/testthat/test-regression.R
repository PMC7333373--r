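# Regression comparison arm: design construction, separation and
# collinearity screening, MLE and Firth fits.

test_that("pairwise and three-way designs have the stated columns", {
  co <- generate_cohort(cohort_spec(n = 120, seed = 31))
  d2 <- build_design(co, c("pse", "ses_mh"))
  expect_equal(colnames(d2$X),
               c("(Intercept)", "age_years", "pse", "ses_mh", "pse:ses_mh"))
  expect_equal(d2$X[, "pse:ses_mh"], co$pse * co$ses_mh)
  d3 <- build_design(co, c("pse", "ses_mh", "eod_any"))
  expect_equal(ncol(d3$X), 9)  # 1 + age + 3 mains + 3 pairs + triple
  expect_equal(d3$highest, "pse:ses_mh:eod_any")
  expect_equal(sum(d3$cell_counts), nrow(co))
  expect_error(build_design(co, c("pse", "pse")), "duplicate")
})

test_that("the LP detector classifies separation correctly", {
  expect_equal(detect_separation(cbind(1, c(0, 0, 1, 1)), c(0, 0, 1, 1)),
               "complete")
  expect_equal(detect_separation(cbind(1, c(0, 0, 1, 1)), c(0, 1, 0, 1)),
               "none")
  # quasi-separation: a single overlapping support point at x = 2
  expect_equal(detect_separation(cbind(1, c(0, 1, 2, 2, 3, 4)),
                                 c(0, 0, 0, 1, 1, 1)), "quasi")
  # brute-force cross-check on tiny designs: separation exists iff some
  # coefficient direction scores every point on its own side
  set.seed(32)
  for (i in 1:25) {
    x <- rbinom(6, 1, 0.5)
    y <- rbinom(6, 1, 0.5)
    X <- cbind(1, x)
    verdict <- detect_separation(X, y)
    sep_found <- FALSE
    for (b0 in seq(-2, 2, by = 0.25)) for (b1 in seq(-2, 2, by = 0.25)) {
      eta <- b0 + b1 * x
      if (all(ifelse(y == 1, eta, -eta) >= 0) && any(eta != 0)) {
        sep_found <- TRUE
      }
    }
    expect_equal(verdict != "none", sep_found)
  }
})

test_that("collinearity diagnostics flag aliasing and inflate for rare cells", {
  n <- 80
  set.seed(33)
  a <- rep(c(0, 1), each = n / 2)
  b <- rep(c(0, 1), times = n / 2)
  X <- cbind(`(Intercept)` = 1, a = a, b = b)
  d <- collinearity_diagnostics(X)
  expect_lt(max(abs(d$vif - 1)), 0.05)
  expect_length(d$flags, 0)
  Xd <- cbind(X, a2 = a)                      # duplicated column
  expect_true("aliased" %in% collinearity_diagnostics(Xd)$flags)
  rare <- rbinom(n, 1, 0.08)
  Xr <- cbind(`(Intercept)` = 1, v1 = rare, v2 = b, `v1:v2` = rare * b)
  expect_gt(max(collinearity_diagnostics(Xr)$vif), 1.5)
})

test_that("MLE reproduces the closed-form 2x2 odds ratio and refuses separation", {
  x <- c(rep(1, 40), rep(0, 60))
  y <- c(rep(1, 30), rep(0, 10), rep(1, 20), rep(0, 40))
  fit <- fit_logistic(cbind(`(Intercept)` = 1, x = x), y = y, method = "mle")
  expect_equal(fit$coefficients$odds_ratio[2], (30 * 40) / (10 * 20),
               tolerance = 1e-6)
  xs <- rep(c(0, 1), each = 5)
  expect_error(fit_logistic(cbind(`(Intercept)` = 1, x = xs), y = xs,
                            method = "mle"), "separation")
})

test_that("Firth on a saturated 2x2 equals the add-half-cell closed form", {
  # completely separated toy: cells a=5, b=0, c=0, d=5 -> OR 121, finite
  x <- rep(c(1, 0), each = 5)
  y <- rep(c(1, 0), each = 5)
  fit <- fit_logistic(cbind(`(Intercept)` = 1, x = x), y = y,
                      method = "firth")
  expect_equal(fit$coefficients$odds_ratio[2], (5.5 * 5.5) / (0.5 * 0.5),
               tolerance = 1e-6)
  # random tables, including zero cells: Haldane identity throughout
  set.seed(34)
  for (i in 1:10) {
    cells <- c(sample(0:10, 2), sample(1:10, 2))  # a, b (maybe 0), c, d
    if (cells[1] + cells[2] == 0) cells[1] <- 1
    xr <- rep(c(1, 1, 0, 0), times = cells)
    yr <- rep(c(1, 0, 1, 0), times = cells)
    if (length(unique(yr)) < 2 || length(unique(xr)) < 2) next
    fw <- episcreen:::.firth_newton(cbind(`(Intercept)` = 1, x = xr), yr)
    hald <- log((cells[1] + 0.5) * (cells[4] + 0.5) /
                  ((cells[2] + 0.5) * (cells[3] + 0.5)))
    expect_equal(unname(fw$coefficients["x"]), hald, tolerance = 1e-6)
  }
})

test_that("Firth and MLE agree on well-behaved balanced data", {
  set.seed(35)
  n <- 1e4
  x <- rbinom(n, 1, 0.5)
  y <- as.integer(runif(n) < plogis(-0.2 + 0.8 * x))
  X <- cbind(`(Intercept)` = 1, x = x)
  mle <- fit_logistic(X, y = y, method = "mle")$coefficients$estimate
  fir <- fit_logistic(X, y = y, method = "firth")$coefficients$estimate
  expect_lt(max(abs(mle - fir) / abs(mle)), 0.01)
})

test_that("auto dispatch uses Firth for sparse interaction cells", {
  co <- generate_cohort(cohort_spec(n = 300, seed = 36))
  df <- as.data.frame(co)
  # engineer a sparse (but nonempty) joint cell
  idx <- which(df$pse == 1 & df$ses_mh == 1)
  df$pse[idx[-(1:3)]] <- 0
  sparse <- discrete_cohort(df)
  des <- build_design(sparse, c("pse", "ses_mh"))
  expect_lt(des$min_cell, 5)
  fit <- fit_logistic(des, method = "auto")
  expect_equal(fit$method, "firth")
  expect_true(all(is.finite(fit$coefficients$estimate)))
})

test_that("a zero-effect interaction has OR near 1 in large samples", {
  set.seed(37)
  n <- 1e4
  prev <- default_prevalences()
  co <- generate_cohort(cohort_spec(n = n, beta_age = 0, seed = 37))
  fit <- fit_logistic(build_design(co, c("eod_any", "no2_hi")),
                      method = "mle")
  row <- fit$coefficients[fit$coefficients$term == "eod_any:no2_hi", ]
  expect_lt(abs(row$estimate), 3 * row$se)
})

test_that("benchmarking reports unassessable models with a reason", {
  co <- generate_cohort(cohort_spec(n = 200, seed = 38))
  df <- as.data.frame(co)
  df$pse[df$ses_mh == 1] <- 0            # empty (1,1) interaction cell
  broken <- discrete_cohort(df)
  hits <- data.frame(v1 = c("pse", "eod_any"), v2 = c("ses_mh", "no2_hi"),
                     bits = c(0.01, 0.02), pct = c(1, 2), p = c(0.5, 0.4))
  out <- benchmark_models(broken, hits)
  expect_equal(nrow(out), 2)
  expect_false(out$assessable[1])
  expect_match(out$reason[1], "collinear|separation|assessable")
  expect_true(out$assessable[2])
  expect_true(is.finite(out$odds_ratio[2]))
  expect_error(benchmark_models(co, hits[0, ]), "empty")
})
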