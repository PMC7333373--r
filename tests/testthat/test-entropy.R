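# Entropy, mutual information and information-gain statistics.

test_that("entropy matches the closed form and handles degenerate input", {
  expect_equal(entropy(c(50, 50)), 1.0)
  expect_equal(entropy(c(100, 0)), 0.0)
  expect_equal(entropy(c(75, 25)),
               -(0.75 * log2(0.75) + 0.25 * log2(0.25)))
  expect_error(entropy(c(0, 0)), "positive total")
  expect_error(entropy(numeric(0)))
  expect_error(entropy(c(-1, 2)), "nonnegative")
})

test_that("mutual information agrees with the likelihood-ratio G statistic", {
  # counts [[30,10],[20,40]]: MI = G / (2 N ln 2)
  tab <- matrix(c(30, 10, 20, 40), 2, byrow = TRUE)
  x <- rep(c(0, 0, 1, 1), times = c(30, 10, 20, 40))
  y <- rep(c(1, 0, 1, 0), times = c(30, 10, 20, 40))
  G <- 0
  N <- sum(tab)
  E <- outer(rowSums(tab), colSums(tab)) / N
  for (i in 1:2) for (j in 1:2) G <- G + 2 * tab[i, j] * log(tab[i, j] / E[i, j])
  expect_equal(mutual_information(x, y)$bits, G / (2 * N * log(2)),
               tolerance = 1e-12)
})

test_that("mutual information basics: identity, independence, symmetry", {
  x <- rep(c(0, 1), each = 10)
  expect_equal(mutual_information(x, x)$bits, 1.0)
  # exhaustive independent truth table
  g <- expand.grid(x = 0:1, c = 0:1)
  expect_equal(mutual_information(g$x, g$c)$bits, 0.0)
  set.seed(42)
  for (i in 1:20) {
    a <- rbinom(40, 1, 0.5)
    b <- rbinom(40, 1, 0.4)
    expect_equal(mutual_information(a, b)$bits,
                 mutual_information(b, a)$bits, tolerance = 1e-12)
    expect_gte(mutual_information(a, b)$bits, 0)
  }
  expect_error(mutual_information(c(0, 1), c(0, 1, 1)), "length")
})

test_that("joint mutual information: degenerate single, XOR, duplication", {
  set.seed(7)
  a <- rbinom(60, 1, 0.5)
  y <- rbinom(60, 1, 0.5)
  expect_equal(joint_mutual_information(list(a), y),
               mutual_information(a, y)$bits)
  g <- expand.grid(x1 = 0:1, x2 = 0:1)
  expect_equal(joint_mutual_information(list(g$x1, g$x2),
                                        (g$x1 + g$x2) %% 2), 1.0)
  expect_equal(joint_mutual_information(list(a, a), y),
               mutual_information(a, y)$bits, tolerance = 1e-12)
  expect_error(joint_mutual_information(list(a, a, a, a), y), "order")
})

test_that("pairwise IG: pure synergy, pure redundancy, independence", {
  g <- expand.grid(x1 = 0:1, x2 = 0:1)
  ig <- information_gain_pairwise(g$x1, g$x2, (g$x1 + g$x2) %% 2)
  expect_equal(ig$bits, 1.0)
  expect_equal(ig$pct, 100)
  # duplicated predictor fully determining a balanced class: 1 - 1 - 1
  x <- rep(c(0, 1), each = 8)
  expect_equal(information_gain_pairwise(x, x, x)$bits, -1.0)
  h <- expand.grid(x1 = 0:1, x2 = 0:1, c = 0:1)
  expect_equal(information_gain_pairwise(h$x1, h$x2, h$c)$bits, 0.0)
  expect_error(information_gain_pairwise(x, x, rep(1, 16)), "constant")
})

test_that("three-way IG: parity is pure three-way synergy", {
  g <- expand.grid(x1 = 0:1, x2 = 0:1, x3 = 0:1)
  cc <- (g$x1 + g$x2 + g$x3) %% 2
  expect_equal(mutual_information(g$x1, cc)$bits, 0.0)
  expect_equal(information_gain_pairwise(g$x1, g$x2, cc)$bits, 0.0)
  expect_equal(information_gain_threeway(g$x1, g$x2, g$x3, cc)$bits, 1.0)
  # class driven by x1 alone: all interaction content absorbed by MI(x1;C)
  expect_equal(information_gain_threeway(g$x1, g$x2, g$x3, g$x1)$bits, 0.0,
               tolerance = 1e-12)
  # three mutually independent nulls
  h <- expand.grid(x1 = 0:1, x2 = 0:1, x3 = 0:1, c = 0:1)
  expect_equal(information_gain_threeway(h$x1, h$x2, h$x3, h$c)$bits, 0.0,
               tolerance = 1e-12)
})

test_that("synergy-only clamp changes IG3 only when a pairwise IG is negative", {
  # x2 duplicates x1 and c = x1: the (x1, x2) pair is purely redundant
  # (IG2 = -1), so the raw subtraction differs from the clamped one by 1
  g <- expand.grid(x1 = 0:1, x3 = 0:1)
  x1 <- g$x1; x2 <- g$x1; x3 <- g$x3
  cc <- g$x1
  expect_equal(information_gain_pairwise(x1, x2, cc)$bits, -1)
  on <- information_gain_threeway(x1, x2, x3, cc, clamp_synergy = TRUE)$bits
  off <- information_gain_threeway(x1, x2, x3, cc, clamp_synergy = FALSE)$bits
  expect_equal(off - on, 1)       # the redundant pair is clamped out
  # with independent predictors and no redundancy the flag is inert
  set.seed(11)
  a <- rbinom(200, 1, 0.5); b <- rbinom(200, 1, 0.5); d <- rbinom(200, 1, 0.5)
  y <- rbinom(200, 1, 0.5)
  ig_on <- information_gain_threeway(a, b, d, y, clamp_synergy = TRUE)$bits
  ig_off <- information_gain_threeway(a, b, d, y, clamp_synergy = FALSE)$bits
  expect_lte(ig_off, ig_on + 1e-12)
})

test_that("to_percent scales by class entropy and rejects H(C) = 0", {
  expect_equal(to_percent(1, 1), 100)
  expect_equal(to_percent(0, 0.9), 0)
  expect_equal(to_percent(0.0278, 1), 2.78)
  expect_error(to_percent(0.1, 0), "positive")
})

test_that("counts kernels agree with the sequence API", {
  set.seed(3)
  for (i in 1:25) {
    x1 <- rbinom(50, 1, 0.5); x2 <- rbinom(50, 1, 0.3)
    x3 <- rbinom(50, 1, 0.6); y <- rbinom(50, 1, 0.5)
    k2 <- ig_pairwise_counts(tabulate(1 + x1 + 2 * x2 + 4 * y, 8))
    expect_lt(abs(k2 - information_gain_pairwise(x1, x2, y)$bits), 1e-12)
    k3 <- ig_threeway_counts(tabulate(1 + x1 + 2 * x2 + 4 * x3 + 8 * y, 16))
    expect_lt(abs(k3 - information_gain_threeway(x1, x2, x3, y)$bits), 1e-12)
  }
})

test_that("information inequalities hold on random cohorts", {
  set.seed(9)
  hc_bound_violations <- 0
  for (i in 1:200) {
    n <- sample(20:80, 1)
    x1 <- rbinom(n, 1, runif(1, 0.2, 0.8))
    x2 <- rbinom(n, 1, runif(1, 0.2, 0.8))
    x3 <- rbinom(n, 1, runif(1, 0.2, 0.8))
    y <- rbinom(n, 1, runif(1, 0.3, 0.7))
    if (length(unique(y)) < 2) next
    hc <- entropy(tabulate(y + 1, 2))
    # joint information dominates each single variable's information
    mj <- joint_mutual_information(list(x1, x2), y)
    expect_gte(mj, mutual_information(x1, y)$bits - 1e-12)
    expect_gte(mj, mutual_information(x2, y)$bits - 1e-12)
    ig2 <- information_gain_pairwise(x1, x2, y)$bits
    ig3 <- information_gain_threeway(x1, x2, x3, y)$bits
    if (abs(ig2) > hc + 1e-12 || abs(ig3) > hc + 1e-12) {
      hc_bound_violations <- hc_bound_violations + 1
    }
  }
  expect_equal(hc_bound_violations, 0)
})

test_that("pairwise IG vanishes for a saturated no-interaction logistic model", {
  # logit P(c|x1,x2) = b0 + b1 x1 + b2 x2 with zero interaction: at large
  # n the plug-in IG converges to the (small, nonzero) population value,
  # which for this parameterization is itself near zero.
  set.seed(21)
  n <- 1e5
  x1 <- rbinom(n, 1, 0.5); x2 <- rbinom(n, 1, 0.5)
  p <- plogis(-0.3 + 0.4 * x1 + 0.6 * x2)
  y <- as.integer(runif(n) < p)
  expect_lt(abs(information_gain_pairwise(x1, x2, y)$bits), 0.005)
})
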