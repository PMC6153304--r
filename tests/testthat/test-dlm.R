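test_that("filter evidence matches the joint-distribution oracles on toys", {
  set.seed(10)
  # spot-check against brute-force quadrature over the precision
  for (i in 1:6) {
    T <- sample(3:5, 1)
    p <- sample(0:2, 1)
    F <- cbind(1, matrix(rnorm(T * p), T, p))
    y <- rnorm(T)
    delta <- sample(c(0.6, 0.8, 1), 1)
    fit <- filterDLM(y, if (p > 0) F[, -1, drop = FALSE] else NULL,
                     delta = delta)
    expect_equal(logEvidence(fit),
                 dlmEvidenceQuadrature(y, F, delta), tolerance = 1e-4)
    expect_equal(logEvidence(fit),
                 dlmEvidenceClosedForm(y, F, delta), tolerance = 1e-8)
  }
  # the specific worked toy: one parent, delta = 0.8
  y <- c(0.3, -0.1, 0.4)
  x <- c(0.2, 0.1, -0.3)
  fit <- filterDLM(y, cbind(x), delta = 0.8)
  expect_equal(logEvidence(fit),
               dlmEvidenceQuadrature(y, cbind(1, x), 0.8),
               tolerance = 1e-4)
})

test_that("delta = 1 reproduces incremental static Bayesian regression", {
  set.seed(11)
  T <- 40
  x <- matrix(rnorm(2 * T), T, 2)
  y <- 0.5 + x %*% c(1, -0.7) + rnorm(T, sd = 0.3)
  fit <- filterDLM(drop(y), x, delta = 1)
  F <- cbind(1, x)
  expect_equal(fit@mPath, staticRegressionMeans(drop(y), F),
               tolerance = 1e-8)
})

test_that("hyperparameter trajectories obey the conjugate recursion", {
  set.seed(12)
  y <- rnorm(30)
  fit <- filterDLM(y, NULL, delta = 0.9)
  expect_equal(fit@nPath[30], 0.001 + 30)          # n_T = n0 + T exactly
  expect_true(all(diff(fit@dPath) > 0))
  expect_equal(logEvidence(fit), sum(fit@forecastLogDens))
  # posterior variances stay symmetric positive definite
  for (t in c(1, 15, 30)) {
    C <- fit@CstarPath[, , t, drop = TRUE]
    expect_true(all(eigen(as.matrix(C))$values > 0))
  }
})

test_that("adding a constant to y shifts only the intercept path", {
  set.seed(13)
  T <- 60
  x <- matrix(rnorm(T), T, 1)
  y <- drop(0.8 * x) + rnorm(T, sd = 0.5)
  f1 <- filterDLM(y, x, delta = 0.85)
  f2 <- filterDLM(y + 5, x, delta = 0.85)
  # once the prior transient has washed out, the shift is absorbed by
  # the intercept and the parent coefficient path is unchanged
  late <- 11:T
  expect_lt(max(abs(f1@mPath[late, 2] - f2@mPath[late, 2])), 0.05)
  expect_equal(f2@mPath[late, 1] - f1@mPath[late, 1], rep(5, length(late)),
               tolerance = 0.05)
})

test_that("searchDiscount honours the grid and the tie rule", {
  set.seed(14)
  y <- rnorm(50)
  single <- searchDiscount(y, NULL, grid = 0.7)
  expect_equal(single@delta, 0.7)
  expect_equal(logEvidence(single), logEvidence(filterDLM(y, NULL, 0.7)))
  # duplicated grid values are exact ties: the larger index (same delta)
  # wins, and generally ties resolve toward the largest delta
  dup <- searchDiscount(y, NULL, grid = c(0.9, 0.9))
  expect_equal(dup@delta, 0.9)
  expect_error(searchDiscount(y, NULL, grid = numeric()), "nonempty")
  expect_error(searchDiscount(y, NULL, grid = c(0.3, 0.9)), "0.5")
})

test_that("static data drives the selected discount toward 1", {
  set.seed(15)
  hits <- 0
  deltas <- numeric(20)
  for (i in 1:20) {
    T <- 400
    x <- matrix(rnorm(T), T, 1)
    y <- drop(1 + 0.8 * x) + rnorm(T, sd = 0.5)
    fit <- searchDiscount(y, x)
    deltas[i] <- fit@delta
    if (fit@delta >= 0.99) hits <- hits + 1
  }
  expect_gte(hits, 16)            # near-1 cell in at least 80% of seeds
  expect_gte(median(deltas), 0.99)
})

test_that("filter rejects invalid inputs", {
  y <- rnorm(10)
  expect_error(filterDLM(y, NULL, delta = 0), "0, 1")
  expect_error(filterDLM(y, NULL, delta = 1.2), "0, 1")
  expect_error(filterDLM(c(y, NA), NULL, 0.9), "non-finite")
  expect_error(filterDLM(1, NULL, 1), "2 time points")
})
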