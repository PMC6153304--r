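test_that("binarization thresholds at the requested quantile", {
  ramp <- TimeSeriesMatrix(cbind(a = 1:100, b = 100:1))
  b75 <- binarize(ramp, q = 0.75)
  expect_equal(sum(tsValues(b75)[, 1]), 25)   # exactly the top quarter
  expect_equal(b75@thresholdQuantile, 0.75)
  b50 <- binarize(ramp, q = 0.5)
  expect_equal(mean(tsValues(b50)), 0.5)
  # active fraction ~ 1 - q across random draws
  set.seed(40)
  for (q in c(0.25, 0.6, 0.9)) {
    x <- TimeSeriesMatrix(matrix(rnorm(400), 200, 2))
    frac <- colMeans(tsValues(binarize(x, q)))
    expect_true(all(abs(frac - (1 - q)) < 0.05))
  }
  expect_error(binarize(TimeSeriesMatrix(cbind(rep(1, 10), rnorm(10)))),
               "constant")
  expect_error(binarize(ramp, q = 1.2), "strictly")
})

test_that("kappa and tau agree with hand-computed contingency values", {
  # identical nondegenerate series: perfect dependence, no asymmetry
  a <- rep(c(1, 0), 10)
  kt <- patelKappaTau(a, a)
  expect_equal(kt$kappa, 1)
  expect_equal(kt$tau, 0)

  # exact product table (independence): kappa = 0
  # 25-step pattern: P(a) = P(b) = 0.4, P(ab) = 4/25 = P(a)P(b)
  a2 <- rep(c(rep(1, 10), rep(0, 15)), 4)
  b2 <- rep(c(rep(1, 4), rep(0, 6), rep(1, 6), rep(0, 9)), 4)
  expect_equal(patelKappaTau(a2, b2)$kappa, 0, tolerance = 1e-12)

  # hand-evaluated arithmetic for (t1,t2,t3,t4) = (.2,.2,.05,.55), T=100:
  #   E = (.4)(.25) = .1; t1 - E = .1 > 0 so D = 1
  #   theta_max = min(.4, .25) = .25; kappa = .1/(.25 - .1) = 2/3
  #   t2 >= t3: tau = 1 - .25/.4 = .375
  a3 <- c(rep(1, 40), rep(0, 60))
  b3 <- c(rep(1, 20), rep(0, 20), rep(1, 5), rep(0, 55))
  kt3 <- patelKappaTau(a3, b3)
  expect_equal(kt3$kappa, 2 / 3, tolerance = 1e-12)
  expect_equal(kt3$tau, 0.375, tolerance = 1e-12)
  expect_equal(unname(kt3$theta), c(0.2, 0.2, 0.05, 0.55))

  expect_error(patelKappaTau(rep(0, 10), rep(c(0, 1), 5)), "never active")
})

test_that("kappa is symmetric, tau antisymmetric, kappa bounded", {
  set.seed(41)
  for (i in 1:25) {
    a <- rbinom(60, 1, runif(1, 0.2, 0.8))
    b <- rbinom(60, 1, runif(1, 0.2, 0.8))
    if (sum(a) == 0 || sum(b) == 0) next
    k1 <- patelKappaTau(a, b)
    k2 <- patelKappaTau(b, a)
    expect_equal(k1$kappa, k2$kappa, tolerance = 1e-12)
    expect_equal(k1$tau, -k2$tau, tolerance = 1e-12)
    expect_lte(abs(k1$kappa), 1 + 1e-12)
    expect_lte(abs(k1$tau), 1 + 1e-12)
  }
  # the all-pairs matrix mirrors the pairwise properties
  bin <- binarize(TimeSeriesMatrix(matrix(rnorm(300), 100, 3)))
  pr <- patelPairwise(bin)
  expect_equal(pr@kappa, t(pr@kappa))
  expect_equal(pr@tau, -t(pr@tau))
})

test_that("the group permutation test is seed-reproducible and calibrated", {
  set.seed(42)
  mkSubject <- function(signal = NULL) {
    v <- matrix(rnorm(240), 80, 3)
    if (!is.null(signal)) {
      v[, 1] <- signal + rnorm(80, sd = 0.3)
      v[, 2] <- signal * rbinom(80, 1, 0.85) + rnorm(80, sd = 0.3)
    }
    TimeSeriesMatrix(v)
  }
  nullGroup <- lapply(1:8, function(s) mkSubject())
  r1 <- kappaPermutationTest(nullGroup, nPerm = 150, seed = 99)
  r2 <- kappaPermutationTest(nullGroup, nPerm = 150, seed = 99)
  expect_identical(r1$pvals, r2$pvals)

  # independent nodes: few significant pairs on average
  sigRate <- mean(replicate(10, {
    g <- lapply(1:8, function(s) mkSubject())
    r <- kappaPermutationTest(g, nPerm = 120)
    sum(r$adjacency)
  }))
  expect_lte(sigRate, 0.6)   # of 3 pairs, well under chance at 5% FDR

  # planted common activation: pair detected, oriented by mean tau sign
  burst <- function() {
    s <- rep(0, 80)
    on <- sort(sample(4:76, 6))
    for (o in on) s[o:min(o + 3, 80)] <- 1.5
    s
  }
  g <- lapply(1:8, function(s) mkSubject(signal = burst()))
  r <- kappaPermutationTest(g, nPerm = 200, seed = 7)
  expect_equal(r$adjacency[1, 2] + r$adjacency[2, 1], 1)
  if (r$meanTau[1, 2] >= 0) expect_equal(r$adjacency[1, 2], 1)
  else expect_equal(r$adjacency[2, 1], 1)
  expect_error(kappaPermutationTest(g[1], nPerm = 150), "2 subjects")
  expect_error(kappaPermutationTest(g, nPerm = 10), "100")
})
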