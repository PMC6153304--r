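# build a stack of random Bernoulli networks (zero diagonal)
bernoulliStack <- function(N, n, p) {
  mats <- lapply(seq_len(N), function(s) {
    A <- matrix(rbinom(n * n, 1, p), n, n)
    diag(A) <- 0
    A
  })
  networkStack(mats)
}

test_that("edge proportions and the null rate follow their definitions", {
  A <- matrix(0, 3, 3); A[1, 2] <- 1
  st <- networkStack(list(A))
  ep <- edgeProportions(st)
  expect_equal(ep$pHat[1, 2], 1)
  expect_equal(ep$p0, 1 / 6)
  # all-empty stack
  ep0 <- edgeProportions(networkStack(list(matrix(0, 3, 3),
                                           matrix(0, 3, 3))))
  expect_equal(ep0$p0, 0)
  # identity: p0 is the mean off-diagonal proportion
  set.seed(30)
  st2 <- bernoulliStack(12, 4, 0.3)
  ep2 <- edgeProportions(st2)
  off <- row(ep2$pHat) != col(ep2$pHat)
  expect_equal(ep2$p0, mean(ep2$pHat[off]), tolerance = 1e-12)
})

test_that("extreme edge counts give tiny exact binomial p-values", {
  # N = 20 subjects, construct p0 = 0.25 with one unanimous edge and
  # two null-consistent edges at the expected count N * p0 = 5
  mats <- lapply(1:20, function(s) {
    A <- matrix(0, 3, 3)
    A[1, 2] <- 1                       # unanimous
    if (s <= 5) A[2, 3] <- 1           # 5 of 20 = N * p0
    if (s > 15) A[3, 1] <- 1           # 5 of 20
    A
  })
  st <- networkStack(mats)
  ep <- edgeProportions(st)
  expect_equal(ep$p0, 0.25)
  res <- binomialEdgeTest(st)
  # oracle: two-sided minimum-likelihood aggregation of Binomial(20, .25)
  d <- dbinom(0:20, 20, 0.25)
  pOracle <- sum(d[d <= dbinom(20, 20, 0.25) * (1 + 1e-7)])
  expect_equal(res@pvals[1, 2], pOracle, tolerance = 1e-10)
  expect_lt(res@pvals[1, 2], 1e-11)
  expect_true(res@sig[1, 2])
  # a null-consistent cell is not significant
  expect_gt(res@pvals[2, 3], 0.1)
  expect_false(res@sig[2, 3])
  # significance implies qval below alpha
  expect_true(all(res@qvals[which(res@sig)] <= res@alpha))
})

test_that("the test errors on degenerate null rates", {
  full <- matrix(1, 3, 3); diag(full) <- 0
  st <- networkStack(list(full, full))
  expect_error(binomialEdgeTest(st), "degenerate")
  empty <- networkStack(list(matrix(0, 3, 3), matrix(0, 3, 3)))
  expect_error(binomialEdgeTest(empty), "degenerate")
})

test_that("FDR is controlled under a null stack", {
  set.seed(31)
  hits <- replicate(200, {
    st <- bernoulliStack(20, 5, 0.2)
    res <- tryCatch(binomialEdgeTest(st),
                    error = function(e) NULL)   # degenerate draws
    if (is.null(res)) 0 else as.numeric(sum(res@sig, na.rm = TRUE) > 0)
  })
  # under the global null the family-wise rejection rate is ~alpha;
  # allow Monte-Carlo margin
  expect_lte(mean(hits), 0.10)
})

test_that("BH significance is monotone in alpha and order-invariant", {
  set.seed(32)
  st <- bernoulliStack(25, 4, 0.3)
  r1 <- binomialEdgeTest(st, alpha = 0.05)
  r2 <- binomialEdgeTest(st, alpha = 0.20)
  expect_true(all(which(r1@sig) %in% which(r2@sig)))
  # permuting node order permutes but does not change the q-values
  perm <- c(3, 1, 4, 2)
  stp <- networkStack(lapply(seq_len(25), function(s)
    st@E[s, perm, perm]))
  rp <- binomialEdgeTest(stp, alpha = 0.05)
  expect_equal(unname(rp@qvals), unname(r1@qvals[perm, perm]))
})

test_that("run reproducibility counts subjects per criterion", {
  n <- 3
  # subject 1 has edge 1->2 in runs 1-3 only; subject 2 never has it
  mk <- function(has12) {
    A <- matrix(0, n, n); if (has12) A[1, 2] <- 1; A
  }
  runs <- list(
    networkStack(list(mk(TRUE), mk(FALSE))),
    networkStack(list(mk(TRUE), mk(FALSE))),
    networkStack(list(mk(TRUE), mk(FALSE))),
    networkStack(list(mk(FALSE), mk(FALSE))))
  rep4 <- runReproducibility(runs, k = 3)
  expect_equal(rep4$atLeastK[1, 2], 0.5)   # subject 1 only
  expect_equal(rep4$allRuns[1, 2], 0)
  expect_equal(rep4$none[1, 2], 0.5)
  expect_equal(rep4$none[2, 3], 1)         # edge never present
  # mismatched subjects are rejected
  bad <- networkStack(list(mk(TRUE), mk(TRUE)), subjectIds = c("x", "y"))
  expect_error(runReproducibility(list(runs[[1]], bad)), "align")
})

test_that("reoccurrence proportions follow the binomial closed form", {
  set.seed(33)
  q <- 0.4
  N <- 4000
  runs <- lapply(1:4, function(r) {
    networkStack(lapply(seq_len(N), function(s) {
      A <- matrix(0, 2, 2)
      A[1, 2] <- rbinom(1, 1, q)
      A
    }))
  })
  rep4 <- runReproducibility(runs, k = 3)
  expected <- 4 * q^3 * (1 - q) + q^4
  expect_equal(rep4$atLeastK[1, 2], expected, tolerance = 0.05)
  expect_equal(rep4$allRuns[1, 2], q^4, tolerance = 0.03)
  expect_equal(rep4$none[1, 2], (1 - q)^4, tolerance = 0.05)
  # counts can be fed to the binomial machinery
  res <- testReproducibilityCounts(rep4$counts$atLeastK, N)
  expect_s4_class(res, "EdgeTestResult")
})
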