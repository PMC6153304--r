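test_that("unconnected nodes produce uncorrelated BOLD", {
  set.seed(50)
  spec <- simulationSpec(matrix(0, 3, 3), duration = 300, TR = 3,
                         dynamic = FALSE)
  cors <- replicate(6, {
    ds <- simulateDataset(spec)
    C <- cor(tsValues(ds@bold))
    mean(C[upper.tri(C)])
  })
  expect_lt(abs(mean(cors)), 0.1)
})

test_that("connected-pair correlations sit in the reported range", {
  set.seed(51)
  meanConn <- function(spec, nrep) {
    prs <- which(spec@trueAdjacency == 1, arr.ind = TRUE)
    mean(replicate(nrep, {
      C <- cor(tsValues(simulateDataset(spec)@bold))
      mean(C[prs])
    }))
  }
  # dynamic (gated) network: reported mean ~0.33, range 0.25-0.40
  expect_gt(m22 <- meanConn(simPreset("sim22"), 6), 0.22)
  expect_lt(m22, 0.42)
  # stationary network: reported mean ~0.32, range 0.30-0.35
  expect_gt(m1 <- meanConn(simPreset("sim1"), 6), 0.20)
  expect_lt(m1, 0.42)
})

test_that("the hemodynamic peak is 4-6 s out and delayed by larger tau0", {
  spec <- simPreset("sim1")
  ttp <- measureTimeToPeak(spec)
  expect_true(all(ttp > 4 & ttp < 6))
  expect_equal(max(ttp) - min(ttp), 0)   # canonical nodes identical
  # monotone in the transit time
  ttps <- vapply(c(-0.4, 0, 0.5, 1, 2), function(o)
    measureTimeToPeak(simulationSpec(fiveNodeTruth(),
                                     transitTimeOffsets = rep(o, 5)))[1],
    numeric(1))
  expect_true(all(diff(ttps) > 0))
})

test_that("calibrated offsets reproduce the target peak delays", {
  spec04 <- simPreset("offset0.4")
  ttp <- measureTimeToPeak(spec04)
  base <- measureTimeToPeak(simPreset("sim22"))[3]
  expect_equal(ttp[1] - base, 0.21, tolerance = 0.02)
  expect_equal(ttp[2] - base, -0.20, tolerance = 0.02)
  expect_equal(ttp[3] - base, 0, tolerance = 1e-9)
  # parent-child total offsets: node1 - node2 ~ 0.41 s
  expect_equal(ttp[1] - ttp[2], 0.41, tolerance = 0.04)
})

test_that("zero neural input yields a flat hemodynamic baseline", {
  spec <- simulationSpec(matrix(0, 2, 2), duration = 300, TR = 3,
                         dynamic = FALSE)
  bold <- balloonBOLD(matrix(0, 6000, 2), spec)
  expect_lt(max(abs(bold)), 1e-10)
})

test_that("simulated datasets match the declared sampling grid", {
  set.seed(53)
  ds <- simulateDataset(simPreset("sim22"))
  expect_equal(nrow(tsValues(ds@bold)), 200L)    # 600 s / 3 s
  expect_equal(ncol(tsValues(ds@bold)), 5L)
  expect_equal(ds@truth, fiveNodeTruth())
  # ~4% signal change: mean per-node range close to 4 (percent units)
  rng <- mean(apply(tsValues(ds@bold), 2, function(x) diff(range(x))))
  expect_equal(rng, 4, tolerance = 0.2)
  expect_length(ds@perNodeTransit, 5L)
})

test_that("network metrics match hand counts and definitional limits", {
  truth <- fiveNodeTruth()
  perfect <- evaluateNetworks(truth, truth)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$cSensitivity, 1)

  reversed <- evaluateNetworks(t(truth), truth)
  expect_equal(reversed$sensitivity, 0)
  expect_equal(reversed$cSensitivity, 1)

  # 4 correct edges + 1 reversed + 1 extra (hand count):
  # TP = 4, FN = 1, FP = 2 (reversed + extra), TN = 13
  est <- truth
  est[4, 5] <- 0; est[5, 4] <- 1       # reverse one true edge
  est[3, 1] <- 1                       # spurious edge
  m <- evaluateNetworks(est, truth)
  expect_equal(m$sensitivity, 4 / 5)
  expect_equal(m$specificity, 13 / 15)
  expect_equal(m$accuracy, 17 / 20)
  expect_equal(m$cSensitivity, 1)      # all 5 pairs connected some way
  expect_equal(m$FP, 2)

  # properties on random estimates: bounds and c-sens >= sensitivity
  set.seed(54)
  for (i in 1:10) {
    A <- matrix(rbinom(25, 1, 0.4), 5, 5); diag(A) <- 0
    r <- evaluateNetworks(A, truth)
    expect_true(all(unlist(r[c("sensitivity", "specificity",
                               "accuracy", "cSensitivity")]) >= 0))
    expect_true(all(unlist(r[c("sensitivity", "specificity",
                               "accuracy", "cSensitivity")]) <= 1))
    expect_gte(r$cSensitivity, r$sensitivity)
  }
  expect_error(evaluateNetworks(matrix(0, 4, 4), truth), "disagree")
})

test_that("an 8-node simulation runs end to end", {
  set.seed(55)
  ds <- simulateDataset(simPreset("8nodes-ns"))
  expect_equal(dim(tsValues(ds@bold)), c(300L, 8L))
  expect_equal(sum(ds@truth), 10)      # two reciprocal pairs included
  expect_equal(sum(ds@truth * t(ds@truth)), 4)
})
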