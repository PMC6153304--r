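# helper: fabricate an evidence table with given log evidences (one
# value per subset, per child) without any fitting
makeTable <- function(n, fill) {
  subsets <- lapply(seq_len(n), function(r) enumerateParentSets(n, r))
  logev <- lapply(seq_len(n), function(r) fill(r, subsets[[r]]))
  delta <- lapply(seq_len(n), function(r) rep(0.9, length(subsets[[r]])))
  new("ModelEvidenceTable", nNodes = as.integer(n),
      nodeLabels = paste0("V", seq_len(n)), subsets = subsets,
      logEvidence = logev, delta = delta)
}

test_that("parent-set enumeration is exhaustive and deterministically ordered", {
  expect_identical(enumerateParentSets(3, 2),
                   list(integer(), 1L, 3L, c(1L, 3L)))
  subs <- enumerateParentSets(5, 4)
  expect_length(subs, 16L)
  expect_false(any(vapply(subs, function(s) 4L %in% s, logical(1))))
  # ordered by size then lexicographically
  expect_true(all(diff(lengths(subs)) >= 0))
  expect_length(enumerateParentSets(15, 1), 16384L)
  expect_error(enumerateParentSets(25, 1), "419,430,400")
  expect_length(enumerateParentSets(16, 1, maxNodes = 16), 2^15)
})

test_that("white noise gives no parent a win beyond the Occam penalty", {
  set.seed(20)
  adv <- replicate(10, {
    ts <- randomStandardizedTS(200, 2)
    tab <- fitAllModels(ts)
    # one-parent evidence minus intercept-only evidence for child 1
    tab@logEvidence[[1]][2] - tab@logEvidence[[1]][1]
  })
  # the spurious parent never wins decisively; the intercept-only model
  # is preferred by only a few log units (the complexity penalty)
  expect_lt(max(adv), 2)
  expect_lt(mean(adv), 0)
  expect_gt(mean(adv), -6)
})

test_that("a planted parent is recovered for the driven child", {
  set.seed(21)
  wins <- 0
  for (i in 1:20) {
    T <- 200
    v <- matrix(rnorm(T * 3), T, 3)
    v[, 3] <- 0.9 * v[, 1] + rnorm(T, sd = 0.4)
    fit <- dgmFit(v)
    if (identical(parentSets(fit$network)[[3]], 1L)) wins <- wins + 1
  }
  expect_gte(wins, 18)
})

test_that("table dimensions follow the 2^(n-1) law", {
  set.seed(22)
  tab <- fitAllModels(randomStandardizedTS(60, 5))
  expect_length(tab@subsets[[1]], 16L)
  expect_equal(sum(lengths(tab@subsets) * 0 + lengths(tab@logEvidence)),
               80)
})

test_that("assembly maximises the total evidence over all subset tuples", {
  set.seed(23)
  for (rep in 1:5) {
    tab <- makeTable(3, function(r, subs) rnorm(length(subs)))
    net <- assembleNetwork(tab)
    # brute force over all 4^3 subset tuples
    best <- -Inf
    for (i1 in 1:4) for (i2 in 1:4) for (i3 in 1:4) {
      tot <- tab@logEvidence[[1]][i1] + tab@logEvidence[[2]][i2] +
        tab@logEvidence[[3]][i3]
      if (tot > best) best <- tot
    }
    expect_equal(totalLogEvidence(net), best, tolerance = 1e-12)
  }
})

test_that("cycles are retained and empty winners give an empty graph", {
  # child 2's best is {1} and child 1's best is {2}: keep the 2-cycle
  tab <- makeTable(2, function(r, subs) c(0, 5))
  net <- assembleNetwork(tab)
  expect_equal(unname(adjacency(net)), matrix(c(0, 1, 1, 0), 2, 2))
  # all children prefer the intercept-only model
  tab0 <- makeTable(3, function(r, subs) c(0, -5, -6, -7))
  net0 <- assembleNetwork(tab0)
  expect_equal(sum(adjacency(net0)), 0)
  expect_equal(totalLogEvidence(net0), 0)
})

test_that("pruning follows the three-model comparison arithmetic", {
  # 3-node toy, hand-computed: children get evidence by subset
  #   child 1: {}: 0,   {2}: 10, {3}: 1, {2,3}: 9
  #   child 2: {}: 0,   {1}: 30, {3}: 2, {1,3}: 29
  #   child 3: {}: 0,   {1}: -1, {2}: -2, {1,2}: -3
  # winners: Pa(1) = {2} (10), Pa(2) = {1} (30), Pa(3) = {} -> pair 1<->2
  # m1 = 10 + 30 = 40
  # m2 (keep 2->1): 10 + best of child 2 without 1 = 10 + 2 = 12
  # m3 (keep 1->2): best of child 1 without 2 + 30 = 1 + 30 = 31
  # m1 - max = 9: kept iff e < 9, else keep 1->2 only, child 1 -> {3}
  fill <- function(r, subs) switch(r,
    c(0, 10, 1, 9), c(0, 30, 2, 29), c(0, -1, -2, -3))
  tab <- makeTable(3, fill)
  net <- assembleNetwork(tab)
  expect_equal(adjacency(net)[1, 2], 1)
  expect_equal(adjacency(net)[2, 1], 1)

  kept <- pruneNetwork(net, tab, e = 5)
  expect_equal(adjacency(kept), adjacency(net))    # 9 > 5: keep both

  pruned <- pruneNetwork(net, tab, e = 20)
  expect_equal(adjacency(pruned)[1, 2], 1)         # 1 -> 2 survives
  expect_equal(adjacency(pruned)[2, 1], 0)         # reverse removed
  expect_identical(parentSets(pruned)[[1]], 3L)    # restricted best {3}
  expect_equal(totalLogEvidence(pruned), 1 + 30 + 0)
  expect_error(pruneNetwork(net, tab, e = -1), "nonnegative")
})

test_that("pruning is the identity at e = 0 and empties pairs at e = Inf", {
  set.seed(24)
  v <- matrix(rnorm(150 * 3), 150, 3)
  v[, 2] <- 0.8 * v[, 1] + rnorm(150, sd = 0.5)
  fit <- dgmFit(v)
  net0 <- pruneNetwork(fit$network, fit$table, e = 0)
  expect_equal(adjacency(net0), adjacency(fit$network))
  netInf <- pruneNetwork(fit$network, fit$table, e = Inf)
  A <- adjacency(netInf)
  expect_equal(sum(A * t(A)), 0)   # no reciprocal pair survives
})

test_that("the number of pruned edges is nondecreasing in e", {
  set.seed(25)
  spec <- simPreset("sim22")
  ds <- simulateDataset(spec)
  fit <- dgmFit(tsValues(ds@bold))
  edges <- vapply(c(0, 5, 10, 20, 26, 50), function(e)
    sum(adjacency(pruneNetwork(fit$network, fit$table, e))), numeric(1))
  expect_true(all(diff(edges) <= 0))
})
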