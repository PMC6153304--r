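#' @include AllClasses.R AllGenerics.R accessors.R dlm.R
NULL

#' Enumerate all admissible parent sets of a child node
#'
#' All \eqn{2^{n-1}} subsets of the remaining nodes, in deterministic
#' order: by size, then lexicographically. The empty (intercept-only)
#' set comes first.
#'
#' @param n number of nodes.
#' @param r child node index.
#' @param maxNodes refuse enumeration above this size unless raised; the
#'   subset count doubles with every added node.
#' @return list of integer vectors.
#' @examples
#' enumerateParentSets(3, 2)   # {}, {1}, {3}, {1,3}
#' @export
enumerateParentSets <- function(n, r, maxNodes = 20) {
  n <- as.integer(n); r <- as.integer(r)
  if (n < 2L) stop("need at least 2 nodes")
  if (r < 1L || r > n) stop("child index out of range")
  if (n > maxNodes)
    stop(sprintf(
      "n = %d exceeds the enumeration cap (%d): %d children x 2^%d = %s model evaluations; raise 'maxNodes' to override",
      n, maxNodes, n, n - 1L,
      format(countModelEvaluations(n), big.mark = ",")))
  others <- setdiff(seq_len(n), r)
  out <- list(integer())
  for (k in seq_along(others)) {
    # combn(x, k) with scalar x would enumerate seq_len(x); force the set
    cmb <- if (length(others) == 1L) matrix(others, 1L, 1L)
           else combn(others, k)
    out <- c(out, lapply(seq_len(ncol(cmb)),
                         function(i) as.integer(cmb[, i])))
  }
  out
}

#' Size of the factorized exhaustive model space
#'
#' The evidence factorises over nodes, so the exhaustive search needs
#' \eqn{n 2^{n-1}} model evaluations (each child has \eqn{2^{n-1}}
#' candidate parent sets) instead of the \eqn{2^{n^2 - n}} possible
#' directed graphs.
#'
#' @param n number of nodes.
#' @return number of (child, parent-set) model evaluations.
#' @examples
#' countModelEvaluations(15)  # 245760
#' countModelEvaluations(25) / 1e6  # ~419 million
#' @export
countModelEvaluations <- function(n) as.numeric(n) * 2^(as.numeric(n) - 1)

#' Fit every (child, parent-set) dynamic regression
#'
#' For every child node and every admissible parent subset, maximises
#' the log model evidence over the discount grid via [searchDiscount()]
#' and stores the optimum. Deterministic given the input series.
#'
#' @param ts a standardized [TimeSeriesMatrix-class].
#' @param priors a [DLMPriors-class].
#' @param grid discount grid (default 0.50..1.00 by 0.01).
#' @param maxNodes enumeration cap, see [enumerateParentSets()].
#' @return a [ModelEvidenceTable-class].
#' @export
fitAllModels <- function(ts, priors = dlmPriors(),
                         grid = defaultDeltaGrid(), maxNodes = 20) {
  stopifnot(is(ts, "TimeSeriesMatrix"))
  if (!ts@standardized)
    stop("time series must be standardized first; see standardize()")
  v <- ts@values
  n <- ncol(v)
  subsets <- vector("list", n)
  logev <- vector("list", n)
  delta <- vector("list", n)
  gridv <- as.numeric(grid)
  for (r in seq_len(n)) {
    subs <- enumerateParentSets(n, r, maxNodes = maxNodes)
    le <- numeric(length(subs))
    de <- numeric(length(subs))
    y <- v[, r]
    for (i in seq_along(subs)) {
      F <- cbind(1, v[, subs[[i]], drop = FALSE])
      pr <- materializePriors(priors, ncol(F))
      ev <- tryCatch(
        as.numeric(dlm_grid_cpp(y, F, gridv, pr$m0, pr$C0, priors@n0,
                                priors@d0)),
        error = function(e) stop(sprintf(
          "child %d, parent set {%s}: %s", r,
          paste(subs[[i]], collapse = ","), conditionMessage(e)),
          call. = FALSE))
      best <- max(which(ev == max(ev)))     # tie -> largest delta
      le[i] <- ev[best]
      de[i] <- gridv[best]
    }
    subsets[[r]] <- subs
    logev[[r]] <- le
    delta[[r]] <- de
  }
  new("ModelEvidenceTable", nNodes = n, nodeLabels = ts@nodeLabels,
      subsets = subsets, logEvidence = logev, delta = delta)
}

## index of the evidence-maximising subset of one child, optionally
## excluding subsets that contain any node in 'excluding'; ties resolve
## to the first (smallest, lexicographically earliest) subset.
bestSubsetIndex <- function(table, child, excluding = integer()) {
  subs <- table@subsets[[child]]
  keep <- if (length(excluding))
    !vapply(subs, function(s) any(excluding %in% s), logical(1L))
  else rep(TRUE, length(subs))
  idx <- which(keep)
  idx[which.max(table@logEvidence[[child]][idx])]
}

buildNetwork <- function(table, winnerIdx) {
  n <- table@nNodes
  A <- matrix(0, n, n, dimnames = list(table@nodeLabels,
                                       table@nodeLabels))
  pa <- vector("list", n)
  de <- numeric(n)
  le <- numeric(n)
  for (j in seq_len(n)) {
    i <- winnerIdx[j]
    pa[[j]] <- table@subsets[[j]][[i]]
    de[j] <- table@delta[[j]][i]
    le[j] <- table@logEvidence[[j]][i]
    A[pa[[j]], j] <- 1
  }
  new("DirectedNetwork", adjacency = A, parentSets = pa, delta = de,
      logEvidence = le, totalLogEvidence = sum(le),
      nodeLabels = table@nodeLabels)
}

#' Assemble the evidence-optimal directed network
#'
#' Selects, independently for each child node, the parent set with the
#' highest log model evidence. Ties are broken toward the smaller
#' subset, then lexicographically. No acyclicity constraint is imposed:
#' reciprocal edges and cycles are retained.
#'
#' @param table a complete [ModelEvidenceTable-class].
#' @return a [DirectedNetwork-class].
#' @export
assembleNetwork <- function(table) {
  stopifnot(is(table, "ModelEvidenceTable"))
  winner <- vapply(seq_len(table@nNodes),
                   function(j) bestSubsetIndex(table, j), integer(1L))
  buildNetwork(table, winner)
}

#' Prune reciprocal edges by Bayes-factor model comparison
#'
#' For every unordered pair \{i, j\} connected in both directions, three
#' models are compared through their summed log evidence at the two
#' nodes: the bidirectional model m1 (both winning parent sets), and the
#' two unidirectional models in which one node drops the other from its
#' parents and is re-optimised over all its parent subsets excluding
#' that node. The bidirectional model is retained iff its log Bayes
#' factor over the better unidirectional model exceeds the penalty `e`
#' (or the two unidirectional models tie exactly); otherwise the losing
#' child's parent set is replaced by its restricted best.
#'
#' All pair decisions are computed from the original table and winning
#' sets and applied simultaneously, so the result does not depend on the
#' order in which pairs are examined. If a child loses several
#' reciprocal comparisons, its final parent set is the best subset
#' excluding all the dropped parents.
#'
#' With `e = 0` the network is returned unchanged (up to exact evidence
#' ties), since the winning sets already maximise each node's evidence.
#'
#' @param net a [DirectedNetwork-class] assembled from `table`.
#' @param table the [ModelEvidenceTable-class] used to assemble `net`.
#' @param e nonnegative pruning penalty, a log Bayes factor; `exp(e)`
#'   are the prior odds favouring unidirectional over bidirectional
#'   connections.
#' @return a [DirectedNetwork-class].
#' @export
pruneNetwork <- function(net, table, e = 0) {
  stopifnot(is(net, "DirectedNetwork"), is(table, "ModelEvidenceTable"))
  if (length(e) != 1L || !is.finite(e) && !identical(e, Inf))
    stop("'e' must be a single nonnegative number")
  if (e < 0) stop("pruning penalty 'e' must be nonnegative")
  A <- net@adjacency
  n <- nrow(A)
  winLE <- net@logEvidence
  banned <- vector("list", n)
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    if (A[i, j] != 1 || A[j, i] != 1) next
    me1 <- winLE[i] + winLE[j]
    # drop i -> j (child j re-optimised without parent i); j -> i kept
    altJ <- bestSubsetIndex(table, j, excluding = i)
    me2 <- winLE[i] + table@logEvidence[[j]][altJ]
    # drop j -> i (child i re-optimised without parent j); i -> j kept
    altI <- bestSubsetIndex(table, i, excluding = j)
    me3 <- table@logEvidence[[i]][altI] + winLE[j]
    if (me1 < max(me2, me3) - 1e-8)
      stop("internal error: bidirectional model cannot have lower ",
           "evidence than its restrictions")
    if (me1 - max(me2, me3) > e || me2 == me3) next      # keep m1
    if (me2 > me3) banned[[j]] <- c(banned[[j]], i)
    else           banned[[i]] <- c(banned[[i]], j)
  }
  winner <- vapply(seq_len(n), function(j) {
    if (length(banned[[j]]))
      bestSubsetIndex(table, j, excluding = banned[[j]])
    else bestSubsetIndex(table, j)
  }, integer(1L))
  buildNetwork(table, winner)
}

#' Refit the winning models to recover coefficient paths
#'
#' Re-runs [filterDLM()] for every child at its winning parent set and
#' stored optimal discount factor, returning the filtered time-varying
#' coefficient paths.
#'
#' @param ts the standardized [TimeSeriesMatrix-class] the network was
#'   estimated from.
#' @param net a [DirectedNetwork-class].
#' @param priors the [DLMPriors-class] used during fitting.
#' @return list of [DLMFit-class], one per child node.
#' @export
coefficientPaths <- function(ts, net, priors = dlmPriors()) {
  stopifnot(is(ts, "TimeSeriesMatrix"), is(net, "DirectedNetwork"))
  v <- ts@values
  lapply(seq_len(nrow(net@adjacency)), function(j) {
    filterDLM(v[, j], regressorSet(ts, j, net@parentSets[[j]]),
              delta = net@delta[j], priors = priors)
  })
}

#' Estimate a dynamic graphical model from node time series
#'
#' Convenience wrapper running the full pipeline: standardization (if
#' needed), exhaustive per-node parent-set search with discount
#' optimisation, network assembly, and optional Bayes-factor pruning of
#' reciprocal edges.
#'
#' @param ts a [TimeSeriesMatrix-class] (standardized or raw) or plain
#'   T x n matrix.
#' @param e pruning penalty (default 0, i.e. no pruning).
#' @param priors a [DLMPriors-class].
#' @param grid discount grid.
#' @param maxNodes enumeration cap, see [enumerateParentSets()].
#' @return list with elements `table` (the [ModelEvidenceTable-class])
#'   and `network` (the pruned [DirectedNetwork-class]).
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(300), 100, 3)
#' x[, 3] <- 0.9 * x[, 1] + rnorm(100, sd = 0.4)
#' fit <- dgmFit(x)
#' adjacency(fit$network)
#' @export
dgmFit <- function(ts, e = 0, priors = dlmPriors(),
                   grid = defaultDeltaGrid(), maxNodes = 20) {
  if (!is(ts, "TimeSeriesMatrix")) ts <- TimeSeriesMatrix(ts)
  if (!ts@standardized) ts <- standardize(ts)
  table <- fitAllModels(ts, priors = priors, grid = grid,
                        maxNodes = maxNodes)
  net <- assembleNetwork(table)
  if (e > 0) net <- pruneNetwork(net, table, e = e)
  list(table = table, network = net)
}
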