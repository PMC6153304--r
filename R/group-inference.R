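#' @include AllClasses.R AllGenerics.R accessors.R
NULL

#' Stack per-subject networks into a binary edge array
#'
#' @param networks list of [DirectedNetwork-class] objects or binary
#'   n x n adjacency matrices (entry \[i, j\] = 1 for edge i -> j), one
#'   per subject, all with the same node set.
#' @param subjectIds optional character identifiers.
#' @return a [NetworkStack-class].
#' @export
networkStack <- function(networks, subjectIds = NULL) {
  mats <- lapply(networks, function(x)
    if (is(x, "DirectedNetwork")) adjacency(x) else as.matrix(x))
  n <- nrow(mats[[1L]])
  if (any(vapply(mats, function(m) nrow(m) != n || ncol(m) != n,
                 logical(1L))))
    stop("all networks must share the same node count")
  N <- length(mats)
  E <- array(0, dim = c(N, n, n))
  for (s in seq_len(N)) E[s, , ] <- mats[[s]]
  labels <- colnames(mats[[1L]])
  if (is.null(labels)) labels <- paste0("V", seq_len(n))
  if (is.null(subjectIds)) subjectIds <- as.character(seq_len(N))
  new("NetworkStack", E = E, subjectIds = as.character(subjectIds),
      nodeLabels = labels)
}

#' Edge proportions and the null edge-connection rate
#'
#' `pHat[i, j]` is the proportion of subjects showing the edge i -> j;
#' the null rate `p0` is the average edge density, i.e. the mean of the
#' off-diagonal proportions (equivalently the total edge count divided
#' by N n (n-1)).
#'
#' @param stack a [NetworkStack-class].
#' @return list with elements `pHat` (n x n matrix, NA diagonal) and
#'   `p0` (scalar).
#' @export
edgeProportions <- function(stack) {
  stopifnot(is(stack, "NetworkStack"))
  pHat <- apply(stack@E, c(2L, 3L), mean)
  dimnames(pHat) <- list(stack@nodeLabels, stack@nodeLabels)
  off <- pHat[row(pHat) != col(pHat)]
  diag(pHat) <- NA_real_
  list(pHat = pHat, p0 = mean(off))
}

## shared engine: exact two-sided binomial tests + BH over a count matrix
testEdgeCounts <- function(counts, N, p0, alpha, labels = NULL) {
  n <- nrow(counts)
  if (p0 <= 0 || p0 >= 1)
    stop("degenerate null edge rate p0 = ", p0,
         ": every (or no) edge is present, the test is undefined")
  pvals <- matrix(NA_real_, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    pvals[i, j] <- binom.test(counts[i, j], N, p = p0)$p.value
  }
  off <- row(pvals) != col(pvals)
  qvals <- pvals
  qvals[off] <- p.adjust(pvals[off], method = "BH")
  sig <- qvals <= alpha
  list(pvals = pvals, qvals = qvals, sig = sig)
}

#' Binomial test of edge consistency across subjects
#'
#' Tests, for every directed edge, whether its prevalence across
#' subjects differs from the null edge-connection rate `p0` (the mean
#' off-diagonal edge proportion of the same stack), using the exact
#' two-sided binomial test (minimum-likelihood two-sided aggregation, as
#' in [stats::binom.test()]) and Benjamini-Hochberg FDR correction over
#' all n(n-1) edges.
#'
#' @param stack a [NetworkStack-class] with at least two subjects.
#' @param alpha FDR level (default 0.05).
#' @return an [EdgeTestResult-class].
#' @export
binomialEdgeTest <- function(stack, alpha = 0.05) {
  stopifnot(is(stack, "NetworkStack"))
  N <- dim(stack@E)[1L]
  if (N < 2L) stop("need at least 2 subjects")
  ep <- edgeProportions(stack)
  counts <- apply(stack@E, c(2L, 3L), sum)
  res <- testEdgeCounts(counts, N, ep$p0, alpha,
                        labels = stack@nodeLabels)
  new("EdgeTestResult", pHat = ep$pHat, p0 = ep$p0, pvals = res$pvals,
      qvals = res$qvals, sig = res$sig, alpha = alpha,
      counts = counts, nSubjects = as.integer(N))
}

#' Within-subject reproducibility of edges across runs
#'
#' Given one [NetworkStack-class] per run over the same subjects,
#' counts for every subject in how many runs each edge occurs and
#' returns the proportion of subjects with the edge in at least `k`
#' runs, in all runs, and in no run. The corresponding count matrices
#' (numbers of subjects) are returned as well so that each criterion can
#' be fed to the binomial consistency test.
#'
#' @param stacks list of [NetworkStack-class], one per run, with equal
#'   subjects and node sets.
#' @param k minimal number of runs for the "at least k" criterion
#'   (default 3, e.g. 3 of 4 runs).
#' @return list with proportion matrices `atLeastK`, `allRuns`, `none`,
#'   matching count matrices in `counts`, plus `nRuns`, `k` and
#'   `nSubjects`.
#' @export
runReproducibility <- function(stacks, k = 3) {
  stopifnot(length(stacks) >= 2L,
            all(vapply(stacks, is, logical(1L), "NetworkStack")))
  d <- dim(stacks[[1L]]@E)
  ids <- stacks[[1L]]@subjectIds
  for (s in stacks[-1L]) {
    if (!identical(dim(s@E), d))
      stop("all runs must have the same subjects and node count")
    if (!identical(s@subjectIds, ids))
      stop("subject identifiers do not align across runs")
  }
  R <- length(stacks)
  if (k < 1 || k > R) stop("'k' must lie in [1, number of runs]")
  tot <- Reduce(`+`, lapply(stacks, function(s) s@E))  # N x n x n in 0..R
  labels <- stacks[[1L]]@nodeLabels
  cnt <- function(test) {
    m <- apply(test, c(2L, 3L), sum)
    dimnames(m) <- list(labels, labels)
    m
  }
  nAtLeastK <- cnt(tot >= k)
  nAll <- cnt(tot == R)
  nNone <- cnt(tot == 0)
  N <- d[1L]
  noDiag <- function(m) { diag(m) <- NA_real_; m }
  list(atLeastK = noDiag(nAtLeastK / N), allRuns = noDiag(nAll / N),
       none = noDiag(nNone / N),
       counts = list(atLeastK = nAtLeastK, allRuns = nAll, none = nNone),
       nRuns = R, k = k, nSubjects = N)
}

#' Binomial consistency test for a reproducibility criterion
#'
#' Applies the same exact binomial / FDR machinery as
#' [binomialEdgeTest()] to a subject-count matrix produced by
#' [runReproducibility()], with the null rate computed analogously as
#' the mean off-diagonal proportion of that matrix.
#'
#' @param counts n x n integer matrix of subjects meeting the criterion.
#' @param nSubjects total number of subjects N.
#' @param alpha FDR level.
#' @return an [EdgeTestResult-class].
#' @export
testReproducibilityCounts <- function(counts, nSubjects, alpha = 0.05) {
  counts <- as.matrix(counts)
  pHat <- counts / nSubjects
  off <- row(pHat) != col(pHat)
  p0 <- mean(pHat[off])
  res <- testEdgeCounts(counts, nSubjects, p0, alpha,
                        labels = colnames(counts))
  diag(pHat) <- NA_real_
  new("EdgeTestResult", pHat = pHat, p0 = p0, pvals = res$pvals,
      qvals = res$qvals, sig = res$sig, alpha = alpha,
      counts = counts, nSubjects = as.integer(nSubjects))
}
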