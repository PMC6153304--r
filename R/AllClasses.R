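## Central S4 containers. All matrices of observed signals are oriented
## rows = time, columns = nodes; adjacency matrices are parent (row) ->
## child (column) with a zero diagonal.

#' TimeSeriesMatrix: multivariate node time series
#'
#' Holds a \eqn{T \times n} matrix of observed node signals (rows = time,
#' columns = nodes) together with node labels and a flag recording whether
#' the standardization convention of [standardize()] has been applied
#' (column means 0, mean of per-column SDs equal to 1).
#'
#' @slot values numeric matrix, T rows (time) by n columns (nodes).
#' @slot nodeLabels character vector of length n.
#' @slot standardized logical flag.
#'
#' @seealso [TimeSeriesMatrix()], [standardize()], [loadTimeSeries()]
#' @exportClass TimeSeriesMatrix
setClass("TimeSeriesMatrix",
  representation(values = "matrix", nodeLabels = "character",
                 standardized = "logical"),
  prototype(standardized = FALSE))

setValidity("TimeSeriesMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (!is.numeric(v)) msg <- c(msg, "'values' must be numeric")
  if (nrow(v) < 2L) msg <- c(msg, "need at least 2 time points (T >= 2)")
  if (ncol(v) < 2L) msg <- c(msg, "need at least 2 nodes (n >= 2)")
  if (anyNA(v) || any(!is.finite(v)))
    msg <- c(msg, "missing or non-finite values are not allowed")
  if (length(object@nodeLabels) != ncol(v))
    msg <- c(msg, "length of 'nodeLabels' must equal the number of columns")
  if (length(object@standardized) != 1L)
    msg <- c(msg, "'standardized' must be a single logical")
  if (isTRUE(object@standardized) && length(msg) == 0L) {
    mu <- colMeans(v)
    s  <- apply(v, 2L, popSD)
    if (max(abs(mu)) > 1e-10)
      msg <- c(msg, "standardized=TRUE but column means are not 0")
    if (abs(mean(s) - 1) > 1e-10)
      msg <- c(msg, "standardized=TRUE but mean per-column SD is not 1")
  }
  if (length(msg)) msg else TRUE
})

#' DLMPriors: conjugate priors for a node-level dynamic regression
#'
#' Normal-gamma prior for one dynamic linear regression: the state vector
#' prior is \eqn{N(m_0, V C_0^*)} and the observation precision prior is
#' \eqn{G(n_0/2, d_0/2)}. `m0` and `C0star` may be given as scalars and
#' are expanded to the model dimension (intercept + number of parents)
#' when a filter is run: a scalar `m0` recycles to the mean vector and a
#' scalar `C0star` becomes that multiple of the identity.
#'
#' Defaults: `m0 = 0`, `C0star = 3` (i.e. \eqn{3 I}), `n0 = 0.001`,
#' `d0 = 0.001` -- a weakly informative choice appropriate for series
#' standardized so the average temporal SD across nodes is 1.
#'
#' @slot m0 numeric, scalar or vector state prior mean.
#' @slot C0star numeric scalar (multiple of identity) or p x p matrix,
#'   scale-free state prior variance.
#' @slot n0,d0 positive reals, precision-prior hyperparameters.
#'
#' @seealso [dlmPriors()], [filterDLM()]
#' @exportClass DLMPriors
setClass("DLMPriors",
  representation(m0 = "numeric", C0star = "ANY", n0 = "numeric",
                 d0 = "numeric"))

setValidity("DLMPriors", function(object) {
  msg <- character()
  if (length(object@n0) != 1L || !is.finite(object@n0) || object@n0 <= 0)
    msg <- c(msg, "'n0' must be a single positive number")
  if (length(object@d0) != 1L || !is.finite(object@d0) || object@d0 <= 0)
    msg <- c(msg, "'d0' must be a single positive number")
  C0 <- object@C0star
  if (is.matrix(C0)) {
    if (nrow(C0) != ncol(C0) || max(abs(C0 - t(C0))) > 1e-12)
      msg <- c(msg, "'C0star' matrix must be symmetric")
    else if (any(eigen(C0, symmetric = TRUE, only.values = TRUE)$values <= 0))
      msg <- c(msg, "'C0star' must be positive definite")
  } else if (!(is.numeric(C0) && length(C0) == 1L && C0 > 0)) {
    msg <- c(msg, "'C0star' must be a positive scalar or an SPD matrix")
  }
  if (length(msg)) msg else TRUE
})

#' RegressorSet: design information for one child node
#'
#' Identifies the child node, its ordered parent set, and the T x
#' (|Pa|+1) design matrix whose rows are the regression vectors
#' \eqn{F_t} (leading 1 for the intercept, then the parent observations
#' at the same time t).
#'
#' @slot child integer child node index.
#' @slot parents integer vector of parent node indices (may be empty),
#'   never containing the child.
#' @slot design numeric T x (length(parents)+1) matrix, first column 1.
#'
#' @seealso [regressorSet()], [filterDLM()]
#' @exportClass RegressorSet
setClass("RegressorSet",
  representation(child = "integer", parents = "integer", design = "matrix"))

setValidity("RegressorSet", function(object) {
  msg <- character()
  if (length(object@child) != 1L || object@child < 1L)
    msg <- c(msg, "'child' must be a single positive index")
  if (object@child %in% object@parents)
    msg <- c(msg, "a node cannot be its own parent")
  if (anyDuplicated(object@parents))
    msg <- c(msg, "duplicated parent indices")
  if (ncol(object@design) != length(object@parents) + 1L)
    msg <- c(msg, "design must have |parents| + 1 columns")
  if (nrow(object@design) > 0L && any(object@design[, 1L] != 1))
    msg <- c(msg, "first design column must be the intercept (all 1)")
  if (length(msg)) msg else TRUE
})

#' DLMFit: filtered dynamic regression for one child / parent set
#'
#' Result of [filterDLM()] (or the grid search [searchDiscount()]): the
#' discount factor used, the log model evidence (sum of one-step
#' Student-t forecast log densities), and the full filtered trajectories
#' of the posterior hyperparameters.
#'
#' @slot child,parents node indices describing the model.
#' @slot delta discount factor in (0, 1].
#' @slot logEvidence total log model evidence.
#' @slot mPath T x p matrix of filtered posterior state means.
#' @slot CstarPath p x p x T array of scale-free posterior variances.
#' @slot nPath,dPath length-T hyperparameter trajectories of the
#'   precision posterior (\eqn{n_t = n_0 + t}; \eqn{d_t} increasing).
#' @slot forecastLogDens length-T per-time log one-step forecast density.
#'
#' @seealso [filterDLM()], [searchDiscount()]
#' @exportClass DLMFit
setClass("DLMFit",
  representation(child = "integer", parents = "integer", delta = "numeric",
                 logEvidence = "numeric", mPath = "matrix",
                 CstarPath = "array", nPath = "numeric", dPath = "numeric",
                 forecastLogDens = "numeric"))

setValidity("DLMFit", function(object) {
  msg <- character()
  if (object@delta <= 0 || object@delta > 1)
    msg <- c(msg, "'delta' must lie in (0, 1]")
  if (abs(object@logEvidence - sum(object@forecastLogDens)) > 1e-8)
    msg <- c(msg, "logEvidence must equal the sum of forecastLogDens")
  if (any(diff(object@dPath) <= 0))
    msg <- c(msg, "dPath must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' ModelEvidenceTable: evidence of every parent set for every child
#'
#' For each child node r the table stores, for each of the
#' \eqn{2^{n-1}} admissible parent subsets of the remaining nodes, the
#' log model evidence maximised over the discount grid together with the
#' optimising discount factor. Subsets are ordered by size then
#' lexicographically (the empty, intercept-only model first).
#'
#' @slot nNodes number of nodes n.
#' @slot nodeLabels character labels.
#' @slot subsets list (per child) of lists of integer parent vectors.
#' @slot logEvidence list (per child) of numeric vectors.
#' @slot delta list (per child) of numeric vectors.
#'
#' @seealso [fitAllModels()], [evidenceTable()], [assembleNetwork()]
#' @exportClass ModelEvidenceTable
setClass("ModelEvidenceTable",
  representation(nNodes = "integer", nodeLabels = "character",
                 subsets = "list", logEvidence = "list", delta = "list"))

setValidity("ModelEvidenceTable", function(object) {
  n <- object@nNodes
  msg <- character()
  if (length(object@subsets) != n || length(object@logEvidence) != n ||
      length(object@delta) != n)
    msg <- c(msg, "per-child lists must have length nNodes")
  else {
    k <- 2^(n - 1L)
    for (r in seq_len(n)) {
      if (length(object@subsets[[r]]) != k)
        msg <- c(msg, sprintf("child %d: expected %d subsets", r, k))
      if (length(object@subsets[[r]][[1L]]) != 0L)
        msg <- c(msg, sprintf("child %d: first subset must be empty", r))
      if (length(object@logEvidence[[r]]) != k ||
          length(object@delta[[r]]) != k)
        msg <- c(msg, sprintf("child %d: evidence/delta length mismatch", r))
    }
  }
  if (length(msg)) msg else TRUE
})

#' DirectedNetwork: an estimated (possibly cyclic) directed graph
#'
#' Binary adjacency with entry \[i, j\] = 1 meaning an edge from parent i
#' to child j, the per-child winning parent sets with their discount
#' factors and log evidences, and the total log evidence (sum over
#' children).
#'
#' @slot adjacency n x n binary matrix, zero diagonal.
#' @slot parentSets list of integer vectors, one per child.
#' @slot delta numeric per-child optimal discount factor.
#' @slot logEvidence numeric per-child log model evidence.
#' @slot totalLogEvidence sum of the per-child evidences.
#' @slot nodeLabels character labels.
#'
#' @seealso [assembleNetwork()], [pruneNetwork()], [adjacency()]
#' @exportClass DirectedNetwork
setClass("DirectedNetwork",
  representation(adjacency = "matrix", parentSets = "list",
                 delta = "numeric", logEvidence = "numeric",
                 totalLogEvidence = "numeric", nodeLabels = "character"))

setValidity("DirectedNetwork", function(object) {
  A <- object@adjacency
  n <- nrow(A)
  msg <- character()
  if (ncol(A) != n) msg <- c(msg, "adjacency must be square")
  if (!all(A %in% c(0, 1))) msg <- c(msg, "adjacency must be binary")
  if (any(diag(A) != 0)) msg <- c(msg, "adjacency diagonal must be zero")
  if (length(object@parentSets) != n)
    msg <- c(msg, "parentSets must have one entry per child")
  else {
    for (j in seq_len(n)) {
      if (!setequal(which(A[, j] == 1), object@parentSets[[j]]))
        msg <- c(msg, sprintf(
          "column %d of adjacency disagrees with parentSets[[%d]]", j, j))
    }
  }
  if (abs(object@totalLogEvidence - sum(object@logEvidence)) > 1e-10)
    msg <- c(msg, "totalLogEvidence must equal sum(logEvidence)")
  if (length(msg)) msg else TRUE
})

#' NetworkStack: per-subject binary networks
#'
#' An N x n x n binary array; `E[s, i, j] = 1` iff subject s has the edge
#' i -> j (parent i, child j). The group-level edge statistics of
#' [edgeProportions()] and [binomialEdgeTest()] operate on this type.
#'
#' @slot E binary array, subjects x nodes x nodes, zero diagonals.
#' @slot subjectIds character identifiers, one per subject.
#' @slot nodeLabels character labels.
#'
#' @seealso [networkStack()], [binomialEdgeTest()]
#' @exportClass NetworkStack
setClass("NetworkStack",
  representation(E = "array", subjectIds = "character",
                 nodeLabels = "character"))

setValidity("NetworkStack", function(object) {
  d <- dim(object@E)
  msg <- character()
  if (length(d) != 3L || d[2L] != d[3L])
    msg <- c(msg, "'E' must be an N x n x n array")
  if (d[1L] < 1L) msg <- c(msg, "need at least one subject")
  if (!all(object@E %in% c(0, 1))) msg <- c(msg, "'E' must be binary")
  for (s in seq_len(d[1L]))
    if (any(diag(object@E[s, , ]) != 0)) {
      msg <- c(msg, "diagonals must be zero"); break
    }
  if (length(object@subjectIds) != d[1L])
    msg <- c(msg, "'subjectIds' must have one entry per subject")
  if (length(msg)) msg else TRUE
})

#' EdgeTestResult: group-level binomial edge-consistency test
#'
#' Edge proportions, the null edge-connection rate, exact two-sided
#' binomial p-values, BH-adjusted q-values, and the significance mask at
#' the requested FDR level. Diagonal entries are NA (self-edges are not
#' tested).
#'
#' @slot pHat n x n observed edge proportions.
#' @slot p0 scalar null edge-connection rate (mean off-diagonal
#'   proportion).
#' @slot pvals,qvals n x n p-values and BH-adjusted q-values.
#' @slot sig n x n logical mask, TRUE where qval <= alpha.
#' @slot alpha FDR level used.
#' @slot counts n x n integer edge counts.
#' @slot nSubjects number of subjects N.
#'
#' @seealso [binomialEdgeTest()]
#' @exportClass EdgeTestResult
setClass("EdgeTestResult",
  representation(pHat = "matrix", p0 = "numeric", pvals = "matrix",
                 qvals = "matrix", sig = "matrix", alpha = "numeric",
                 counts = "matrix", nSubjects = "integer"))

#' BinaryActivationMatrix: thresholded node activations
#'
#' Binary T x n matrix obtained by min-max scaling each node to \[0, 1\]
#' and thresholding strictly above the chosen quantile; input to Patel's
#' kappa/tau.
#'
#' @slot values binary T x n matrix.
#' @slot thresholdQuantile the quantile used (default 0.75).
#' @slot nodeLabels character labels.
#'
#' @seealso [binarize()], [patelPairwise()]
#' @exportClass BinaryActivationMatrix
setClass("BinaryActivationMatrix",
  representation(values = "matrix", thresholdQuantile = "numeric",
                 nodeLabels = "character"))

setValidity("BinaryActivationMatrix", function(object) {
  msg <- character()
  if (!all(object@values %in% c(0, 1)))
    msg <- c(msg, "'values' must be binary")
  q <- object@thresholdQuantile
  if (length(q) != 1L || q <= 0 || q >= 1)
    msg <- c(msg, "'thresholdQuantile' must lie strictly in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' PatelResult: pairwise connection strength and direction
#'
#' Patel's kappa (symmetric connection strength) and tau (antisymmetric
#' direction; positive `tau[i, j]` means i is ascendant, i.e. i -> j)
#' for every node pair, plus the joint activation probabilities.
#'
#' @slot kappa n x n symmetric matrix (NA diagonal).
#' @slot tau n x n antisymmetric matrix (NA diagonal), |tau| <= 1.
#' @slot theta n x n x 4 array of joint probabilities
#'   (P11, P10, P01, P00) for each ordered pair.
#'
#' @seealso [patelPairwise()], [patelKappaTau()]
#' @exportClass PatelResult
setClass("PatelResult",
  representation(kappa = "matrix", tau = "matrix", theta = "array"))

#' SimulationSpec: declarative description of a network simulation
#'
#' All parameters of the balloon-model network simulator: ground-truth
#' adjacency and neural coupling, input-train statistics, dynamic gating,
#' sampling, noise, and per-node hemodynamic transit-time manipulation.
#' Durations and lags are in seconds; `noisePct` is the SD of the
#' measurement noise in percent of the baseline signal (baseline = 100).
#'
#' @slot nNodes number of nodes.
#' @slot trueAdjacency n x n binary ground truth (parent -> child).
#' @slot connectionStrength neural coupling weight for true edges.
#' @slot neuralLag self-decay time constant of the neural state, seconds.
#' @slot dynamic logical; if TRUE each edge is gated on/off over time.
#' @slot gateMeanOff mean duration (s) of the random off intervals (and
#'   of the on intervals) of the edge gates.
#' @slot duration total simulated time, seconds.
#' @slot TR sampling interval of the BOLD output, seconds.
#' @slot noisePct measurement noise SD, percent of baseline.
#' @slot hrfLagSd SD (s) of the random per-node jitter on the venous
#'   transit time.
#' @slot transitTimeOffsets per-node systematic offset (s) added to the
#'   canonical venous transit time.
#' @slot inputOnMean,inputOffMean mean on/off durations (s) of the
#'   Poisson-like binary input trains.
#' @slot inputDurationRange truncation range (s) for the input durations.
#' @slot inputNoiseFrac SD of the additive input noise as a fraction of
#'   the neural amplitude.
#' @slot dt Euler integration step, seconds.
#'
#' @seealso [simulationSpec()], [simPreset()], [simulateDataset()]
#' @exportClass SimulationSpec
setClass("SimulationSpec",
  representation(nNodes = "integer", trueAdjacency = "matrix",
                 connectionStrength = "numeric", neuralLag = "numeric",
                 dynamic = "logical", gateMeanOff = "numeric",
                 duration = "numeric", TR = "numeric", noisePct = "numeric",
                 hrfLagSd = "numeric", transitTimeOffsets = "numeric",
                 inputOnMean = "numeric", inputOffMean = "numeric",
                 inputDurationRange = "numeric", inputNoiseFrac = "numeric",
                 dt = "numeric"))

setValidity("SimulationSpec", function(object) {
  msg <- character()
  n <- object@nNodes
  A <- object@trueAdjacency
  if (nrow(A) != n || ncol(A) != n) msg <- c(msg, "adjacency must be n x n")
  if (!all(A %in% c(0, 1))) msg <- c(msg, "adjacency must be binary")
  if (any(diag(A) != 0)) msg <- c(msg, "adjacency diagonal must be zero")
  Tn <- object@duration / object@TR
  if (abs(Tn - round(Tn)) > 1e-8 || round(Tn) < 2)
    msg <- c(msg, "duration/TR must be an integer >= 2")
  if (object@noisePct < 0) msg <- c(msg, "noisePct must be >= 0")
  if (length(object@transitTimeOffsets) != n)
    msg <- c(msg, "transitTimeOffsets must have one entry per node")
  if (object@neuralLag <= 0) msg <- c(msg, "neuralLag must be positive")
  if (object@dt <= 0 || object@dt > object@TR)
    msg <- c(msg, "dt must be positive and smaller than TR")
  if (length(msg)) msg else TRUE
})

#' SimulatedDataset: output of one simulator run
#'
#' The sampled BOLD matrix (a [TimeSeriesMatrix-class]), the fine-grid
#' neural states and binary input trains, the ground-truth adjacency, the
#' realised per-node venous transit times, and the generating spec.
#'
#' @slot bold TimeSeriesMatrix of sampled BOLD signals.
#' @slot neural fine-grid neural state matrix.
#' @slot inputs fine-grid binary input trains (without additive noise).
#' @slot truth n x n ground-truth adjacency.
#' @slot perNodeTransit realised venous transit times, seconds.
#' @slot spec the generating [SimulationSpec-class].
#'
#' @seealso [simulateDataset()]
#' @exportClass SimulatedDataset
setClass("SimulatedDataset",
  representation(bold = "TimeSeriesMatrix", neural = "matrix",
                 inputs = "matrix", truth = "matrix",
                 perNodeTransit = "numeric", spec = "SimulationSpec"))
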