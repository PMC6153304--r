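#' @include AllClasses.R AllGenerics.R
NULL

## population SD (denominator T), used by the standardization convention
popSD <- function(x) sqrt(mean((x - mean(x))^2))

#' @describeIn tsValues data matrix of a time-series object.
#' @export
setMethod("tsValues", "TimeSeriesMatrix", function(x) x@values)

#' @describeIn tsValues binary matrix of a thresholded activation object.
#' @export
setMethod("tsValues", "BinaryActivationMatrix", function(x) x@values)

#' @describeIn nodeLabels labels of a time-series matrix.
#' @export
setMethod("nodeLabels", "TimeSeriesMatrix", function(x) x@nodeLabels)

#' @describeIn nodeLabels labels of a binary activation matrix.
#' @export
setMethod("nodeLabels", "BinaryActivationMatrix", function(x) x@nodeLabels)

#' @describeIn nodeLabels labels of a directed network.
#' @export
setMethod("nodeLabels", "DirectedNetwork", function(x) x@nodeLabels)

#' @describeIn nodeLabels labels of a model-evidence table.
#' @export
setMethod("nodeLabels", "ModelEvidenceTable", function(x) x@nodeLabels)

#' @describeIn isStandardized flag of a time-series matrix.
#' @export
setMethod("isStandardized", "TimeSeriesMatrix", function(x) x@standardized)

#' @describeIn adjacency adjacency of an estimated network.
#' @export
setMethod("adjacency", "DirectedNetwork", function(x) x@adjacency)

#' @describeIn adjacency ground-truth adjacency of a simulated dataset.
#' @export
setMethod("adjacency", "SimulatedDataset", function(x) x@truth)

#' @describeIn parentSets winning parent sets per child.
#' @export
setMethod("parentSets", "DirectedNetwork", function(x) x@parentSets)

#' @describeIn discountFactors per-child optimal discount factors.
#' @export
setMethod("discountFactors", "DirectedNetwork", function(x) x@delta)

#' @describeIn logEvidence evidence of a single fitted DLM.
#' @export
setMethod("logEvidence", "DLMFit", function(x) x@logEvidence)

#' @describeIn logEvidence per-child evidences of a network.
#' @export
setMethod("logEvidence", "DirectedNetwork", function(x) x@logEvidence)

#' @describeIn totalLogEvidence total evidence of a network.
#' @export
setMethod("totalLogEvidence", "DirectedNetwork",
          function(x) x@totalLogEvidence)

#' @describeIn evidenceTable tabulated evidence for one child node.
#' @export
setMethod("evidenceTable", "ModelEvidenceTable", function(x, child) {
  child <- as.integer(child)
  stopifnot(length(child) == 1L, child >= 1L, child <= x@nNodes)
  subs <- x@subsets[[child]]
  data.frame(
    parents = vapply(subs, function(s) paste(s, collapse = ","), ""),
    size = lengths(subs),
    logEvidence = x@logEvidence[[child]],
    delta = x@delta[[child]],
    stringsAsFactors = FALSE)
})

setMethod("show", "TimeSeriesMatrix", function(object) {
  v <- object@values
  cat(sprintf("TimeSeriesMatrix: %d time points x %d nodes (%s)\n",
              nrow(v), ncol(v),
              if (object@standardized) "standardized" else "raw"))
  cat("  nodes:", paste(object@nodeLabels, collapse = ", "), "\n")
})

setMethod("show", "DLMFit", function(object) {
  cat(sprintf(
    "DLMFit: child %d <- {%s}, delta = %.3f, log evidence = %.3f\n",
    object@child, paste(object@parents, collapse = ","), object@delta,
    object@logEvidence))
})

setMethod("show", "ModelEvidenceTable", function(object) {
  n <- object@nNodes
  cat(sprintf(
    "ModelEvidenceTable: %d nodes, %d parent sets per child (%d total)\n",
    n, 2^(n - 1L), n * 2^(n - 1L)))
})

setMethod("show", "DirectedNetwork", function(object) {
  n <- nrow(object@adjacency)
  cat(sprintf("DirectedNetwork: %d nodes, %d edges, total log ME = %.3f\n",
              n, sum(object@adjacency), object@totalLogEvidence))
  for (j in seq_len(n)) {
    pa <- object@parentSets[[j]]
    if (length(pa))
      cat(sprintf("  %s <- {%s} (delta %.2f)\n", object@nodeLabels[j],
                  paste(object@nodeLabels[pa], collapse = ", "),
                  object@delta[j]))
  }
})

setMethod("show", "NetworkStack", function(object) {
  d <- dim(object@E)
  cat(sprintf("NetworkStack: %d subjects, %d nodes, %.2f edges/subject\n",
              d[1L], d[2L], mean(apply(object@E, 1L, sum))))
})

setMethod("show", "EdgeTestResult", function(object) {
  cat(sprintf(
    "EdgeTestResult: N = %d, p0 = %.4f, %d significant edges at FDR %.2f\n",
    object@nSubjects, object@p0, sum(object@sig, na.rm = TRUE),
    object@alpha))
})

setMethod("show", "SimulationSpec", function(object) {
  cat(sprintf(
    "SimulationSpec: %d nodes, %d true edges, %s, %.0f s @ TR %.1f s\n",
    object@nNodes, sum(object@trueAdjacency),
    if (object@dynamic) "dynamic (gated) coupling" else "stationary coupling",
    object@duration, object@TR))
})

setMethod("show", "SimulatedDataset", function(object) {
  cat(sprintf(
    "SimulatedDataset: %d x %d BOLD matrix, %d true edges\n",
    nrow(object@bold@values), ncol(object@bold@values), sum(object@truth)))
})
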