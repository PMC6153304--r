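#' @include AllClasses.R
NULL

#' Extract the numeric data matrix
#'
#' @param x a [TimeSeriesMatrix-class] or [BinaryActivationMatrix-class].
#' @return the underlying T x n numeric matrix.
#' @export
setGeneric("tsValues", function(x) standardGeneric("tsValues"))

#' Node labels of an object
#'
#' @param x an object carrying node labels.
#' @return character vector of labels.
#' @export
setGeneric("nodeLabels", function(x) standardGeneric("nodeLabels"))

#' Has the standardization convention been applied?
#'
#' @param x a [TimeSeriesMatrix-class].
#' @return logical flag.
#' @export
setGeneric("isStandardized", function(x) standardGeneric("isStandardized"))

#' Standardize a time-series matrix for network estimation
#'
#' Mean-centers every column and divides *all* columns by the single
#' global factor mean(per-column SD), so that the average temporal SD
#' across nodes is 1 while the relative variances between nodes are
#' preserved. Nodes are deliberately *not* variance-normalized
#' individually: the relative variance between nodes carries
#' directionality information that the per-node dynamic regressions
#' exploit.
#'
#' Population SDs (denominator T) are used in the global scale factor.
#'
#' @param x a [TimeSeriesMatrix-class] with `standardized = FALSE`.
#' @return a standardized [TimeSeriesMatrix-class].
#' @examples
#' ts <- TimeSeriesMatrix(cbind(a = rnorm(100, sd = 2),
#'                              b = rnorm(100, sd = 4)))
#' s <- standardize(ts)
#' mean(apply(tsValues(s), 2, sd)) # ~1
#' @export
setGeneric("standardize", function(x) standardGeneric("standardize"))

#' Adjacency matrix of a directed network
#'
#' @param x a [DirectedNetwork-class] or [SimulatedDataset-class] (for
#'   the latter the ground-truth adjacency is returned).
#' @return n x n binary matrix, entry \[i, j\] = 1 for an edge i -> j.
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))

#' Winning parent sets of a directed network
#'
#' @param x a [DirectedNetwork-class].
#' @return list of integer parent vectors, one per child node.
#' @export
setGeneric("parentSets", function(x) standardGeneric("parentSets"))

#' Per-child optimal discount factors
#'
#' @param x a [DirectedNetwork-class].
#' @return numeric vector of discount factors.
#' @export
setGeneric("discountFactors", function(x) standardGeneric("discountFactors"))

#' Log model evidence
#'
#' @param x a [DLMFit-class] or [DirectedNetwork-class] (per child).
#' @return numeric log evidence.
#' @export
setGeneric("logEvidence", function(x) standardGeneric("logEvidence"))

#' Total log model evidence of a network
#'
#' Sum of the per-child log model evidences of the winning parent sets.
#'
#' @param x a [DirectedNetwork-class].
#' @return a single number.
#' @export
setGeneric("totalLogEvidence",
           function(x) standardGeneric("totalLogEvidence"))

#' Tabulate the evidence of all parent sets of one child
#'
#' @param x a [ModelEvidenceTable-class].
#' @param child child node index.
#' @return data.frame with columns `parents` (comma-separated indices,
#'   "" for the intercept-only model), `size`, `logEvidence` and `delta`,
#'   in the deterministic subset order (size, then lexicographic).
#' @export
setGeneric("evidenceTable",
           function(x, child) standardGeneric("evidenceTable"))
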