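#' @include AllClasses.R AllGenerics.R accessors.R
NULL

#' Conjugate priors for the node-level dynamic regressions
#'
#' @param m0 state prior mean; scalar (recycled) or vector.
#' @param C0star scale-free state prior variance; positive scalar c
#'   (meaning c times the identity) or an SPD matrix.
#' @param n0,d0 precision-prior hyperparameters (shape n0/2, rate d0/2).
#' @return a [DLMPriors-class].
#' @examples
#' dlmPriors()            # m0 = 0, C0* = 3 I, n0 = d0 = 0.001
#' @export
dlmPriors <- function(m0 = 0, C0star = 3, n0 = 0.001, d0 = 0.001) {
  new("DLMPriors", m0 = m0, C0star = C0star, n0 = n0, d0 = d0)
}

## expand scalar priors to dimension p
materializePriors <- function(priors, p) {
  m0 <- priors@m0
  if (length(m0) == 1L) m0 <- rep(m0, p)
  if (length(m0) != p)
    stop("prior mean has length ", length(m0), ", model dimension is ", p)
  C0 <- priors@C0star
  if (!is.matrix(C0)) C0 <- diag(C0, p)
  if (nrow(C0) != p)
    stop("prior variance has dimension ", nrow(C0),
         ", model dimension is ", p)
  list(m0 = m0, C0 = C0)
}

#' Build the design information for one child node
#'
#' @param ts a [TimeSeriesMatrix-class] (or plain T x n matrix).
#' @param child child node index.
#' @param parents integer vector of parent indices (possibly empty),
#'   excluding the child.
#' @return a [RegressorSet-class] whose design matrix is
#'   `cbind(1, ts[, parents])`.
#' @export
regressorSet <- function(ts, child, parents = integer()) {
  v <- if (is(ts, "TimeSeriesMatrix")) ts@values else as.matrix(ts)
  child <- as.integer(child)
  parents <- as.integer(parents)
  if (any(parents < 1L) || any(parents > ncol(v)) || child > ncol(v))
    stop("node indices must lie in [1, ", ncol(v), "]")
  design <- cbind(1, v[, parents, drop = FALSE])
  new("RegressorSet", child = child, parents = parents, design = design)
}

designMatrix <- function(X, T) {
  if (is(X, "RegressorSet")) return(X@design)
  if (is.null(X)) return(matrix(1, T, 1L))
  X <- as.matrix(X)
  cbind(1, X)
}

#' Filter one dynamic regression at a fixed discount factor
#'
#' Runs the conjugate filtering recursion for the dynamic linear
#' regression of a child series on its parents with a random walk on
#' the coefficients. With discount factor \eqn{\delta}, the scale-free
#' prior state variance at time t is \eqn{R^*_t = C^*_{t-1}/\delta};
#' \eqn{\delta = 1} recovers a static Bayesian regression. The one-step
#' forecast of \eqn{y_t} is Student-t with \eqn{n_{t-1}} degrees of
#' freedom, location \eqn{F_t' m_{t-1}} and squared scale
#' \eqn{(d_{t-1}/n_{t-1}) Q^*_t}; the log model evidence is the sum of
#' the forecast log densities. Note the very small default \eqn{n_0}
#' makes the first forecast extremely heavy-tailed; this is intended.
#'
#' @param y numeric child series of length T (standardized scale
#'   recommended; see [standardize()]).
#' @param X a [RegressorSet-class], a T x |Pa| matrix of parent series
#'   (an intercept column is added), or NULL for the intercept-only
#'   model.
#' @param delta discount factor in (0, 1].
#' @param priors a [DLMPriors-class].
#' @return a [DLMFit-class].
#' @examples
#' y <- rnorm(50); x <- rnorm(50)
#' fit <- filterDLM(y, cbind(x), delta = 0.9)
#' logEvidence(fit)
#' @export
filterDLM <- function(y, X = NULL, delta = 1, priors = dlmPriors()) {
  y <- as.numeric(y)
  if (length(y) < 2L) stop("need at least 2 time points")
  if (any(!is.finite(y))) stop("'y' contains non-finite values")
  if (length(delta) != 1L || delta <= 0 || delta > 1)
    stop("'delta' must lie in (0, 1]")
  F <- designMatrix(X, length(y))
  if (nrow(F) != length(y))
    stop("design matrix and 'y' disagree in length")
  if (any(!is.finite(F))) stop("design matrix contains non-finite values")
  pr <- materializePriors(priors, ncol(F))
  out <- dlm_filter_cpp(y, F, delta, pr$m0, pr$C0, priors@n0, priors@d0)
  child <- if (is(X, "RegressorSet")) X@child else NA_integer_
  parents <- if (is(X, "RegressorSet")) X@parents else integer()
  new("DLMFit", child = child, parents = parents, delta = delta,
      logEvidence = out$logEvidence, mPath = out$mPath,
      CstarPath = out$CstarPath, nPath = as.numeric(out$nPath),
      dPath = as.numeric(out$dPath),
      forecastLogDens = as.numeric(out$forecastLogDens))
}

#' Default discount-factor grid
#'
#' 0.50 to 1.00 in steps of 0.01 (51 values).
#'
#' @return numeric vector of grid values.
#' @export
defaultDeltaGrid <- function() seq(0.5, 1, by = 0.01)

#' Optimise the discount factor of one dynamic regression
#'
#' Runs [filterDLM()] at every grid value and returns the fit with the
#' largest log model evidence; exact ties are broken toward the largest
#' discount factor (the smoothest model).
#'
#' @inheritParams filterDLM
#' @param grid ordered vector of discount factors within \[0.5, 1\].
#' @return a [DLMFit-class] at the optimal grid value.
#' @export
searchDiscount <- function(y, X = NULL, priors = dlmPriors(),
                           grid = defaultDeltaGrid()) {
  if (length(grid) == 0L) stop("discount grid must be nonempty")
  if (any(grid < 0.5 - 1e-12) || any(grid > 1 + 1e-12))
    stop("discount grid values must lie within [0.5, 1]")
  y <- as.numeric(y)
  F <- designMatrix(X, length(y))
  pr <- materializePriors(priors, ncol(F))
  logev <- tryCatch(
    as.numeric(dlm_grid_cpp(y, F, grid, pr$m0, pr$C0, priors@n0,
                            priors@d0)),
    error = function(e) stop("discount grid search failed: ",
                             conditionMessage(e), call. = FALSE))
  best <- max(which(logev == max(logev)))    # tie -> largest delta
  filterDLM(y, X, delta = grid[best], priors = priors)
}
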