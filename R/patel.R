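#' @include AllClasses.R AllGenerics.R accessors.R
NULL

#' Binarize node time series for Patel's conditional-dependence measures
#'
#' Each node is min-max scaled to \[0, 1\] and set to 1 strictly above
#' the `q`-quantile of its scaled values (quantile type 7, linear
#' interpolation).
#'
#' @param ts a [TimeSeriesMatrix-class] or T x n matrix.
#' @param q threshold quantile in (0, 1); default 0.75.
#' @return a [BinaryActivationMatrix-class].
#' @examples
#' b <- binarize(TimeSeriesMatrix(matrix(rnorm(200), 100, 2)))
#' colMeans(tsValues(b))   # ~0.25 active
#' @export
binarize <- function(ts, q = 0.75) {
  if (length(q) != 1L || q <= 0 || q >= 1)
    stop("'q' must lie strictly in (0, 1)")
  v <- if (is(ts, "TimeSeriesMatrix")) ts@values else as.matrix(ts)
  labels <- colnames(v)
  if (is.null(labels)) labels <- paste0("V", seq_len(ncol(v)))
  b <- apply(v, 2L, function(x) {
    rg <- range(x)
    if (rg[1L] == rg[2L])
      stop("constant node series cannot be binarized")
    xs <- (x - rg[1L]) / (rg[2L] - rg[1L])
    as.numeric(xs > quantile(xs, q, type = 7, names = FALSE))
  })
  new("BinaryActivationMatrix", values = b, thresholdQuantile = q,
      nodeLabels = labels)
}

## vectorised kappa from the three joint activation probabilities
## theta1 = P(a=1, b=1), theta2 = P(a=1, b=0), theta3 = P(a=0, b=1)
kappaFromTheta <- function(t1, t2, t3, eps = 1e-12) {
  E <- (t1 + t2) * (t1 + t3)
  tmax <- pmin(t1 + t2, t1 + t3)
  tmin <- pmax(0, 2 * t1 + t2 + t3 - 1)
  num <- t1 - E
  D <- 0.5 * (1 + num / pmax(abs(num), eps))  # 1 if t1 > E, 0 if <, .5 tie
  den <- D * (tmax - E) + (1 - D) * (E - tmin)
  ifelse(abs(den) <= eps, 0, num / den)
}

tauFromTheta <- function(t1, t2, t3) {
  ifelse(t2 >= t3,
         1 - (t1 + t3) / (t1 + t2),
         (t1 + t2) / (t1 + t3) - 1)
}

#' Patel's pairwise connection strength and direction
#'
#' From the empirical joint activation frequencies of two binarized
#' series a and b -- theta1 = P(a=1, b=1), theta2 = P(a=1, b=0), theta3
#' = P(a=0, b=1) -- kappa measures the departure of the joint activation
#' from independence, normalised to \[-1, 1\] by its attainable extreme
#' (the bound used depends on the sign of theta1 - E with E the product
#' of the marginals), and tau measures the asymmetry of the conditional
#' probabilities: positive tau means a is ascendant (edge a -> b).
#'
#' @param a,b binary vectors of equal length (T >= 2).
#' @return list with elements `kappa`, `tau` and `theta` (the four
#'   joint probabilities P11, P10, P01, P00).
#' @examples
#' a <- c(1, 1, 0, 0, 1, 0); b <- c(1, 0, 0, 0, 1, 0)
#' patelKappaTau(a, b)
#' @export
patelKappaTau <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b) || length(a) < 2L)
    stop("'a' and 'b' must have equal length >= 2")
  if (!all(a %in% c(0, 1)) || !all(b %in% c(0, 1)))
    stop("inputs must be binary")
  t1 <- mean(a == 1 & b == 1)
  t2 <- mean(a == 1 & b == 0)
  t3 <- mean(a == 0 & b == 1)
  t4 <- 1 - t1 - t2 - t3
  if (t1 + t2 == 0 || t1 + t3 == 0)
    stop("a node is never active; tau is undefined")
  list(kappa = kappaFromTheta(t1, t2, t3),
       tau = tauFromTheta(t1, t2, t3),
       theta = c(P11 = t1, P10 = t2, P01 = t3, P00 = t4))
}

#' All-pairs Patel kappa and tau of a binarized dataset
#'
#' @param bin a [BinaryActivationMatrix-class] (or a
#'   [TimeSeriesMatrix-class], binarized with [binarize()] defaults).
#' @return a [PatelResult-class]; `kappa` is symmetric, `tau`
#'   antisymmetric with positive `tau[i, j]` meaning i -> j.
#' @export
patelPairwise <- function(bin) {
  if (is(bin, "TimeSeriesMatrix")) bin <- binarize(bin)
  stopifnot(is(bin, "BinaryActivationMatrix"))
  v <- bin@values
  n <- ncol(v)
  kap <- matrix(NA_real_, n, n,
                dimnames = list(bin@nodeLabels, bin@nodeLabels))
  tau <- kap
  theta <- array(NA_real_, dim = c(n, n, 4L),
                 dimnames = list(bin@nodeLabels, bin@nodeLabels,
                                 c("P11", "P10", "P01", "P00")))
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    kt <- patelKappaTau(v[, i], v[, j])
    kap[i, j] <- kap[j, i] <- kt$kappa
    tau[i, j] <- kt$tau
    tau[j, i] <- -kt$tau
    theta[i, j, ] <- kt$theta
    theta[j, i, ] <- kt$theta[c(1L, 3L, 2L, 4L)]
  }
  new("PatelResult", kappa = kap, tau = tau, theta = theta)
}

## mean kappa across subjects for every unordered pair, given T x n x N
## binary array A and, for each subject, the subject supplying node j's
## series (identity for the observed statistic)
meanKappaPairs <- function(A, pairs, partner = NULL) {
  N <- dim(A)[3L]
  if (is.null(partner)) partner <- seq_len(N)
  out <- numeric(nrow(pairs))
  for (p in seq_len(nrow(pairs))) {
    Mi <- A[, pairs[p, 1L], , drop = TRUE]
    Mj <- A[, pairs[p, 2L], partner, drop = TRUE]
    t1 <- colMeans(Mi * Mj)
    t2 <- colMeans(Mi) - t1
    t3 <- colMeans(Mj) - t1
    out[p] <- mean(kappaFromTheta(t1, t2, t3))
  }
  out
}

#' Group permutation test for Patel's kappa with tau-based orientation
#'
#' The observed statistic of a node pair is the mean kappa across
#' subjects. The null distribution is built by pairing, for each
#' permutation and each pair (i, j), node i's series of every subject
#' with node j's series of a randomly chosen *different* subject
#' (shuffling time series across subjects while keeping nodes fixed) and
#' recomputing the mean kappa. Two-sided permutation p-values are
#' FDR-adjusted (BH) across pairs; each significant pair is oriented by
#' the sign of the mean tau across subjects.
#'
#' @param group list of [BinaryActivationMatrix-class] (or
#'   [TimeSeriesMatrix-class], binarized at 0.75), one per subject, all
#'   with the same nodes and series length.
#' @param nPerm number of permutations (>= 100; default 1000).
#' @param alpha FDR level.
#' @param seed optional integer seed for reproducible permutations.
#' @return list with `adjacency` (binary n x n, oriented significant
#'   pairs), `kappa` (observed mean kappa per pair, n x n symmetric),
#'   `meanTau`, `pvals` and `qvals` (symmetric matrices).
#' @export
kappaPermutationTest <- function(group, nPerm = 1000, alpha = 0.05,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (length(group) < 2L) stop("need at least 2 subjects to permute")
  if (nPerm < 100L) stop("'nPerm' must be at least 100")
  bins <- lapply(group, function(g)
    if (is(g, "TimeSeriesMatrix")) binarize(g) else g)
  n <- ncol(bins[[1L]]@values)
  Tlen <- nrow(bins[[1L]]@values)
  if (any(vapply(bins, function(b) ncol(b@values) != n ||
                 nrow(b@values) != Tlen, logical(1L))))
    stop("all subjects must share node count and series length")
  N <- length(bins)
  A <- array(0, dim = c(Tlen, n, N))
  for (s in seq_len(N)) A[, , s] <- bins[[s]]@values
  pairs <- t(combn(n, 2L))

  obs <- meanKappaPairs(A, pairs)
  exceed <- integer(nrow(pairs))
  for (b in seq_len(nPerm)) {
    partner <- vapply(seq_len(N),
                      function(s) sample(seq_len(N)[-s], 1L), integer(1L))
    nullk <- meanKappaPairs(A, pairs, partner)
    exceed <- exceed + (abs(nullk) >= abs(obs))
  }
  pv <- (1 + exceed) / (nPerm + 1)
  qv <- p.adjust(pv, method = "BH")

  meanTau <- matrix(0, n, n)
  for (s in seq_len(N)) meanTau <- meanTau + patelPairwise(bins[[s]])@tau
  meanTau <- meanTau / N

  labels <- bins[[1L]]@nodeLabels
  adj <- matrix(0, n, n, dimnames = list(labels, labels))
  kapM <- matrix(NA_real_, n, n, dimnames = list(labels, labels))
  pM <- kapM; qM <- kapM
  for (p in seq_len(nrow(pairs))) {
    i <- pairs[p, 1L]; j <- pairs[p, 2L]
    kapM[i, j] <- kapM[j, i] <- obs[p]
    pM[i, j] <- pM[j, i] <- pv[p]
    qM[i, j] <- qM[j, i] <- qv[p]
    if (qv[p] <= alpha) {
      if (meanTau[i, j] >= 0) adj[i, j] <- 1 else adj[j, i] <- 1
    }
  }
  list(adjacency = adj, kappa = kapM, meanTau = meanTau, pvals = pM,
       qvals = qM)
}
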