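# Independent oracles for the dynamic-regression evidence, coded from
# the joint distribution of the observations rather than the sequential
# filter, plus small simulation helpers shared across test files.

# Scale-free joint covariance of y implied by the discount random walk:
# the innovation variances W*_t are a data-free function of the design
# (Riccati-style recursion), the state path has covariance
# Cov(theta_t, theta_s) = C0* + sum_{u <= min(t,s)} W*_u, and
# Cov(y) = F Cov(theta) F' + I (all times V).
dlmJointSigma <- function(F, delta, C0) {
  T <- nrow(F)
  C <- C0
  cums <- vector("list", T)
  cum <- C0
  for (t in seq_len(T)) {
    R <- C / delta
    W <- R - C
    cum <- cum + W
    cums[[t]] <- cum
    Ft <- F[t, ]
    Q <- drop(t(Ft) %*% R %*% Ft) + 1
    A <- (R %*% Ft) / Q
    C <- R - (A %*% t(A)) * Q
    C <- (C + t(C)) / 2
  }
  Sig <- matrix(0, T, T)
  for (t in seq_len(T)) for (s in seq_len(T))
    Sig[t, s] <- drop(t(F[t, ]) %*% cums[[min(t, s)]] %*% F[s, ]) +
      as.numeric(t == s)
  Sig
}

# Closed-form marginal likelihood: y | V ~ N(F m0, V Sigma), precision
# ~ Gamma(n0/2, d0/2)  =>  multivariate Student-t evaluated directly.
dlmEvidenceClosedForm <- function(y, F, delta, m0 = NULL, C0 = NULL,
                                  n0 = 0.001, d0 = 0.001) {
  p <- ncol(F)
  if (is.null(m0)) m0 <- rep(0, p)
  if (is.null(C0)) C0 <- diag(3, p)
  T <- length(y)
  Sig <- dlmJointSigma(F, delta, C0)
  r <- y - drop(F %*% m0)
  Q <- drop(t(r) %*% solve(Sig, r))
  ld <- as.numeric(determinant(Sig)$modulus)
  -0.5 * ld - (T / 2) * log(2 * pi) +
    lgamma((n0 + T) / 2) - lgamma(n0 / 2) +
    (n0 / 2) * log(d0 / 2) - ((n0 + T) / 2) * log((d0 + Q) / 2)
}

# Brute-force marginal likelihood: numerical quadrature over the
# observation precision of the Gaussian likelihood N(y; F m0, Sigma/phi)
# times the Gamma(n0/2, d0/2) prior density.
dlmEvidenceQuadrature <- function(y, F, delta, m0 = NULL, C0 = NULL,
                                  n0 = 0.001, d0 = 0.001) {
  p <- ncol(F)
  if (is.null(m0)) m0 <- rep(0, p)
  if (is.null(C0)) C0 <- diag(3, p)
  T <- length(y)
  Sig <- dlmJointSigma(F, delta, C0)
  r <- y - drop(F %*% m0)
  Q <- drop(t(r) %*% solve(Sig, r))
  ld <- as.numeric(determinant(Sig)$modulus)
  logIntegrand <- function(phi)
    dgamma(phi, n0 / 2, rate = d0 / 2, log = TRUE) +
      (T / 2) * log(phi) - 0.5 * ld - (T / 2) * log(2 * pi) -
      0.5 * phi * Q
  # peak of the gamma-shaped integrand, for stable rescaling
  shape <- (n0 + T) / 2
  rate <- (d0 + Q) / 2
  M <- logIntegrand(max((shape - 1) / rate, 1e-12))
  val <- integrate(function(phi) exp(logIntegrand(phi) - M), 0, Inf,
                   rel.tol = 1e-10, abs.tol = 0)$value
  M + log(val)
}

# Incremental conjugate Bayesian static regression (normal-gamma),
# textbook update formulas applied one observation at a time; posterior
# means must match the delta = 1 filter path.
staticRegressionMeans <- function(y, F, m0 = NULL, C0 = NULL) {
  p <- ncol(F)
  if (is.null(m0)) m0 <- rep(0, p)
  if (is.null(C0)) C0 <- diag(3, p)
  P <- solve(C0)              # scale-free precision
  b <- P %*% m0
  out <- matrix(0, length(y), p)
  for (t in seq_along(y)) {
    Ft <- F[t, ]
    P <- P + Ft %*% t(Ft)
    b <- b + Ft * y[t]
    out[t, ] <- solve(P, b)
  }
  out
}

# random standardized time-series matrix
randomStandardizedTS <- function(T, n) {
  standardize(TimeSeriesMatrix(matrix(rnorm(T * n), T, n)))
}

# run a small simulation study: returns per-dataset fitted results
fitStudy <- function(spec, nDatasets, e = 0) {
  lapply(seq_len(nDatasets), function(i) {
    ds <- simulateDataset(spec)
    dgmFit(tsValues(ds@bold), e = e)
  })
}
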