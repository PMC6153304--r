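#' @include AllClasses.R AllGenerics.R accessors.R
NULL

## Canonical balloon/Windkessel parameter set (per-node hemodynamics).
## eps: neural efficacy; kappa: vasodilatory signal decay (1/s); gamma:
## flow-dependent elimination (1/s); tau0: venous transit time (s);
## alpha: Grubb vessel stiffness exponent; E0: resting oxygen
## extraction; V0: resting venous volume fraction.
balloonParams <- function() {
  list(eps = 0.2, kappa = 0.65, gamma = 0.41, tau0 = 0.98,
       alpha = 0.32, E0 = 0.4, V0 = 0.04)
}

## smallest admissible venous transit time; below this the Windkessel
## equations become too stiff for the fine Euler grid
.tau0Min <- 0.15

#' Ground-truth topology of the 5-node simulation network
#'
#' Directed edges 1->2, 2->3, 3->4, 4->5 and 1->5.
#'
#' @return 5 x 5 binary adjacency matrix (parent -> child).
#' @export
fiveNodeTruth <- function() {
  A <- matrix(0, 5, 5)
  A[cbind(c(1, 2, 3, 4, 1), c(2, 3, 4, 5, 5))] <- 1
  dimnames(A) <- list(paste0("N", 1:5), paste0("N", 1:5))
  A
}

#' Default ground-truth topology of the 8-node simulation network
#'
#' A chain-plus-branches graph with two reciprocal pairs (2<->3 and
#' 6<->7) totalling 10 directed edges. The exact 8-node layout used in
#' the original validation study is not fully published; this default is
#' an approximation with the same node count, reciprocal-pair count and
#' edge count, and can be replaced by any adjacency via
#' [simulationSpec()].
#'
#' @return 8 x 8 binary adjacency matrix.
#' @export
eightNodeTruth <- function() {
  A <- matrix(0, 8, 8)
  A[cbind(c(1, 2, 3, 3, 4, 1, 5, 6, 7, 7),
          c(2, 3, 2, 4, 5, 5, 6, 7, 6, 8))] <- 1
  dimnames(A) <- list(paste0("N", 1:8), paste0("N", 1:8))
  A
}

#' Construct a simulation specification
#'
#' @param trueAdjacency n x n binary ground-truth adjacency
#'   (parent -> child), zero diagonal.
#' @param connectionStrength neural coupling weight of the true edges;
#'   the default is calibrated so that truly connected node pairs show
#'   BOLD correlations around 0.3, matching the descriptive statistics
#'   reported for this class of network simulations.
#' @param neuralLag within-node neural decay time constant in seconds
#'   (0.05 for the 5-node presets, 0.5 for the 8-node presets).
#' @param dynamic gate each true edge on/off over time?
#' @param gateMeanOff mean duration (s) of the exponentially distributed
#'   gate intervals (used for both off and on intervals).
#' @param duration,TR total length and sampling interval, seconds.
#' @param noisePct measurement-noise SD in percent of the baseline
#'   (baseline = 100; the BOLD excursion is scaled to about 4%).
#' @param hrfLagSd SD (s) of the random per-node jitter on the venous
#'   transit time (hemodynamic-lag variability).
#' @param transitTimeOffsets per-node systematic venous transit-time
#'   offsets (s) relative to canonical; see
#'   [calibrateTransitOffsets()].
#' @param inputOnMean,inputOffMean,inputDurationRange mean on/off
#'   durations and truncation range (s) of the binary input trains.
#' @param inputNoiseFrac SD of the additive input noise relative to the
#'   unit neural amplitude.
#' @param dt Euler step, seconds (default 5 ms).
#' @return a [SimulationSpec-class].
#' @export
simulationSpec <- function(trueAdjacency, connectionStrength = 1.1,
                           neuralLag = 0.05, dynamic = TRUE,
                           gateMeanOff = 30, duration = 600, TR = 3,
                           noisePct = 0.1, hrfLagSd = 0.5,
                           transitTimeOffsets = NULL,
                           inputOnMean = 2.7, inputOffMean = 10,
                           inputDurationRange = c(0.77, 10.1),
                           inputNoiseFrac = 1 / 20, dt = 0.005) {
  A <- as.matrix(trueAdjacency)
  n <- nrow(A)
  if (is.null(transitTimeOffsets)) transitTimeOffsets <- rep(0, n)
  new("SimulationSpec", nNodes = as.integer(n), trueAdjacency = A,
      connectionStrength = connectionStrength, neuralLag = neuralLag,
      dynamic = dynamic, gateMeanOff = gateMeanOff, duration = duration,
      TR = TR, noisePct = noisePct, hrfLagSd = hrfLagSd,
      transitTimeOffsets = as.numeric(transitTimeOffsets),
      inputOnMean = inputOnMean, inputOffMean = inputOffMean,
      inputDurationRange = as.numeric(inputDurationRange),
      inputNoiseFrac = inputNoiseFrac, dt = dt)
}

## truncated exponential durations via inverse-CDF sampling
rtexp <- function(n, mean, lo, hi) {
  rate <- 1 / mean
  u <- runif(n, pexp(lo, rate), pexp(hi, rate))
  qexp(u, rate)
}

## one binary on/off train on the fine grid; both on and off durations
## are exponentials truncated to the admissible duration range, the
## train starts in the off state
inputTrain <- function(nT, dt, onMean, offMean, range) {
  tEnd <- nT * dt
  times <- numeric(0)
  states <- logical(0)
  total <- 0
  on <- FALSE
  while (total < tEnd) {
    d <- rtexp(1L, if (on) onMean else offMean, range[1L], range[2L])
    times <- c(times, d)
    states <- c(states, on)
    total <- total + d
    on <- !on
  }
  expandTrain(states, times, nT, dt)
}

## turn (state, duration) pairs into a fine-grid 0/1 vector of length nT
expandTrain <- function(states, times, nT, dt) {
  v <- rep(as.numeric(states), times = pmax(1L, round(times / dt)))
  if (length(v) < nT) v <- c(v, rep(v[length(v)], nT - length(v)))
  v[seq_len(nT)]
}

## binary gate train with exponential on/off intervals (mean gateMean
## for both), random initial state
gateTrain <- function(nT, dt, gateMean) {
  tEnd <- nT * dt
  times <- numeric(0)
  states <- logical(0)
  total <- 0
  on <- runif(1L) < 0.5
  while (total < tEnd) {
    d <- rexp(1L, 1 / gateMean)
    times <- c(times, d)
    states <- c(states, on)
    total <- total + d
    on <- !on
  }
  expandTrain(states, times, nT, dt)
}

#' Simulate the neural states of a network
#'
#' Each node receives a binary external input train (truncated
#' exponential on/off durations) plus additive Gaussian input noise; the
#' neural states follow the linear dynamics \eqn{\dot z = \sigma(A z +
#' C u)} integrated by Euler on the fine grid, with diagonal -1,
#' \eqn{\sigma = 1 /} `neuralLag`, and off-diagonal entries
#' `connectionStrength` times the (possibly time-varying) gate of each
#' true edge. When `dynamic = TRUE` every edge is switched off for
#' exponentially distributed intervals of mean `gateMeanOff` seconds.
#'
#' @param spec a [SimulationSpec-class].
#' @return list with fine-grid matrices `neural` (states), `inputs`
#'   (noise-free binary trains), `gates` (one column per true edge),
#'   the `edges` index matrix (parent, child) and the time step `dt`.
#' @export
simulateNeural <- function(spec) {
  stopifnot(is(spec, "SimulationSpec"))
  n <- spec@nNodes
  nT <- round(spec@duration / spec@dt)
  inputs <- vapply(seq_len(n), function(j)
    inputTrain(nT, spec@dt, spec@inputOnMean, spec@inputOffMean,
               spec@inputDurationRange), numeric(nT))
  u <- inputs + matrix(rnorm(nT * n, 0, spec@inputNoiseFrac), nT, n)
  idx <- which(spec@trueAdjacency == 1, arr.ind = TRUE)
  edges <- matrix(as.integer(idx), ncol = 2L)   # col1 parent, col2 child
  k <- nrow(edges)
  gates <- if (spec@dynamic && k > 0L)
    vapply(seq_len(k), function(e)
      gateTrain(nT, spec@dt, spec@gateMeanOff), numeric(nT))
  else matrix(1, nT, max(k, 1L))
  if (k == 0L) edges <- matrix(integer(), 0L, 2L)
  z <- neural_integrate_cpp(u, edges,
                            rep(spec@connectionStrength, k),
                            gates, 1 / spec@neuralLag, spec@dt)
  list(neural = z, inputs = inputs, gates = gates, edges = edges,
       dt = spec@dt)
}

#' Balloon-model BOLD transform of neural states
#'
#' Applies the nonlinear balloon/Windkessel hemodynamic model per node
#' (vasodilatory signal, inflow, venous volume, deoxyhemoglobin;
#' canonical parameters in the package source) with node-specific venous
#' transit times, returning percent signal change on the fine grid.
#'
#' @param neural fine-grid neural state matrix.
#' @param spec a [SimulationSpec-class] (supplies dt).
#' @param tau0 per-node venous transit times in seconds; default
#'   canonical + `spec@transitTimeOffsets`.
#' @return fine-grid BOLD matrix, percent signal change around 0.
#' @export
balloonBOLD <- function(neural, spec, tau0 = NULL) {
  bp <- balloonParams()
  if (is.null(tau0)) tau0 <- bp$tau0 + spec@transitTimeOffsets
  if (any(tau0 < .tau0Min))
    stop("venous transit time below ", .tau0Min, " s is not supported")
  balloon_cpp(neural, tau0, spec@dt, bp$eps, bp$kappa, bp$gamma,
              bp$alpha, bp$E0, bp$V0)
}

#' Simulate one BOLD dataset from a network specification
#'
#' Full forward simulation: neural dynamics ([simulateNeural()]),
#' balloon-model hemodynamics with per-node transit times (systematic
#' offsets plus Normal(0, `hrfLagSd`) jitter, floored at the stability
#' limit), downsampling to TR, a single global rescaling to
#' approximately 4% signal change (preserving relative node variances),
#' and additive Gaussian measurement noise around a baseline of 100.
#'
#' @param spec a [SimulationSpec-class].
#' @return a [SimulatedDataset-class].
#' @examples
#' \donttest{
#' set.seed(1)
#' ds <- simulateDataset(simPreset("sim22"))
#' ds
#' }
#' @export
simulateDataset <- function(spec) {
  stopifnot(is(spec, "SimulationSpec"))
  n <- spec@nNodes
  bp <- balloonParams()
  tau0 <- bp$tau0 + spec@transitTimeOffsets +
    rnorm(n, 0, spec@hrfLagSd)
  tau0 <- pmax(tau0, .tau0Min)
  ns <- simulateNeural(spec)
  boldFine <- balloonBOLD(ns$neural, spec, tau0 = tau0)
  stepsPerTR <- round(spec@TR / spec@dt)
  idx <- seq(stepsPerTR, nrow(boldFine), by = stepsPerTR)
  bold <- boldFine[idx, , drop = FALSE]
  rng <- mean(apply(bold, 2L, function(x) diff(range(x))))
  if (rng > 1e-8) bold <- bold * (4 / rng)
  bold <- 100 + bold +
    matrix(rnorm(length(bold), 0, spec@noisePct), nrow(bold), n)
  labels <- colnames(spec@trueAdjacency)
  if (is.null(labels)) labels <- paste0("N", seq_len(n))
  new("SimulatedDataset",
      bold = TimeSeriesMatrix(bold, nodeLabels = labels),
      neural = ns$neural, inputs = ns$inputs,
      truth = spec@trueAdjacency, perNodeTransit = tau0, spec = spec)
}

## single-node time-to-peak (s) of the hemodynamic response to a
## blockDuration block of unit neural input, for one transit time
singleNodeTTP <- function(tau0, neuralLag, blockDuration = 2.5,
                          dt = 0.001, window = 30, onset = 1) {
  nT <- round(window / dt)
  u <- matrix(0, nT, 1L)
  u[seq(round(onset / dt), round((onset + blockDuration) / dt)), 1L] <- 1
  z <- neural_integrate_cpp(u, matrix(integer(), 0L, 2L), numeric(0),
                            matrix(1, nT, 1L), 1 / neuralLag, dt)
  bp <- balloonParams()
  bold <- balloon_cpp(z, tau0, dt, bp$eps, bp$kappa, bp$gamma,
                      bp$alpha, bp$E0, bp$V0)
  peak <- which.max(bold[, 1L])
  if (peak <= round(onset / dt) || peak >= nT)
    stop("no hemodynamic peak found within the calibration window")
  peak * dt - onset
}

#' Time to peak of each node's hemodynamic response
#'
#' Simulates a single noiseless block of neural firing (default 2.5 s)
#' at every node in isolation and measures the time from stimulus onset
#' to the peak of the simulated hemodynamic response, using each node's
#' systematic transit-time offset (no random jitter). Used to verify and
#' calibrate transit-time interventions.
#'
#' @param spec a [SimulationSpec-class].
#' @param blockDuration block length in seconds.
#' @param dt integration step for the calibration run (default 1 ms for
#'   sharper peak resolution).
#' @return numeric vector of per-node times to peak, seconds.
#' @export
measureTimeToPeak <- function(spec, blockDuration = 2.5, dt = 0.001) {
  stopifnot(is(spec, "SimulationSpec"))
  bp <- balloonParams()
  vapply(seq_len(spec@nNodes), function(j)
    singleNodeTTP(bp$tau0 + spec@transitTimeOffsets[j], spec@neuralLag,
                  blockDuration, dt), numeric(1L))
}

.ttpCache <- new.env(parent = emptyenv())

#' Calibrate transit-time offsets to target hemodynamic delays
#'
#' Finds, for each requested time-to-peak change (s, relative to the
#' canonical response), the venous transit-time offset that produces it,
#' by root finding on the monotone offset -> time-to-peak map measured
#' with [measureTimeToPeak()]'s single-block procedure. Positive delays
#' slow the response (larger transit time), negative delays speed it up.
#'
#' @param delays numeric vector of target time-to-peak changes per node,
#'   seconds (0 leaves a node canonical).
#' @param neuralLag neural decay constant used in the calibration runs.
#' @param blockDuration,dt calibration block length and step.
#' @return numeric vector of transit-time offsets, seconds.
#' @examples
#' \donttest{
#' off <- calibrateTransitOffsets(c(0.21, -0.20, 0, 0.21, -0.20))
#' }
#' @export
calibrateTransitOffsets <- function(delays, neuralLag = 0.05,
                                    blockDuration = 2.5, dt = 0.001) {
  bp <- balloonParams()
  ttp0 <- singleNodeTTP(bp$tau0, neuralLag, blockDuration, dt)
  vapply(delays, function(d) {
    if (d == 0) return(0)
    key <- sprintf("%.6f|%.4f|%.3f|%.4f", d, neuralLag, blockDuration, dt)
    if (!is.null(.ttpCache[[key]])) return(.ttpCache[[key]])
    f <- function(o) singleNodeTTP(bp$tau0 + o, neuralLag,
                                   blockDuration, dt) - ttp0 - d
    lo <- max(.tau0Min - bp$tau0 + 1e-6, -0.8)
    root <- uniroot(f, lower = lo, upper = 6, tol = dt / 2)$root
    .ttpCache[[key]] <- root
    root
  }, numeric(1L))
}

## Table of per-node hemodynamic delay targets (s) for the systematic
## "slow parent, fast child" interventions: nodes 1 and 4 are slowed,
## nodes 2 and 5 sped up, node 3 untouched.
offsetDelayTargets <- list(
  "offset0.4" = c(0.21, -0.20), "offset0.8" = c(0.48, -0.35),
  "offset1.1" = c(0.69, -0.46), "offset1.4" = c(0.85, -0.54),
  "offset1.7" = c(1.04, -0.58), "offset1.9" = c(1.24, -0.59))

#' Predefined simulation presets
#'
#' Returns the [SimulationSpec-class] of a named study condition:
#' \describe{
#'   \item{"sim1"}{stationary 5-node network, 10 min, TR 3 s, 1.0%
#'     noise, transit-time jitter SD 0.5 s.}
#'   \item{"sim22"}{dynamic (gated) 5-node network, 10 min, TR 3 s,
#'     0.1% noise, jitter SD 0.5 s.}
#'   \item{"offset<0.4"}{dynamic 5-node, TR 2 s, jitter SD 0.3 s, no
#'     systematic offsets.}
#'   \item{"offset0.4" .. "offset1.9"}{dynamic 5-node, TR 2 s, with
#'     systematic transit-time interventions calibrated so nodes 1 and 4
#'     peak later and nodes 2 and 5 peak earlier by the stated average
#'     hemodynamic delays (e.g. +0.48/-0.35 s for "offset0.8"), plus
#'     random jitter of variance 0.05 on the transit time.}
#'   \item{"60min"}{as "offset<0.4" but 60 minutes long.}
#'   \item{"8nodes-st", "8nodes-ns"}{stationary / dynamic 8-node network
#'     ([eightNodeTruth()]) with neural lag 0.5 s, TR 2 s.}
#' }
#'
#' Offset presets trigger a one-off transit-time calibration
#' ([calibrateTransitOffsets()]), cached for the session.
#'
#' @param name preset name.
#' @return a [SimulationSpec-class].
#' @export
simPreset <- function(name = c("sim1", "sim22", "offset<0.4",
                               "offset0.4", "offset0.8", "offset1.1",
                               "offset1.4", "offset1.7", "offset1.9",
                               "60min", "8nodes-st", "8nodes-ns")) {
  name <- match.arg(name)
  A5 <- fiveNodeTruth()
  switch(name,
    "sim1" = simulationSpec(A5, dynamic = FALSE, TR = 3,
                            noisePct = 1.0, hrfLagSd = 0.5),
    "sim22" = simulationSpec(A5, dynamic = TRUE, TR = 3,
                             noisePct = 0.1, hrfLagSd = 0.5),
    "offset<0.4" = simulationSpec(A5, dynamic = TRUE, TR = 2,
                                  noisePct = 0.1, hrfLagSd = 0.3),
    "60min" = simulationSpec(A5, dynamic = TRUE, TR = 2, duration = 3600,
                             noisePct = 0.1, hrfLagSd = 0.3),
    "8nodes-st" = simulationSpec(eightNodeTruth(), dynamic = FALSE,
                                 connectionStrength = 0.55,
                                 neuralLag = 0.5, TR = 2,
                                 noisePct = 0.1, hrfLagSd = 0.5),
    "8nodes-ns" = simulationSpec(eightNodeTruth(), dynamic = TRUE,
                                 connectionStrength = 0.55,
                                 neuralLag = 0.5, TR = 2,
                                 noisePct = 0.1, hrfLagSd = 0.5),
    {
      tg <- offsetDelayTargets[[name]]
      delays <- c(tg[1L], tg[2L], 0, tg[1L], tg[2L])
      offs <- calibrateTransitOffsets(delays)
      simulationSpec(A5, dynamic = TRUE, TR = 2, noisePct = 0.1,
                     hrfLagSd = sqrt(0.05), transitTimeOffsets = offs)
    })
}

#' Sensitivity, specificity, accuracy and c-sensitivity of estimates
#'
#' Pools directed-edge decisions over all ordered node pairs (i, j),
#' i != j, across all estimated networks against a fixed ground truth.
#' An estimated edge where the truth has one is a true positive; an
#' estimated edge where the truth lacks one is a false positive even if
#' the reverse edge is true. c-sensitivity is the proportion of true
#' connections detected in either direction, ignoring orientation.
#'
#' @param estimated a [DirectedNetwork-class] / binary matrix, or a list
#'   of them (one per dataset).
#' @param truth ground-truth binary adjacency (or
#'   [DirectedNetwork-class]).
#' @return list with `sensitivity`, `specificity`, `accuracy`,
#'   `cSensitivity` and the pooled counts `TP`, `FP`, `TN`, `FN`.
#' @examples
#' truth <- fiveNodeTruth()
#' evaluateNetworks(truth, truth)$sensitivity  # 1
#' @export
evaluateNetworks <- function(estimated, truth) {
  if (is(truth, "DirectedNetwork")) truth <- adjacency(truth)
  truth <- as.matrix(truth)
  if (!is.list(estimated)) estimated <- list(estimated)
  mats <- lapply(estimated, function(x)
    if (is(x, "DirectedNetwork")) adjacency(x) else as.matrix(x))
  n <- nrow(truth)
  off <- row(truth) != col(truth)
  TP <- FP <- TN <- FN <- 0
  cDet <- 0; cTot <- 0
  truthU <- (truth + t(truth)) > 0
  for (A in mats) {
    if (!identical(dim(A), dim(truth)))
      stop("estimated and truth adjacency sizes disagree")
    TP <- TP + sum(A[off] == 1 & truth[off] == 1)
    FP <- FP + sum(A[off] == 1 & truth[off] == 0)
    TN <- TN + sum(A[off] == 0 & truth[off] == 0)
    FN <- FN + sum(A[off] == 0 & truth[off] == 1)
    estU <- (A + t(A)) > 0
    up <- upper.tri(truth)
    cDet <- cDet + sum(truthU[up] & estU[up])
    cTot <- cTot + sum(truthU[up])
  }
  list(sensitivity = TP / (TP + FN), specificity = TN / (TN + FP),
       accuracy = (TP + TN) / (TP + TN + FP + FN),
       cSensitivity = cDet / cTot, TP = TP, FP = FP, TN = TN, FN = FN)
}
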