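#' @include AllClasses.R utils.R
NULL

#' Construct a synthetic-ensemble specification
#'
#' @param nTrajectories,nFrames ensemble dimensions. Defaults mirror the study
#'   design this package targets: 50 independent trajectories of order
#'   1 microsecond each.
#' @param frameIntervalNs stored-frame interval, ns. The default 0.8 ns makes
#'   160-ns bootstrap blocks and 16-ns tICA lags integer frame counts.
#' @param seed master seed; per-trajectory seeds come from
#'   \code{\link{deriveSeed}}.
#' @param generator generator name.
#' @param params generator-specific parameter list.
#' @return a \linkS4class{SyntheticSpec}.
#' @export
syntheticSpec <- function(nTrajectories = 50L, nFrames = 1000L,
                          frameIntervalNs = 0.8, seed = 1L,
                          generator = "release_system", params = list()) {
  new("SyntheticSpec", nTrajectories = as.integer(nTrajectories),
      nFrames = as.integer(nFrames), frameIntervalNs = frameIntervalNs,
      seed = as.integer(seed), generator = generator, params = params)
}

#' Sample a discrete-state Markov chain
#'
#' @param tpm row-stochastic transition matrix (rows sum to 1 within 1e-9).
#' @param nSteps length of the returned sequence (including the start state).
#' @param startState 0-based start state.
#' @param seed integer seed.
#' @return integer vector of 0-based states, length \code{nSteps}.
#' @examples
#' sampleMarkovChain(matrix(c(0, 1, 1, 0), 2, byrow = TRUE), 6, 0, seed = 1)
#' @export
sampleMarkovChain <- function(tpm, nSteps, startState = 0L, seed) {
  checkStochasticMatrix(tpm, tol = 1e-9)
  nSteps <- as.integer(nSteps)
  if (nSteps < 1L) .stopf("nSteps must be >= 1")
  k <- nrow(tpm)
  if (startState < 0L || startState >= k)
    .stopf("startState must be in [0, %d)", k)
  if (nSteps == 1L) return(as.integer(startState))
  cum <- t(apply(tpm, 1, cumsum))
  if (k == 1L) cum <- matrix(cum, 1)
  set.seed(seed)
  u <- stats::runif(nSteps - 1L)
  chain_steps_cpp(cum, as.integer(startState), u)
}

#' Emit Gaussian features from a hidden state sequence
#'
#' Draws one feature vector per frame from the state's Gaussian emission
#' model. A zero covariance reproduces the state means exactly.
#'
#' @param states integer vector of 0-based hidden states.
#' @param means numeric matrix (nStates x d) or list of per-state mean
#'   vectors.
#' @param covariances list of per-state covariance matrices (symmetric
#'   positive semi-definite), or a single matrix shared by all states.
#' @param seed integer seed.
#' @return numeric matrix (length(states) x d).
#' @export
emitGaussianFeatures <- function(states, means, covariances, seed) {
  if (is.list(means)) means <- do.call(rbind, means)
  means <- as.matrix(means)
  nStates <- nrow(means)
  d <- ncol(means)
  if (is.matrix(covariances)) covariances <- rep(list(covariances), nStates)
  if (length(covariances) != nStates)
    .stopf("need one covariance per state (%d states, %d covariances)",
           nStates, length(covariances))
  roots <- lapply(seq_len(nStates), function(s) {
    cv <- as.matrix(covariances[[s]])
    if (!isTRUE(all.equal(cv, t(cv), tolerance = 1e-8)))
      .stopf("covariance for state %d is not symmetric", s - 1L)
    e <- eigen((cv + t(cv)) / 2, symmetric = TRUE)
    if (min(e$values) < -1e-8 * max(abs(e$values), 1))
      .stopf("covariance for state %d is not positive semi-definite", s - 1L)
    e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
  })
  if (min(states) < 0L || max(states) >= nStates)
    .stopf("states must be 0-based indices into the emission model")
  n <- length(states)
  set.seed(seed)
  z <- matrix(stats::rnorm(n * d), n, d)
  out <- matrix(0, n, d)
  for (s in seq_len(nStates)) {
    idx <- which(states == s - 1L)
    if (!length(idx)) next
    out[idx, ] <- z[idx, , drop = FALSE] %*% roots[[s]] +
      matrix(means[s, ], length(idx), d, byrow = TRUE)
  }
  out
}

#' Overdamped Langevin dynamics in a well potential
#'
#' Euler--Maruyama integration of
#' \eqn{dx = -\nabla U(x)/\gamma\,dt + \sqrt{2 k_B T dt/\gamma}\,\xi}. The
#' long-run histogram is Boltzmann, \eqn{p(x) \propto e^{-U(x)/k_B T}}.
#'
#' @param potential list describing the potential and bath:
#'   \code{type = "harmonic"} with \code{k} (kcal/mol/A^2) and \code{center},
#'   or \code{type = "double_well"} with \code{height} (barrier, kcal/mol),
#'   \code{halfSeparation} (minima at +/- this, A) and optional \code{kPerp}
#'   for extra dimensions; plus \code{kT} (kcal/mol) and friction
#'   \code{gamma}.
#' @param nSteps number of frames returned (including the start).
#' @param dt integration time step. For multi-well potentials the per-step
#'   noise displacement must stay below 0.2 x the minimum well separation;
#'   otherwise an error reports the largest admissible \code{dt}.
#' @param seed integer seed.
#' @param x0 start position (default: well centre).
#' @return numeric matrix (nSteps x d).
#' @export
brownianWells <- function(potential, nSteps, dt, seed, x0 = NULL) {
  type <- match.arg(potential$type, c("harmonic", "double_well"))
  kT <- potential$kT
  gamma <- potential$gamma
  if (is.null(kT) || kT < 0) .stopf("potential$kT must be >= 0")
  if (is.null(gamma) || gamma <= 0) .stopf("potential$gamma must be > 0")
  if (type == "harmonic") {
    center <- potential$center
    if (is.null(center)) center <- 0
    d <- length(center)
    par <- c(potential$k, center)
    potType <- 0L
    if (is.null(x0)) x0 <- center
  } else {
    a <- potential$halfSeparation
    kPerp <- if (is.null(potential$kPerp)) 1 else potential$kPerp
    d <- if (is.null(potential$ndim)) 1L else as.integer(potential$ndim)
    par <- c(potential$height, a, kPerp)
    potType <- 1L
    if (is.null(x0)) x0 <- c(-a, numeric(d - 1L))
    sep <- 2 * a
    stepSd <- sqrt(2 * kT * dt / gamma)
    if (stepSd >= 0.2 * sep) {
      dtMax <- (0.2 * sep)^2 * gamma / (2 * kT)
      .stopf(paste("unstable dt: per-step displacement sd %.3g >= 0.2 x well",
                   "separation %.3g; use dt < %.3g"), stepSd, sep, dtMax)
    }
  }
  nSteps <- as.integer(nSteps)
  if (nSteps < 1L) .stopf("nSteps must be >= 1")
  set.seed(seed)
  noise <- matrix(stats::rnorm((nSteps - 1L) * d), nSteps - 1L, d)
  em_langevin_cpp(as.numeric(x0), noise, dt, gamma, kT, potType, par)
}

#' Scheduled bead-model structure ensemble
#'
#' Wraps exactly-scheduled coordinates and an atom table into a
#' \linkS4class{StructureEnsemble}; no randomness. Duplicate
#' (segment, resid, atom) triples are rejected.
#'
#' @param atoms data.frame with columns \code{atom}, \code{element},
#'   \code{resname}, \code{resid}, \code{segment}.
#' @param coords one frames x atoms x 3 array, or a list of them (one per
#'   trajectory).
#' @param frameIntervalNs frame interval, ns.
#' @return a \linkS4class{StructureEnsemble}.
#' @export
beadFrames <- function(atoms, coords, frameIntervalNs = 0.8) {
  if (!is.list(coords) || is.array(coords)) coords <- list(coords)
  new("StructureEnsemble", coords = coords,
      topology = new("Topology", atoms = as.data.frame(atoms)),
      frameIntervalNs = frameIntervalNs)
}

# default parameters of the ion-release generator; rates are per frame
.releaseDefaults <- function() {
  list(
    kOff = 0.004,        # bound -> released
    kOn = 0.0004,        # released -> bound
    boundMeanA = 3.0, boundSdA = 0.3,
    releasedMeanA = 12.0, releasedSdA = 1.0,
    gates = list(
      list(name = "R60-D436", partners = c("R60", "D436"),
           pOpen = 0.02, pClose = 0.02),
      list(name = "E428-R445", partners = c("E428", "R445"),
           pOpen = 0.01, pClose = 0.03),
      list(name = "K66-D345", partners = c("K66", "D345"),
           pOpen = 0.03, pClose = 0.01)),
    gateClosedMeanA = 4.0, gateClosedSdA = 0.25,
    gateOpenMeanA = 9.5, gateOpenSdA = 0.5,
    includeStructures = TRUE)  # FALSE skips bead coordinates (features only)
}

# bead table used by the release generator: a 57-residue N-terminal tail with
# a few charged beads, the six gate partner residues, and two sodium beads
.releaseAtoms <- function() {
  headAtom <- c(LYS = "NZ", ARG = "CZ", GLU = "CD", ASP = "CG")
  ntRes <- sprintf("GLY")
  resnames <- rep("GLY", 57)
  resnames[c(3, 5)] <- "LYS"      # distal charged beads
  resnames[c(27, 35)] <- "ARG"    # proximal charged beads
  resnames[c(44)] <- "GLU"
  nt <- data.frame(
    atom = ifelse(resnames == "GLY", "CA", headAtom[resnames]),
    element = ifelse(resnames == "GLY", "C",
                     substr(ifelse(resnames == "LYS", "N", "C"), 1, 1)),
    resname = resnames, resid = 1:57, segment = "NTERM",
    stringsAsFactors = FALSE)
  core <- data.frame(
    atom = c("CZ", "NZ", "CG", "CD", "CG", "CZ"),
    element = c("C", "N", "C", "C", "C", "C"),
    resname = c("ARG", "LYS", "ASP", "GLU", "ASP", "ARG"),
    resid = c(60L, 66L, 345L, 428L, 436L, 445L),
    segment = "CORE", stringsAsFactors = FALSE)
  ion <- data.frame(
    atom = c("NA", "NA"), element = c("NA", "NA"),
    resname = c("SOD", "SOD"), resid = c(901L, 902L),
    segment = "ION", stringsAsFactors = FALSE)
  rbind(nt, core, ion)
}

#' Generate a synthetic ion-release trajectory ensemble
#'
#' Emulates the statistical structure of an ensemble-MD study of sodium
#' release: each trajectory carries (a) an ion-distance coordinate hopping
#' from a bound basin to a released basin, driven by a hidden two-state
#' Markov chain with known rates, (b) three gate-distance coordinates with
#' independent two-state open/close dynamics at known rates, and (c) a
#' labelled bead-model structural trajectory whose head-group-atom distances
#' reproduce the gate and ion coordinates exactly. The returned ground truth
#' records the hidden chain, its analytic mean first-passage time
#' (1/kOff frames) and relaxation time, per-frame basin labels, and the
#' release-labelling convention (midpoint threshold, 5-frame debounce).
#'
#' @param spec a \linkS4class{SyntheticSpec} with
#'   \code{generator = "release_system"}; entries of \code{spec@params}
#'   override the documented defaults.
#' @return list with elements \code{structures}
#'   (\linkS4class{StructureEnsemble}), \code{features}
#'   (\linkS4class{FeatureEnsemble}: ion distance + three gate distances),
#'   \code{groundTruth} (\linkS4class{GroundTruth}) and \code{spec}.
#' @export
releaseSystem <- function(spec) {
  if (spec@generator != "release_system")
    .stopf("spec generator is '%s', expected 'release_system'", spec@generator)
  p <- utils::modifyList(.releaseDefaults(), spec@params)
  # gates is an unnamed list, which modifyList cannot merge element-wise;
  # a caller-supplied gates list replaces the default wholesale
  if (!is.null(spec@params$gates)) p$gates <- spec@params$gates
  nT <- spec@nTrajectories
  nF <- spec@nFrames
  ionTPM <- matrix(c(1 - p$kOff, p$kOff, p$kOn, 1 - p$kOn), 2, byrow = TRUE)
  nGates <- length(p$gates)
  atoms <- .releaseAtoms()
  nAtoms <- nrow(atoms)
  baseCoords <- matrix(0, nAtoms, 3)
  # static N-terminal tail laid out along x, spaced 10 A apart
  ntIdx <- which(atoms$segment == "NTERM")
  baseCoords[ntIdx, 1] <- 10 * atoms$resid[ntIdx]
  baseCoords[ntIdx, 2] <- 1000
  coreIdx <- which(atoms$segment == "CORE")
  ionIdx <- which(atoms$segment == "ION")

  featNames <- c("na2_distance", vapply(p$gates, `[[`, "", "name"))
  coords <- vector("list", nT)
  feats <- vector("list", nT)
  labels <- vector("list", nT)

  for (tr in seq_len(nT)) {
    sIon <- sampleMarkovChain(ionTPM, nF, startState = 0L,
                              seed = deriveSeed(spec@seed, tr))
    dIon <- drop(emitGaussianFeatures(
      sIon, means = rbind(p$boundMeanA, p$releasedMeanA),
      covariances = list(matrix(p$boundSdA^2), matrix(p$releasedSdA^2)),
      seed = deriveSeed(spec@seed, nT + tr)))
    dIon <- pmax(dIon, 0.1)
    gateD <- matrix(0, nF, nGates)
    for (g in seq_len(nGates)) {
      gp <- p$gates[[g]]
      gTPM <- matrix(c(1 - gp$pOpen, gp$pOpen, gp$pClose, 1 - gp$pClose),
                     2, byrow = TRUE)
      # start from the stationary distribution so open fractions are unbiased
      pOpenStat <- gp$pOpen / (gp$pOpen + gp$pClose)
      startSeed <- deriveSeed(spec@seed, (2 + 2 * g) * nT + tr)
      set.seed(startSeed)
      start <- as.integer(stats::runif(1) < pOpenStat)
      sg <- sampleMarkovChain(gTPM, nF, startState = start, seed = startSeed)
      gateD[, g] <- pmax(drop(emitGaussianFeatures(
        sg, means = rbind(p$gateClosedMeanA, p$gateOpenMeanA),
        covariances = list(matrix(p$gateClosedSdA^2),
                           matrix(p$gateOpenSdA^2)),
        seed = deriveSeed(spec@seed, (3 + 2 * g) * nT + tr))), 0.1)
    }
    if (isTRUE(p$includeStructures)) {
      # bead coordinates: one fixed partner per gate, the other displaced
      # along x by the scheduled distance; pairs are spaced far apart in y
      tc <- array(rep(baseCoords, each = nF), dim = c(nF, nAtoms, 3))
      for (g in seq_len(nGates)) {
        partners <- p$gates[[g]]$partners
        resids <- as.integer(sub("^[A-Z]+", "", partners))
        iA <- coreIdx[match(resids[1], atoms$resid[coreIdx])]
        iB <- coreIdx[match(resids[2], atoms$resid[coreIdx])]
        tc[, iA, 2] <- 200 * g
        tc[, iB, 2] <- 200 * g
        tc[, iB, 1] <- gateD[, g]
      }
      tc[, ionIdx[1], 2] <- -100          # Na1-site reference bead, fixed
      tc[, ionIdx[2], 2] <- -100
      tc[, ionIdx[2], 1] <- dIon          # Na+/Na2 bead
      coords[[tr]] <- tc
    }
    feats[[tr]] <- cbind(dIon, gateD)
    colnames(feats[[tr]]) <- featNames
    labels[[tr]] <- sIon
  }

  threshold <- (p$boundMeanA + p$releasedMeanA) / 2
  gt <- new("GroundTruth", trueTPM = ionTPM,
            trueSlowMode = c(1, -1),
            trueMFPTFrames = 1 / p$kOff,
            stateLabels = labels,
            metadata = list(
              releaseThresholdA = threshold,
              dwellFrames = 5L,
              trueRelaxationFrames = -1 / log(1 - p$kOff - p$kOn),
              mfptRelaxationFrames = 1 / (p$kOff + p$kOn),
              gateOpenProb = vapply(p$gates, function(g)
                g$pOpen / (g$pOpen + g$pClose), numeric(1))))
  structures <- if (isTRUE(p$includeStructures))
    new("StructureEnsemble", coords = coords,
        topology = new("Topology", atoms = atoms),
        frameIntervalNs = spec@frameIntervalNs)
  list(structures = structures,
       features = new("FeatureEnsemble", trajs = feats,
                      featureNames = featNames,
                      frameIntervalNs = spec@frameIntervalNs),
       groundTruth = gt, spec = spec)
}
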