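#' @import methods
NULL

#' Topology of a bead/atom model
#'
#' Ordered atom records shared by every trajectory of a
#' \linkS4class{StructureEnsemble}. Each record carries an atom name, element,
#' residue name, 1-based residue id and a segment label. The triple
#' (segment, resid, atom) must be unique and residue ids must be
#' non-decreasing within a segment.
#'
#' @slot atoms data.frame with columns \code{atom}, \code{element},
#'   \code{resname}, \code{resid}, \code{segment}.
#' @export
setClass("Topology", representation(atoms = "data.frame"))

setValidity("Topology", function(object) {
  at <- object@atoms
  need <- c("atom", "element", "resname", "resid", "segment")
  if (!all(need %in% names(at)))
    return(paste("topology must have columns:", paste(need, collapse = ", ")))
  key <- paste(at$segment, at$resid, at$atom)
  if (anyDuplicated(key))
    return(sprintf("duplicate (segment, resid, atom) triple: %s",
                   key[anyDuplicated(key)]))
  for (seg in unique(at$segment)) {
    r <- at$resid[at$segment == seg]
    if (is.unsorted(r))
      return(sprintf("residue ids in segment '%s' are not non-decreasing", seg))
  }
  TRUE
})

#' Ensemble of labelled coordinate trajectories
#'
#' A list of coordinate blocks (frames x atoms x 3, in Angstrom) sharing one
#' \linkS4class{Topology} and a common frame interval in nanoseconds.
#'
#' @slot coords list of 3-d numeric arrays, one per trajectory.
#' @slot topology a \linkS4class{Topology}.
#' @slot frameIntervalNs positive numeric, time between stored frames (ns).
#' @export
setClass("StructureEnsemble",
         representation(coords = "list", topology = "Topology",
                        frameIntervalNs = "numeric"))

setValidity("StructureEnsemble", function(object) {
  na <- nrow(object@topology@atoms)
  if (length(object@frameIntervalNs) != 1 || object@frameIntervalNs <= 0)
    return("frameIntervalNs must be a single positive number")
  for (i in seq_along(object@coords)) {
    x <- object@coords[[i]]
    if (!is.array(x) || length(dim(x)) != 3 || dim(x)[3] != 3)
      return(sprintf("trajectory %d is not a frames x atoms x 3 array", i))
    if (dim(x)[2] != na)
      return(sprintf("trajectory %d has %d atoms, topology has %d",
                     i, dim(x)[2], na))
    if (!all(is.finite(x)))
      return(sprintf("trajectory %d contains non-finite coordinates", i))
  }
  TRUE
})

#' Ensemble of feature trajectories
#'
#' Real-valued time-series matrices (frames x features) sharing feature names
#' and a frame interval; the input container for tICA and everything
#' downstream of it.
#'
#' @slot trajs list of numeric matrices, one per trajectory.
#' @slot featureNames character vector, one name per column.
#' @slot frameIntervalNs positive numeric (ns).
#' @export
setClass("FeatureEnsemble",
         representation(trajs = "list", featureNames = "character",
                        frameIntervalNs = "numeric"))

setValidity("FeatureEnsemble", function(object) {
  nf <- length(object@featureNames)
  if (length(object@frameIntervalNs) != 1 || object@frameIntervalNs <= 0)
    return("frameIntervalNs must be a single positive number")
  for (i in seq_along(object@trajs)) {
    x <- object@trajs[[i]]
    if (!is.matrix(x) || ncol(x) != nf)
      return(sprintf("trajectory %d has %d features, expected %d",
                     i, NCOL(x), nf))
    if (!all(is.finite(x)))
      return(sprintf("trajectory %d contains non-finite values", i))
  }
  TRUE
})

#' Specification of a synthetic trajectory ensemble
#'
#' Fully determines a generated ensemble: identical spec and seed reproduce
#' identical output bit for bit.
#'
#' @slot nTrajectories positive integer.
#' @slot nFrames positive integer (>= 2).
#' @slot frameIntervalNs positive numeric (ns).
#' @slot seed integer master seed; per-trajectory seeds are derived with
#'   \code{\link{deriveSeed}}.
#' @slot generator one of \code{"markov_chain"}, \code{"gaussian_hmm"},
#'   \code{"brownian_wells"}, \code{"release_system"}, \code{"bead_frames"}.
#' @slot params generator-specific parameter list.
#' @export
setClass("SyntheticSpec",
         representation(nTrajectories = "integer", nFrames = "integer",
                        frameIntervalNs = "numeric", seed = "integer",
                        generator = "character", params = "list"))

setValidity("SyntheticSpec", function(object) {
  gens <- c("markov_chain", "gaussian_hmm", "brownian_wells",
            "release_system", "bead_frames")
  if (object@nTrajectories < 1L) return("nTrajectories must be >= 1")
  if (object@nFrames < 2L) return("nFrames must be >= 2")
  if (object@frameIntervalNs <= 0) return("frameIntervalNs must be > 0")
  if (!(object@generator %in% gens))
    return(paste("generator must be one of:", paste(gens, collapse = ", ")))
  TRUE
})

#' Ground truth attached to a synthetic ensemble
#'
#' Records whatever is analytically known about a generated ensemble so that
#' downstream estimators can be scored against it.
#'
#' @slot trueTPM row-stochastic matrix of the hidden chain, or NULL.
#' @slot trueSlowMode numeric vector, or NULL.
#' @slot trueMFPTFrames positive numeric, mean first-passage time in frames,
#'   or NA.
#' @slot stateLabels list of per-trajectory integer state sequences (0-based),
#'   indexing rows of \code{trueTPM}; may be empty.
#' @slot metadata list of generator-declared conventions (release threshold,
#'   debounce frames, analytic relaxation time, ...).
#' @export
setClass("GroundTruth",
         representation(trueTPM = "ANY", trueSlowMode = "ANY",
                        trueMFPTFrames = "numeric", stateLabels = "list",
                        metadata = "list"))

setValidity("GroundTruth", function(object) {
  if (!is.null(object@trueTPM)) {
    rs <- rowSums(object@trueTPM)
    if (any(abs(rs - 1) > 1e-12))
      return("trueTPM rows must sum to 1 within 1e-12")
    ns <- nrow(object@trueTPM)
    for (lab in object@stateLabels)
      if (length(lab) && (min(lab) < 0 || max(lab) >= ns))
        return("state labels must index rows of trueTPM (0-based)")
  }
  TRUE
})

#' Distance time series for a named residue pair
#'
#' @slot name label of the pair (e.g. \code{"R60-D436"}).
#' @slot series list of per-trajectory numeric distance vectors (Angstrom).
#' @slot thresholdA numeric; distances above it count as "broken".
#' @slot frameIntervalNs positive numeric (ns).
#' @export
setClass("GateSeries",
         representation(name = "character", series = "list",
                        thresholdA = "numeric", frameIntervalNs = "numeric"))

#' Residue-residue minimum-distance map
#'
#' Entry (i, j) is the minimum over all frames, trajectories and heavy-atom
#' pairs of the distance between residue i of the query set and residue j of
#' the target set ("closest-heavy" convention). Self pairs are excluded and
#' reported as NA.
#'
#' @slot map numeric matrix (Angstrom) with residue-key dimnames.
#' @slot queryKeys,targetKeys character residue keys ("SEG:resid").
#' @export
setClass("ContactMap",
         representation(map = "matrix", queryKeys = "character",
                        targetKeys = "character"))

setValidity("ContactMap", function(object) {
  if (any(object@map < 0, na.rm = TRUE)) return("distances must be >= 0")
  TRUE
})

#' Population free-energy profile
#'
#' Per-bin \eqn{\Delta G = -RT \ln(\mathrm{population})} in kcal/mol, shifted
#' so the minimum over occupied bins is 0, with a per-bin block-bootstrap
#' standard error. Empty bins are flagged, not assigned a finite value.
#'
#' @slot breaks list of bin-edge vectors (length 1 for 1-d, 2 for 2-d).
#' @slot mids list of bin-centre vectors.
#' @slot dG numeric vector (1-d) or matrix (2-d), NA on empty bins.
#' @slot error bootstrap standard error, same shape as \code{dG}.
#' @slot empty logical, same shape, TRUE where no counts fell.
#' @slot temperatureK numeric temperature (K).
#' @export
setClass("FreeEnergyProfile",
         representation(breaks = "list", mids = "list", dG = "ANY",
                        error = "ANY", empty = "ANY", temperatureK = "numeric"))

setValidity("FreeEnergyProfile", function(object) {
  g <- object@dG[!object@empty]
  if (length(g) && abs(min(g)) > 1e-9)
    return("minimum of dG over occupied bins must be 0")
  TRUE
})

#' Fitted tICA transform
#'
#' Solution of the generalized eigenproblem \eqn{C_{TL} V = C V \Lambda} on
#' mean-free features, with the time-lagged covariance symmetrized and
#' \eqn{C} ridge-regularized. Eigenvectors are C-orthonormal, sorted by
#' descending eigenvalue, sign-fixed so each vector's largest-magnitude
#' component is positive.
#'
#' @slot mean numeric feature mean.
#' @slot cov,covLagged covariance and symmetrized time-lagged covariance
#'   matrices.
#' @slot lagNs numeric lag (ns).
#' @slot eigenvalues numeric, descending.
#' @slot eigenvectors numeric matrix (columns).
#' @slot regEpsilon numeric ridge added to C.
#' @slot featureNames character.
#' @export
setClass("TicaModel",
         representation(mean = "numeric", cov = "matrix",
                        covLagged = "matrix", lagNs = "numeric",
                        eigenvalues = "numeric", eigenvectors = "matrix",
                        regEpsilon = "numeric", featureNames = "character"))

setValidity("TicaModel", function(object) {
  if (is.unsorted(rev(object@eigenvalues), strictly = FALSE))
    return("eigenvalues must be sorted in descending order")
  TRUE
})

#' Discretized trajectories in reduced space
#'
#' @slot dtrajs list of per-trajectory integer vectors with states in
#'   [0, nStates).
#' @slot nStates integer number of microstates.
#' @slot centers numeric matrix (nStates x d) of cluster centres.
#' @slot frameIntervalNs positive numeric (ns).
#' @export
setClass("DiscreteTrajectories",
         representation(dtrajs = "list", nStates = "integer",
                        centers = "matrix", frameIntervalNs = "numeric"))

setValidity("DiscreteTrajectories", function(object) {
  for (i in seq_along(object@dtrajs)) {
    d <- object@dtrajs[[i]]
    if (length(d) && (min(d) < 0L || max(d) >= object@nStates))
      return(sprintf("trajectory %d has states outside [0, %d)",
                     i, object@nStates))
  }
  TRUE
})

#' Estimated Markov state model
#'
#' Row-normalized transition probability matrix on the largest strongly
#' connected (active) state set, with its spectral decomposition and
#' stationary distribution.
#'
#' @slot lagNs numeric lag time (ns).
#' @slot counts full transition count matrix (all states).
#' @slot tpm row-stochastic matrix on the active set.
#' @slot eigenvalues complex, sorted by descending modulus.
#' @slot rightVectors,leftVectors complex matrices, columns matching
#'   \code{eigenvalues}.
#' @slot pi numeric stationary distribution on the active set.
#' @slot activeSet integer original (0-based) state ids of active states.
#' @slot frameIntervalNs positive numeric (ns).
#' @export
setClass("MarkovModel",
         representation(lagNs = "numeric", counts = "matrix", tpm = "matrix",
                        eigenvalues = "complex", rightVectors = "matrix",
                        leftVectors = "matrix", pi = "numeric",
                        activeSet = "integer", frameIntervalNs = "numeric"))

setValidity("MarkovModel", function(object) {
  rs <- rowSums(object@tpm)
  if (any(abs(rs - 1) > 1e-12)) return("TPM rows must sum to 1 within 1e-12")
  if (abs(Mod(object@eigenvalues[1]) - 1) > 1e-9)
    return("leading eigenvalue must be 1 within 1e-9")
  if (any(object@pi < -1e-12)) return("stationary distribution must be >= 0")
  if (abs(sum(object@pi) - 1) > 1e-9)
    return("stationary distribution must sum to 1")
  resid <- max(abs(drop(object@pi %*% object@tpm) - object@pi))
  if (resid > 1e-9)
    return(sprintf("pi' TPM = pi' violated (residual %.3g)", resid))
  TRUE
})

#' PCCA+ macrostate lumping of a Markov model
#'
#' @slot membership integer vector: macrostate (1-based) per active
#'   microstate.
#' @slot memberships numeric fuzzy membership matrix (micro x macro), rows
#'   summing to 1.
#' @slot nMacrostates integer.
#' @slot tpm macrostate transition matrix (pi-weighted aggregation).
#' @slot pi macrostate stationary distribution.
#' @slot microActiveSet integer 0-based original microstate ids.
#' @export
setClass("MacroModel",
         representation(membership = "integer", memberships = "matrix",
                        nMacrostates = "integer", tpm = "matrix",
                        pi = "numeric", microActiveSet = "integer"))

setValidity("MacroModel", function(object) {
  if (length(object@membership) != nrow(object@memberships))
    return("membership length must match memberships rows")
  if (abs(sum(object@pi) - 1) > 1e-9) return("macro pi must sum to 1")
  if (!all(object@membership %in% seq_len(object@nMacrostates)))
    return("crisp membership must cover 1..nMacrostates indices")
  TRUE
})

#' Reactive flux network between a source and a sink set
#'
#' Committors and gross/net transition-path-theory fluxes of a Markov model
#' between disjoint source (A) and sink (B) state sets.
#'
#' @slot A,B integer state indices (1-based, within the model's state space).
#' @slot qplus,qminus forward and backward committors.
#' @slot gross,net flux matrices; \code{net = max(0, gross - t(gross))}.
#' @slot totalFlux numeric total A to B net flux per lag time.
#' @slot pi,tpm stationary distribution and TPM the network was built from.
#' @export
setClass("FluxNetwork",
         representation(A = "integer", B = "integer", qplus = "numeric",
                        qminus = "numeric", gross = "matrix", net = "matrix",
                        totalFlux = "numeric", pi = "numeric", tpm = "matrix"))

setValidity("FluxNetwork", function(object) {
  q <- object@qplus
  if (any(abs(q[object@A]) > 1e-12)) return("q+ must be 0 on A")
  if (any(abs(q[object@B] - 1) > 1e-12)) return("q+ must be 1 on B")
  if (any(q < -1e-9 | q > 1 + 1e-9)) return("q+ must lie in [0, 1]")
  if (object@totalFlux < -1e-15) return("total flux must be >= 0")
  inter <- setdiff(seq_along(q), c(object@A, object@B))
  if (length(inter)) {
    imbalance <- rowSums(object@net)[inter] - colSums(object@net)[inter]
    if (max(abs(imbalance)) > 1e-9)
      return(sprintf("net flux not conserved at intermediate states (max %.3g)",
                     max(abs(imbalance))))
  }
  TRUE
})

#' Ranked pathway decomposition of a flux network
#'
#' Pathways extracted by iterative bottleneck (widest-path) decomposition of
#' the net flux graph, each with the flux it carries and its fraction of the
#' total A to B flux.
#'
#' @slot paths list of integer state sequences (A state ... B state).
#' @slot table data.frame with columns \code{pathway}, \code{flux},
#'   \code{fraction}, \code{cumulative}.
#' @slot totalFlux numeric.
#' @export
setClass("PathwayDecomposition",
         representation(paths = "list", table = "data.frame",
                        totalFlux = "numeric"))

setValidity("PathwayDecomposition", function(object) {
  fr <- object@table$fraction
  if (length(fr)) {
    if (any(fr < -1e-12 | fr > 1 + 1e-9)) return("fractions must be in [0, 1]")
    if (is.unsorted(rev(fr), strictly = FALSE) && any(diff(fr) > 1e-12))
      return("pathway fractions must be non-increasing")
    if (max(object@table$cumulative) > 1 + 1e-9)
      return("cumulative fraction must not exceed 1")
  }
  TRUE
})

#' Results bundle of a pipeline run
#'
#' @slot results named list of stage outputs.
#' @slot config the validated configuration the run used.
#' @slot provenance list: config hash, seeds, package version.
#' @export
setClass("ReportBundle",
         representation(results = "list", config = "list",
                        provenance = "list"))
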