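#' @include AllClasses.R
NULL

#' Number of trajectories in an ensemble
#' @param x a StructureEnsemble or FeatureEnsemble.
#' @return integer.
#' @export
setGeneric("nTrajectories", function(x) standardGeneric("nTrajectories"))

#' Per-trajectory frame counts
#' @param x a StructureEnsemble, FeatureEnsemble or DiscreteTrajectories.
#' @return integer vector.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Frame interval in nanoseconds
#' @param x an ensemble-like object.
#' @return numeric.
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))

#' Trajectory list of an ensemble
#' @param x a StructureEnsemble (coordinate arrays) or FeatureEnsemble
#'   (matrices).
#' @return list.
#' @export
setGeneric("trajectories", function(x) standardGeneric("trajectories"))

#' Topology of a structure ensemble
#' @param x a StructureEnsemble or Topology.
#' @return data.frame of atom records.
#' @export
setGeneric("topology", function(x) standardGeneric("topology"))

#' Feature names of a feature ensemble or tICA model
#' @param x the object.
#' @return character vector.
#' @export
setGeneric("featureNames", function(x) standardGeneric("featureNames"))

#' Transition probability matrix of a kinetic model
#' @param x a MarkovModel or MacroModel.
#' @return row-stochastic numeric matrix.
#' @export
setGeneric("transitionProbabilities",
           function(x) standardGeneric("transitionProbabilities"))

#' Stationary distribution of a kinetic model
#' @param x a MarkovModel or MacroModel.
#' @return numeric vector summing to 1.
#' @export
setGeneric("stationaryDistribution",
           function(x) standardGeneric("stationaryDistribution"))

#' Forward and backward committors between source and sink sets
#'
#' @param model a \linkS4class{MarkovModel} or \linkS4class{MacroModel}.
#' @param A,B disjoint non-empty integer sets of 1-based state indices within
#'   the model's (active) state space.
#' @return list with elements \code{qplus} and \code{qminus}.
#' @export
setGeneric("committors", function(model, A, B) standardGeneric("committors"))

#' Transition-path-theory flux network between source and sink sets
#'
#' Gross flux \eqn{f_{ij} = \pi_i q^-_i T_{ij} q^+_j} (i != j), net flux
#' \eqn{f^+_{ij} = \max(0, f_{ij} - f_{ji})}, and the total A to B flux.
#'
#' @inheritParams committors
#' @return a \linkS4class{FluxNetwork}.
#' @export
setGeneric("fluxNetwork", function(model, A, B) standardGeneric("fluxNetwork"))

# ---- accessors -------------------------------------------------------------

#' @describeIn nTrajectories structure ensembles
setMethod("nTrajectories", "StructureEnsemble",
          function(x) length(x@coords))
#' @describeIn nTrajectories feature ensembles
setMethod("nTrajectories", "FeatureEnsemble", function(x) length(x@trajs))

#' @describeIn nFrames structure ensembles
setMethod("nFrames", "StructureEnsemble",
          function(x) vapply(x@coords, function(a) dim(a)[1], integer(1)))
#' @describeIn nFrames feature ensembles
setMethod("nFrames", "FeatureEnsemble",
          function(x) vapply(x@trajs, nrow, integer(1)))
#' @describeIn nFrames discrete trajectories
setMethod("nFrames", "DiscreteTrajectories",
          function(x) lengths(x@dtrajs))

#' @describeIn frameInterval structure ensembles
setMethod("frameInterval", "StructureEnsemble", function(x) x@frameIntervalNs)
#' @describeIn frameInterval feature ensembles
setMethod("frameInterval", "FeatureEnsemble", function(x) x@frameIntervalNs)
#' @describeIn frameInterval discrete trajectories
setMethod("frameInterval", "DiscreteTrajectories",
          function(x) x@frameIntervalNs)
#' @describeIn frameInterval gate series
setMethod("frameInterval", "GateSeries", function(x) x@frameIntervalNs)

#' @describeIn trajectories structure ensembles
setMethod("trajectories", "StructureEnsemble", function(x) x@coords)
#' @describeIn trajectories feature ensembles
setMethod("trajectories", "FeatureEnsemble", function(x) x@trajs)

#' @describeIn topology structure ensembles
setMethod("topology", "StructureEnsemble", function(x) x@topology@atoms)
#' @describeIn topology topologies
setMethod("topology", "Topology", function(x) x@atoms)

#' @describeIn featureNames feature ensembles
setMethod("featureNames", "FeatureEnsemble", function(x) x@featureNames)
#' @describeIn featureNames tICA models
setMethod("featureNames", "TicaModel", function(x) x@featureNames)

#' @describeIn transitionProbabilities microstate models
setMethod("transitionProbabilities", "MarkovModel", function(x) x@tpm)
#' @describeIn transitionProbabilities macrostate models
setMethod("transitionProbabilities", "MacroModel", function(x) x@tpm)

#' @describeIn stationaryDistribution microstate models
setMethod("stationaryDistribution", "MarkovModel", function(x) x@pi)
#' @describeIn stationaryDistribution macrostate models
setMethod("stationaryDistribution", "MacroModel", function(x) x@pi)

# ---- show methods ----------------------------------------------------------

setMethod("show", "StructureEnsemble", function(object) {
  nf <- nFrames(object)
  cat(sprintf("StructureEnsemble: %d trajectories, %d atoms, %s frames, dt = %g ns\n",
              nTrajectories(object), nrow(object@topology@atoms),
              paste(range(nf), collapse = "-"), object@frameIntervalNs))
})

setMethod("show", "FeatureEnsemble", function(object) {
  nf <- nFrames(object)
  cat(sprintf("FeatureEnsemble: %d trajectories, %d features (%s), %s frames, dt = %g ns\n",
              nTrajectories(object), length(object@featureNames),
              paste(utils::head(object@featureNames, 4), collapse = ", "),
              paste(range(nf), collapse = "-"), object@frameIntervalNs))
})

setMethod("show", "TicaModel", function(object) {
  cat(sprintf("TicaModel: %d features, lag %g ns\n  top eigenvalues: %s\n",
              length(object@mean), object@lagNs,
              paste(signif(utils::head(object@eigenvalues, 4), 4),
                    collapse = ", ")))
})

setMethod("show", "MarkovModel", function(object) {
  ev <- Mod(object@eigenvalues)
  cat(sprintf("MarkovModel: %d active states, lag %g ns\n  |eigenvalues|: %s\n",
              nrow(object@tpm), object@lagNs,
              paste(signif(utils::head(ev, 5), 4), collapse = ", ")))
})

setMethod("show", "MacroModel", function(object) {
  cat(sprintf("MacroModel: %d macrostates over %d microstates\n  macro pi: %s\n",
              object@nMacrostates, length(object@membership),
              paste(signif(object@pi, 3), collapse = ", ")))
})

setMethod("show", "FluxNetwork", function(object) {
  cat(sprintf("FluxNetwork: |A| = %d, |B| = %d, total flux = %.6g per lag\n",
              length(object@A), length(object@B), object@totalFlux))
})

setMethod("show", "PathwayDecomposition", function(object) {
  cat(sprintf("PathwayDecomposition: %d pathways, cumulative fraction %.3f\n",
              nrow(object@table),
              if (nrow(object@table)) max(object@table$cumulative) else 0))
  if (nrow(object@table)) print(utils::head(object@table, 10))
})

setMethod("show", "GateSeries", function(object) {
  cat(sprintf("GateSeries '%s': %d trajectories, threshold %g A\n",
              object@name, length(object@series), object@thresholdA))
})

setMethod("show", "FreeEnergyProfile", function(object) {
  cat(sprintf("FreeEnergyProfile: %s bins, T = %g K, %d empty\n",
              paste(lengths(object@mids), collapse = " x "),
              object@temperatureK, sum(object@empty)))
})

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf("SyntheticSpec: generator '%s', %d x %d frames, dt = %g ns, seed %d\n",
              object@generator, object@nTrajectories, object@nFrames,
              object@frameIntervalNs, object@seed))
})

setMethod("show", "ReportBundle", function(object) {
  cat(sprintf("ReportBundle with stages: %s\n",
              paste(names(object@results), collapse = ", ")))
})
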