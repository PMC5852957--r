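#' @include AllClasses.R utils.R
NULL

#' Estimate instantaneous and time-lagged covariance matrices
#'
#' The mean and covariance pool every frame of every usable trajectory; the
#' time-lagged covariance pools frame pairs (t, t + lag) within trajectories
#' only, never across trajectory boundaries, and is symmetrized as
#' \eqn{(C_{TL} + C_{TL}^T)/2} so the downstream spectrum is real.
#' Trajectories shorter than the lag are excluded with a warning.
#'
#' @param ensemble a \linkS4class{FeatureEnsemble}.
#' @param lagNs lag time in ns (default 16); must be an integer multiple of
#'   the frame interval.
#' @return list with \code{mean}, \code{C}, \code{Ctl}, \code{lagNs},
#'   \code{nFrames}, \code{nPairs}, \code{featureNames},
#'   \code{frameIntervalNs}.
#' @export
estimateCovariances <- function(ensemble, lagNs = 16) {
  dt <- ensemble@frameIntervalNs
  lagF <- lagNs / dt
  if (!.isWholeNumber(lagF))
    .stopf("lag %g ns is not an integer multiple of the frame interval %g ns",
           lagNs, dt)
  lagF <- as.integer(round(lagF))
  if (lagF < 1L) .stopf("lag must be at least one frame")
  lens <- nFrames(ensemble)
  use <- which(lens > lagF)
  if (!length(use)) .stopf("every trajectory is shorter than the lag")
  if (length(use) < length(lens))
    .warnf("excluding %d trajectories shorter than the lag (%g ns)",
           length(lens) - length(use), lagNs)
  trajs <- ensemble@trajs[use]
  n <- sum(vapply(trajs, nrow, integer(1)))
  mu <- Reduce(`+`, lapply(trajs, colSums)) / n
  d <- length(mu)
  C <- matrix(0, d, d)
  Ctl <- matrix(0, d, d)
  nPairs <- 0
  for (x in trajs) {
    xc <- sweep(x, 2, mu)
    C <- C + crossprod(xc)
    m <- nrow(xc)
    Ctl <- Ctl + crossprod(xc[seq_len(m - lagF), , drop = FALSE],
                           xc[(lagF + 1L):m, , drop = FALSE])
    nPairs <- nPairs + (m - lagF)
  }
  C <- C / n
  Ctl <- Ctl / nPairs
  Ctl <- (Ctl + t(Ctl)) / 2
  list(mean = mu, C = C, Ctl = Ctl, lagNs = lagNs, nFrames = n,
       nPairs = nPairs, featureNames = ensemble@featureNames,
       frameIntervalNs = dt)
}

#' Solve the tICA generalized eigenproblem
#'
#' Solves \eqn{C_{TL} V = C V \Lambda} with \eqn{C} replaced by
#' \eqn{C + \epsilon I}, via whitening:
#' \eqn{C^{-1/2} C_{TL} C^{-1/2}} is symmetric, its eigenpairs are
#' back-transformed and sorted by descending eigenvalue. Eigenvectors are
#' normalized to unit C-weighted norm and sign-fixed so the
#' largest-magnitude component of each is positive.
#'
#' @param C covariance matrix, or the list returned by
#'   \code{\link{estimateCovariances}} (then \code{Ctl} is ignored).
#' @param Ctl symmetrized time-lagged covariance matrix.
#' @param regEpsilon ridge added to the diagonal of C; default
#'   \code{1e-10 * trace(C) / nfeatures}. With \code{regEpsilon = 0} a
#'   singular C is an error recommending regularization.
#' @param lagNs,mean,featureNames metadata when calling with bare matrices.
#' @return a \linkS4class{TicaModel}.
#' @export
solveTica <- function(C, Ctl = NULL, regEpsilon = NULL, lagNs = NA_real_,
                      mean = NULL, featureNames = NULL) {
  if (is.list(C) && !is.matrix(C)) {
    est <- C
    C <- est$C; Ctl <- est$Ctl; lagNs <- est$lagNs
    mean <- est$mean; featureNames <- est$featureNames
  }
  d <- ncol(C)
  if (!isTRUE(all.equal(dim(C), dim(Ctl))))
    .stopf("C and Ctl must have identical shape")
  if (max(abs(C - t(C))) > 1e-8 * max(1, max(abs(C))))
    .stopf("C must be symmetric")
  if (is.null(regEpsilon)) regEpsilon <- 1e-10 * sum(diag(C)) / d
  Creg <- C + diag(regEpsilon, d)
  e <- eigen((Creg + t(Creg)) / 2, symmetric = TRUE)
  if (min(e$values) <= 1e-14 * max(e$values, 1))
    .stopf("C is singular; increase regEpsilon (current %g)", regEpsilon)
  W <- e$vectors %*% ((1 / sqrt(e$values)) * t(e$vectors))
  M <- W %*% ((Ctl + t(Ctl)) / 2) %*% W
  em <- eigen((M + t(M)) / 2, symmetric = TRUE)
  V <- W %*% em$vectors
  for (j in seq_len(d))
    if (V[which.max(abs(V[, j])), j] < 0) V[, j] <- -V[, j]
  if (is.null(mean)) mean <- numeric(d)
  if (is.null(featureNames)) featureNames <- paste0("f", seq_len(d))
  new("TicaModel", mean = mean, cov = C, covLagged = Ctl, lagNs = lagNs,
      eigenvalues = em$values, eigenvectors = V, regEpsilon = regEpsilon,
      featureNames = featureNames)
}

#' Estimate and solve tICA in one step
#'
#' @inheritParams estimateCovariances
#' @param regEpsilon see \code{\link{solveTica}}.
#' @return a \linkS4class{TicaModel}.
#' @export
runTica <- function(ensemble, lagNs = 16, regEpsilon = NULL) {
  solveTica(estimateCovariances(ensemble, lagNs), regEpsilon = regEpsilon)
}

#' Project a feature ensemble onto leading tICA components
#'
#' Mean-free features times the first \code{nComponents} eigenvectors;
#' per-trajectory structure is preserved.
#'
#' @param ensemble a \linkS4class{FeatureEnsemble} with the model's features.
#' @param model a \linkS4class{TicaModel}.
#' @param nComponents number of components to keep (default 2).
#' @return a reduced \linkS4class{FeatureEnsemble} with features
#'   \code{tIC1, tIC2, ...}.
#' @export
projectTica <- function(ensemble, model, nComponents = 2) {
  d <- length(model@mean)
  if (length(ensemble@featureNames) != d)
    .stopf("ensemble has %d features, model expects %d",
           length(ensemble@featureNames), d)
  if (nComponents > ncol(model@eigenvectors))
    .stopf("nComponents (%d) exceeds the rank of the model (%d)",
           nComponents, ncol(model@eigenvectors))
  V <- model@eigenvectors[, seq_len(nComponents), drop = FALSE]
  nm <- paste0("tIC", seq_len(nComponents))
  trajs <- lapply(ensemble@trajs, function(x) {
    y <- sweep(x, 2, model@mean) %*% V
    colnames(y) <- nm
    y
  })
  new("FeatureEnsemble", trajs = trajs, featureNames = nm,
      frameIntervalNs = ensemble@frameIntervalNs)
}
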