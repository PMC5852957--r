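#' @include AllClasses.R utils.R
NULL

# k-means++ seeding (not provided by stats::kmeans)
.kmeansppInit <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(0, k, ncol(X))
  idx <- sample.int(n, 1L)
  centers[1L, ] <- X[idx, ]
  d2 <- rowSums(sweep(X, 2, centers[1L, ])^2)
  for (j in seq_len(k - 1L) + 1L) {
    if (all(d2 == 0)) idx <- sample.int(n, 1L)
    else idx <- sample.int(n, 1L, prob = d2)
    centers[j, ] <- X[idx, ]
    d2 <- pmin(d2, rowSums(sweep(X, 2, centers[j, ])^2))
  }
  centers
}

.nearestCenter <- function(X, centers) {
  # squared distances n x k; ties broken towards the lowest center index
  D <- outer(rowSums(X^2), rep(1, nrow(centers))) +
    outer(rep(1, nrow(X)), rowSums(centers^2)) - 2 * X %*% t(centers)
  max.col(-D, ties.method = "first")
}

#' Discretize reduced coordinates into microstates
#'
#' k-means (Lloyd iterations over a seeded k-means++ initialization) on the
#' pooled frames of the reduced ensemble. Final assignments are
#' nearest-centre with ties broken towards the lowest centre index, so
#' identical seeds give identical discretizations. Empty clusters trigger a
#' reseeded retry (up to 5) before erroring.
#'
#' @param reduced a \linkS4class{FeatureEnsemble} (e.g. tICA projections).
#' @param nStates number of microstates (default 100).
#' @param seed integer seed (required).
#' @return a \linkS4class{DiscreteTrajectories} with 0-based states.
#' @export
clusterMicrostates <- function(reduced, nStates = 100, seed) {
  X <- do.call(rbind, reduced@trajs)
  nStates <- as.integer(nStates)
  if (nStates > nrow(X))
    .stopf("nStates (%d) exceeds total frames (%d)", nStates, nrow(X))
  fit <- NULL
  for (attempt in 1:5) {
    set.seed(deriveSeed(seed, attempt - 1L))
    init <- .kmeansppInit(X, nStates)
    fit <- tryCatch(
      stats::kmeans(X, centers = init, iter.max = 200, algorithm = "Lloyd"),
      error = function(e) NULL, warning = function(w) NULL)
    if (!is.null(fit) && nrow(fit$centers) == nStates) break
    fit <- NULL
  }
  if (is.null(fit))
    .stopf("k-means produced an empty cluster in 5 reseeded attempts")
  assign <- .nearestCenter(X, fit$centers) - 1L
  lens <- vapply(reduced@trajs, nrow, integer(1))
  splits <- split(assign, rep(seq_along(lens), lens))
  new("DiscreteTrajectories", dtrajs = unname(splits), nStates = nStates,
      centers = fit$centers, frameIntervalNs = reduced@frameIntervalNs)
}

#' Sliding-window transition count matrix
#'
#' Counts every frame pair (t, t + lag) within each trajectory; pairs never
#' span trajectory boundaries.
#'
#' @param dtrajs a \linkS4class{DiscreteTrajectories}.
#' @param lagNs lag time, ns; must be an integer multiple of the frame
#'   interval, and at least one trajectory must be longer than the lag.
#' @return numeric count matrix (nStates x nStates).
#' @export
countMatrix <- function(dtrajs, lagNs) {
  dt <- dtrajs@frameIntervalNs
  lagF <- lagNs / dt
  if (!.isWholeNumber(lagF))
    .stopf("lag %g ns is not an integer multiple of the frame interval %g ns",
           lagNs, dt)
  lagF <- as.integer(round(lagF))
  if (lagF < 1L) .stopf("lag must be at least one frame")
  ns <- dtrajs@nStates
  counts <- matrix(0, ns, ns)
  any <- FALSE
  for (d in dtrajs@dtrajs) {
    if (length(d) <= lagF) next
    any <- TRUE
    counts <- count_transitions_cpp(as.integer(d), lagF, ns, counts)
  }
  if (!any) .stopf("all trajectories are shorter than the lag (%g ns)", lagNs)
  counts
}

# largest strongly connected component of the count graph (0-based ids out)
.largestSCC <- function(counts) {
  g <- igraph::graph_from_adjacency_matrix((counts > 0) * 1,
                                           mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  best <- which.max(comp$csize)
  sort(which(comp$membership == best))
}

#' Row-normalized Markov model on the largest connected set
#'
#' Restricts the counts to the largest strongly connected component (the
#' active set, logged when states are trimmed), row-normalizes to a TPM, and
#' computes the spectral decomposition and the stationary distribution.
#' Estimation is non-reversible by design (plain row normalization);
#' \code{reversible = TRUE} symmetrizes the counts first,
#' \eqn{(C + C^T)/2}, as an optional variant.
#'
#' @param counts non-negative count matrix.
#' @param lagNs lag time the counts were taken at (ns).
#' @param frameIntervalNs frame interval (ns).
#' @param reversible symmetrize counts before normalizing (default FALSE).
#' @return a \linkS4class{MarkovModel}.
#' @export
transitionMatrix <- function(counts, lagNs = 1, frameIntervalNs = 1,
                             reversible = FALSE) {
  if (any(counts < 0)) .stopf("counts must be non-negative")
  if (reversible) counts <- (counts + t(counts)) / 2
  active <- .largestSCC(counts)
  sub <- counts[active, active, drop = FALSE]
  rs <- rowSums(sub)
  if (!length(active) || any(rs == 0))
    .stopf("empty active set: no strongly connected states with outgoing counts")
  if (length(active) < nrow(counts))
    message(sprintf("msmflux: trimmed to largest strongly connected set (%d of %d states)",
                    length(active), nrow(counts)))
  tpm <- sub / rs
  eig <- eigen(tpm)
  ord <- order(Mod(eig$values), decreasing = TRUE)
  evals <- eig$values[ord]
  right <- eig$vectors[, ord, drop = FALSE]
  leig <- eigen(t(tpm))
  lord <- order(Mod(leig$values), decreasing = TRUE)
  left <- leig$vectors[, lord, drop = FALSE]
  p <- Re(left[, 1])
  if (sum(p) < 0) p <- -p
  p[p < 0 & p > -1e-12] <- 0
  p <- p / sum(p)
  new("MarkovModel", lagNs = lagNs, counts = counts, tpm = tpm,
      eigenvalues = as.complex(evals), rightVectors = right,
      leftVectors = left, pi = p, activeSet = as.integer(active - 1L),
      frameIntervalNs = frameIntervalNs)
}

#' Estimate a Markov model from discrete trajectories
#'
#' Convenience wrapper: \code{\link{countMatrix}} then
#' \code{\link{transitionMatrix}}.
#'
#' @inheritParams countMatrix
#' @param reversible see \code{\link{transitionMatrix}}.
#' @return a \linkS4class{MarkovModel}.
#' @export
estimateMarkovModel <- function(dtrajs, lagNs, reversible = FALSE) {
  transitionMatrix(countMatrix(dtrajs, lagNs), lagNs = lagNs,
                   frameIntervalNs = dtrajs@frameIntervalNs,
                   reversible = reversible)
}

#' Implied timescales of an estimated model
#'
#' \eqn{\tau_i = -\tau' / \ln \lambda_i} for the eigenvalues after the
#' stationary one. Real eigenvalues \eqn{\le 0} give NA (undefined),
#' eigenvalues at 1 give Inf; complex pairs use the modulus.
#'
#' @param model a \linkS4class{MarkovModel}.
#' @param nTimescales how many timescales (default 5, capped by the
#'   spectrum).
#' @return numeric vector of timescales in the model's lag units (ns).
#' @export
modelTimescales <- function(model, nTimescales = 5) {
  ev <- model@eigenvalues
  idx <- seq_len(min(nTimescales, length(ev) - 1L)) + 1L
  vapply(ev[idx], function(l) {
    if (abs(Im(l)) < 1e-12) {
      lr <- Re(l)
      if (lr >= 1) return(Inf)
      if (lr <= 0) return(NA_real_)
      -model@lagNs / log(lr)
    } else {
      m <- Mod(l)
      if (m >= 1) Inf else -model@lagNs / log(m)
    }
  }, numeric(1))
}

#' Implied relaxation timescales across lag times
#'
#' For each lag \eqn{\tau'}, estimates a TPM and reports
#' \eqn{\tau_i = -\tau' / \ln \lambda_i} for the leading eigenvalues below 1.
#' Real eigenvalues \eqn{\le 0} give an undefined (NA) timescale; eigenvalues
#' at 1 give Inf. Complex pairs use the modulus. A lag whose estimation
#' fails is reported with NA timescales and a warning; other lags proceed.
#'
#' @param dtrajs a \linkS4class{DiscreteTrajectories}.
#' @param lagsNs numeric vector of lag times (ns).
#' @param nTimescales how many timescales per lag (default 5).
#' @return data.frame with columns \code{lag_ns}, \code{index} (2 = slowest),
#'   \code{eigenvalue}, \code{timescale_ns}.
#' @export
impliedTimescales <- function(dtrajs, lagsNs, nTimescales = 5) {
  rows <- lapply(lagsNs, function(lag) {
    mod <- tryCatch(estimateMarkovModel(dtrajs, lag), error = function(e) {
      .warnf("lag %g ns: %s", lag, conditionMessage(e))
      NULL
    })
    idx <- seq_len(nTimescales) + 1L
    if (is.null(mod))
      return(data.frame(lag_ns = lag, index = idx, eigenvalue = NA_real_,
                        timescale_ns = NA_real_))
    ev <- mod@eigenvalues
    ev <- ev[idx[idx <= length(ev)]]
    ts <- vapply(ev, function(l) {
      if (abs(Im(l)) < 1e-12) {
        lr <- Re(l)
        if (lr >= 1) return(Inf)
        if (lr <= 0) return(NA_real_)
        -lag / log(lr)
      } else {
        m <- Mod(l)
        if (m >= 1) Inf else -lag / log(m)
      }
    }, numeric(1))
    data.frame(lag_ns = lag, index = seq_along(ev) + 1L,
               eigenvalue = Mod(ev), timescale_ns = ts)
  })
  do.call(rbind, rows)
}

#' Locate the Markovian plateau of an implied-timescale table
#'
#' Finds the smallest tested lag from which the slowest implied timescale
#' varies by at most \code{tolerance} (relative) across all larger tested
#' lags. Lags with undefined slowest timescales are skipped with a warning;
#' if no plateau exists the result is flagged.
#'
#' @param itsTable output of \code{\link{impliedTimescales}} (>= 3 lags).
#' @param tolerance relative variation allowed on the plateau (default 0.1).
#' @return list with \code{plateauLagNs} (NA when absent), \code{found},
#'   and the per-lag slowest timescales used.
#' @export
markovianityCheck <- function(itsTable, tolerance = 0.1) {
  slow <- itsTable[itsTable$index == 2L, ]
  bad <- is.na(slow$timescale_ns)
  if (any(bad)) {
    .warnf("skipping %d lags with undefined slowest timescale", sum(bad))
    slow <- slow[!bad, ]
  }
  if (nrow(slow) < 3L)
    .stopf("markovianity check needs at least 3 lags with defined timescales")
  slow <- slow[order(slow$lag_ns), ]
  ts <- slow$timescale_ns
  # a plateau needs at least two lags of support: the last lag alone is
  # never evidence of lag-independence
  for (i in seq_len(length(ts) - 1L)) {
    rest <- ts[i:length(ts)]
    if (all(abs(rest - ts[i]) <= tolerance * abs(ts[i])))
      return(list(plateauLagNs = slow$lag_ns[i], found = TRUE,
                  timescales = stats::setNames(ts, slow$lag_ns)))
  }
  list(plateauLagNs = NA_real_, found = FALSE,
       timescales = stats::setNames(ts, slow$lag_ns))
}

#' Sign structure of a relaxation mode
#'
#' Signs of each active state's entry in the chosen right eigenvector of the
#' TPM (mode 2 = slowest relaxation). The global sign is fixed so the
#' largest-magnitude entry is positive, making the labels stable under
#' eigenvector negation. A (near-)degenerate eigenvalue at the requested
#' mode triggers a warning.
#'
#' @param model a \linkS4class{MarkovModel}.
#' @param modeIndex which eigenvector (default 2).
#' @return integer vector of -1/0/+1 per active state, named by original
#'   state id.
#' @export
relaxationModeSigns <- function(model, modeIndex = 2) {
  ev <- model@eigenvalues
  if (modeIndex > length(ev))
    .stopf("modeIndex (%d) exceeds the spectrum size (%d)",
           modeIndex, length(ev))
  gaps <- abs(Mod(ev) - Mod(ev[modeIndex]))
  near <- which(gaps < 1e-10)
  if (length(setdiff(near, modeIndex)))
    .warnf("eigenvalue at mode %d is degenerate with mode(s) %s; reporting mode %d",
           modeIndex, paste(setdiff(near, modeIndex), collapse = ","),
           modeIndex)
  v <- model@rightVectors[, modeIndex]
  if (max(abs(Im(v))) > 1e-8 * max(Mod(v)))
    .warnf("mode %d eigenvector has a non-negligible imaginary part; using the real part",
           modeIndex)
  v <- Re(v)
  if (v[which.max(abs(v))] < 0) v <- -v
  stats::setNames(as.integer(sign(v)), model@activeSet)
}
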