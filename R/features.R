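#' @include AllClasses.R utils.R
NULL

# PDB-style head-group atom per charged residue type
.HEAD_ATOMS <- c(LYS = "NZ", ARG = "CZ", GLU = "CD", ASP = "CG")

#' Describe a residue/atom selection
#'
#' A light selector resolved against a \linkS4class{Topology}: any field left
#' NULL matches everything.
#'
#' @param segment,resid,atom,resname optional filters.
#' @return a list of class \code{"residueSelection"}.
#' @export
residueSelection <- function(segment = NULL, resid = NULL, atom = NULL,
                             resname = NULL) {
  structure(list(segment = segment, resid = resid, atom = atom,
                 resname = resname), class = "residueSelection")
}

# resolve a selection to atom row indices; errors name the selection
.resolveSelection <- function(topo, sel) {
  at <- topo@atoms
  keep <- rep(TRUE, nrow(at))
  if (!is.null(sel$segment)) keep <- keep & at$segment %in% sel$segment
  if (!is.null(sel$resid)) keep <- keep & at$resid %in% sel$resid
  if (!is.null(sel$atom)) keep <- keep & at$atom %in% sel$atom
  if (!is.null(sel$resname)) keep <- keep & at$resname %in% sel$resname
  idx <- which(keep)
  if (!length(idx))
    .stopf("selection (segment=%s, resid=%s, atom=%s, resname=%s) resolves to zero atoms",
           paste(sel$segment %||% "*", collapse = ","),
           paste(sel$resid %||% "*", collapse = ","),
           paste(sel$atom %||% "*", collapse = ","),
           paste(sel$resname %||% "*", collapse = ","))
  idx
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# distance time series between two atom indices, one trajectory
.atomPairDistance <- function(coordArr, i, j) {
  d <- coordArr[, i, , drop = FALSE] - coordArr[, j, , drop = FALSE]
  sqrt(rowSums(matrix(d, nrow = dim(coordArr)[1])^2))
}

#' Residue-residue minimum-distance contact map
#'
#' Entry (i, j) is the minimum, over every frame of every trajectory and
#' every heavy-atom (non-hydrogen) pair, of the distance between residue i of
#' the query selection and residue j of the target selection. Residues paired
#' with themselves are excluded and reported as NA.
#'
#' @param ensemble a \linkS4class{StructureEnsemble}.
#' @param query,target \code{\link{residueSelection}}s.
#' @return a \linkS4class{ContactMap}.
#' @export
contactMap <- function(ensemble, query, target) {
  topo <- ensemble@topology
  at <- topo@atoms
  heavy <- at$element != "H" & !grepl("^H", at$atom)
  qIdx <- intersect(.resolveSelection(topo, query), which(heavy))
  tIdx <- intersect(.resolveSelection(topo, target), which(heavy))
  if (!length(qIdx) || !length(tIdx))
    .stopf("selection resolves to zero heavy atoms")
  qKey <- unique(.resKey(at$segment[qIdx], at$resid[qIdx]))
  tKey <- unique(.resKey(at$segment[tIdx], at$resid[tIdx]))
  m <- matrix(Inf, length(qKey), length(tKey), dimnames = list(qKey, tKey))
  for (tr in trajectories(ensemble)) {
    for (qa in qIdx) {
      kq <- .resKey(at$segment[qa], at$resid[qa])
      for (ta in tIdx) {
        kt <- .resKey(at$segment[ta], at$resid[ta])
        if (kq == kt) next
        dmin <- min(.atomPairDistance(tr, qa, ta))
        if (dmin < m[kq, kt]) m[kq, kt] <- dmin
      }
    }
  }
  for (k in intersect(qKey, tKey)) m[k, k] <- NA_real_
  m[is.infinite(m)] <- NA_real_
  new("ContactMap", map = m, queryKeys = qKey, targetKeys = tKey)
}

#' Ensemble-averaged charged-pair interaction strengths
#'
#' For each labelled group pair, counts per frame the residue pairs (one
#' residue from each group) whose head-group atoms lie within the cutoff
#' (inclusive at the boundary), sums the counts over all frames of the
#' analysis window and over trajectories, and divides the total by the number
#' of trajectories. The spread is the population standard deviation of the
#' per-trajectory totals. Head-group atoms are NZ (Lys), CZ (Arg), CD (Glu)
#' and CG (Asp); every selected residue must be one of these types.
#'
#' @param ensemble a \linkS4class{StructureEnsemble}.
#' @param pairSpec named list; each element is a list with
#'   \code{\link{residueSelection}}s \code{query} and \code{target}.
#' @param cutoffA contact cutoff, Angstrom (default 7).
#' @param windowNs two-element numeric: analysis window in ns (default
#'   c(500, 940); frames at times within the closed interval are used). Must
#'   lie within the trajectory span.
#' @return data.frame with columns \code{pair}, \code{mean}, \code{sd},
#'   \code{nTrajectories}.
#' @export
interactionStrength <- function(ensemble, pairSpec, cutoffA = 7,
                                windowNs = c(500, 940)) {
  topo <- ensemble@topology
  at <- topo@atoms
  dt <- ensemble@frameIntervalNs
  nT <- nTrajectories(ensemble)
  nFr <- nFrames(ensemble)
  times <- lapply(nFr, function(n) (seq_len(n) - 1) * dt)
  spanNs <- (min(nFr) - 1) * dt
  if (windowNs[2] < windowNs[1] || windowNs[1] < 0)
    .stopf("invalid analysis window [%g, %g] ns", windowNs[1], windowNs[2])
  if (windowNs[1] > spanNs)
    .stopf("analysis window [%g, %g] ns lies outside the trajectory span (%g ns)",
           windowNs[1], windowNs[2], spanNs)

  headIndices <- function(sel) {
    idx <- .resolveSelection(topo, sel)
    res <- unique(data.frame(segment = at$segment[idx], resid = at$resid[idx]))
    out <- integer(nrow(res))
    for (i in seq_len(nrow(res))) {
      rows <- which(at$segment == res$segment[i] & at$resid == res$resid[i])
      rn <- at$resname[rows[1]]
      if (!rn %in% names(.HEAD_ATOMS))
        .stopf("residue %s:%d (%s) is not a supported charged type (Lys/Arg/Glu/Asp)",
               res$segment[i], res$resid[i], rn)
      hit <- rows[at$atom[rows] == .HEAD_ATOMS[[rn]]]
      if (!length(hit))
        .stopf("residue %s:%d (%s) lacks its head-group atom %s",
               res$segment[i], res$resid[i], rn, .HEAD_ATOMS[[rn]])
      out[i] <- hit[1]
    }
    out
  }

  rows <- lapply(names(pairSpec), function(lbl) {
    ps <- pairSpec[[lbl]]
    qa <- headIndices(ps$query)
    ta <- headIndices(ps$target)
    totals <- numeric(nT)
    for (k in seq_len(nT)) {
      inWin <- which(times[[k]] >= windowNs[1] & times[[k]] <= windowNs[2])
      if (!length(inWin)) .stopf("empty analysis window for trajectory %d", k)
      tr <- ensemble@coords[[k]]
      cnt <- 0
      for (a in qa) for (b in ta) {
        if (a == b) next
        d <- .atomPairDistance(tr, a, b)[inWin]
        cnt <- cnt + sum(d <= cutoffA)
      }
      totals[k] <- cnt
    }
    m <- sum(totals) / nT
    data.frame(pair = lbl, mean = m,
               sd = sqrt(mean((totals - m)^2)),
               nTrajectories = nT, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Gate-distance time series from a structure ensemble
#'
#' Distance between the head-group atoms of two charged residues, per frame
#' and trajectory.
#'
#' @param ensemble a \linkS4class{StructureEnsemble}.
#' @param query,target \code{\link{residueSelection}}s each resolving to one
#'   charged residue.
#' @param thresholdA "broken" threshold in Angstrom (default 7, the
#'   interaction cutoff).
#' @param name pair label.
#' @return a \linkS4class{GateSeries}.
#' @export
gateSeries <- function(ensemble, query, target, thresholdA = 7,
                       name = "gate") {
  topo <- ensemble@topology
  at <- topo@atoms
  one <- function(sel) {
    idx <- .resolveSelection(topo, sel)
    res <- unique(.resKey(at$segment[idx], at$resid[idx]))
    if (length(res) != 1)
      .stopf("gate selection must resolve to one residue, got %d", length(res))
    rn <- at$resname[idx[1]]
    if (!rn %in% names(.HEAD_ATOMS))
      .stopf("residue %s (%s) is not a supported charged type", res, rn)
    hit <- idx[at$atom[idx] == .HEAD_ATOMS[[rn]]]
    if (!length(hit)) .stopf("residue %s lacks head-group atom %s",
                             res, .HEAD_ATOMS[[rn]])
    hit[1]
  }
  a <- one(query); b <- one(target)
  ser <- lapply(trajectories(ensemble), .atomPairDistance, i = a, j = b)
  new("GateSeries", name = name, series = ser, thresholdA = thresholdA,
      frameIntervalNs = ensemble@frameIntervalNs)
}

#' Build a gate series directly from numeric distance vectors
#'
#' @param series list of per-trajectory numeric distance vectors.
#' @param thresholdA broken threshold, Angstrom.
#' @param name pair label.
#' @param frameIntervalNs frame interval, ns.
#' @return a \linkS4class{GateSeries}.
#' @export
newGateSeries <- function(series, thresholdA = 7, name = "gate",
                          frameIntervalNs = 0.8) {
  if (!is.list(series)) series <- list(series)
  new("GateSeries", name = name, series = lapply(series, as.numeric),
      thresholdA = thresholdA, frameIntervalNs = frameIntervalNs)
}

#' Broken fraction of a gate with a trajectory bootstrap
#'
#' The per-trajectory fraction of frames with distance strictly above the
#' threshold is averaged over trajectories; the confidence interval comes
#' from resampling whole trajectories with replacement.
#'
#' @param gate a \linkS4class{GateSeries}.
#' @param nBoot bootstrap iterations (default 1000).
#' @param seed integer seed.
#' @param level confidence level (default 0.95, percentile interval).
#' @return list with \code{fraction} (percent), \code{ci} (percent,
#'   length 2), \code{perTrajectory} (percent) and \code{bootMeans}.
#' @export
brokenFraction <- function(gate, nBoot = 1000, seed = 1, level = 0.95) {
  if (nBoot < 1) .stopf("nBoot must be >= 1")
  fr <- vapply(gate@series, function(d) 100 * mean(d > gate@thresholdA),
               numeric(1))
  point <- mean(fr)
  set.seed(seed)
  nT <- length(fr)
  boots <- vapply(seq_len(nBoot), function(i)
    mean(fr[sample.int(nT, nT, replace = TRUE)]), numeric(1))
  alpha <- (1 - level) / 2
  ci <- unname(stats::quantile(boots, c(alpha, 1 - alpha), type = 7))
  list(fraction = point, ci = ci, perTrajectory = fr, bootMeans = boots)
}

#' Ion-release distance coordinate
#'
#' Per-frame Euclidean distance between two single-atom selections (the
#' mobile ion and its binding-site reference), per trajectory.
#'
#' @param ensemble a \linkS4class{StructureEnsemble}.
#' @param ionSelection,referenceSelection \code{\link{residueSelection}}s
#'   each resolving to exactly one atom.
#' @return a one-feature \linkS4class{FeatureEnsemble}
#'   (\code{"release_distance"}, Angstrom).
#' @export
releaseCoordinate <- function(ensemble, ionSelection, referenceSelection) {
  topo <- ensemble@topology
  one <- function(sel, what) {
    idx <- .resolveSelection(topo, sel)
    if (length(idx) != 1)
      .stopf("%s selection must resolve to exactly one atom, got %d",
             what, length(idx))
    idx
  }
  a <- one(ionSelection, "ion")
  b <- one(referenceSelection, "reference")
  trajs <- lapply(trajectories(ensemble), function(tr)
    matrix(.atomPairDistance(tr, a, b), ncol = 1,
           dimnames = list(NULL, "release_distance")))
  new("FeatureEnsemble", trajs = trajs, featureNames = "release_distance",
      frameIntervalNs = ensemble@frameIntervalNs)
}

#' Detect first sustained threshold crossings
#'
#' For each trajectory, finds the first frame at which the distance exceeds
#' the threshold and stays above it for at least \code{dwellFrames}
#' consecutive frames (debounce); at most one event per trajectory.
#' Trajectories without an event are absent from the result.
#'
#' @param series a one-feature \linkS4class{FeatureEnsemble} or a list of
#'   numeric vectors.
#' @param thresholdA threshold, Angstrom.
#' @param dwellFrames minimum dwell above threshold (>= 1).
#' @return data.frame with columns \code{trajectory}, \code{frame} (1-based).
#' @export
detectReleaseEvents <- function(series, thresholdA, dwellFrames = 1L) {
  dwellFrames <- as.integer(dwellFrames)
  if (dwellFrames < 1L) .stopf("dwellFrames must be >= 1")
  if (is(series, "FeatureEnsemble"))
    series <- lapply(series@trajs, function(m) m[, 1])
  out <- list()
  for (i in seq_along(series)) {
    above <- series[[i]] > thresholdA
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    hit <- which(r$values & r$lengths >= dwellFrames)
    if (length(hit))
      out[[length(out) + 1L]] <- data.frame(trajectory = i,
                                            frame = starts[hit[1]])
  }
  if (!length(out)) return(data.frame(trajectory = integer(),
                                      frame = integer()))
  do.call(rbind, out)
}
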