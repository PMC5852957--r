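#' @include AllClasses.R utils.R
NULL

# bin values into counts on fixed breaks; x is a vector (1-d) or 2-col matrix
.binCounts <- function(x, breaks) {
  if (length(breaks) == 1L) {
    b <- breaks[[1]]
    idx <- findInterval(x[[1]], b, rightmost.closed = TRUE,
                        all.inside = FALSE)
    keep <- idx >= 1L & idx <= length(b) - 1L
    tabulate(idx[keep], nbins = length(b) - 1L)
  } else {
    b1 <- breaks[[1]]; b2 <- breaks[[2]]
    i <- findInterval(x[[1]], b1, rightmost.closed = TRUE)
    j <- findInterval(x[[2]], b2, rightmost.closed = TRUE)
    keep <- i >= 1L & i <= length(b1) - 1L & j >= 1L & j <= length(b2) - 1L
    n1 <- length(b1) - 1L; n2 <- length(b2) - 1L
    matrix(tabulate((j[keep] - 1L) * n1 + i[keep], nbins = n1 * n2), n1, n2)
  }
}

.countsToDG <- function(counts, RT) {
  total <- sum(counts)
  dG <- ifelse(counts > 0, -RT * log(counts / total), NA_real_)
  dG - min(dG, na.rm = TRUE)
}

#' Population free-energy profile with block-bootstrap errors
#'
#' Histograms a projected coordinate (1-d profile or 2-d landscape) and
#' converts bin populations to \eqn{\Delta G = -RT \ln(\mathrm{population})}
#' (kcal/mol), shifting so the minimum over occupied bins is 0. Empty bins
#' are flagged rather than assigned a finite value. The per-bin error is the
#' standard deviation of \eqn{\Delta G} over bootstrap replicates, each built
#' from \code{nBlocks} contiguous frame blocks of \code{blockNs} drawn with
#' replacement from random positions in random trajectories.
#'
#' @param values a \linkS4class{FeatureEnsemble} with 1 or 2 features, or a
#'   list of numeric vectors / 2-column matrices.
#' @param bins number of bins per axis, or a list of explicit break vectors.
#' @param temperatureK temperature, K (default 310).
#' @param blockNs bootstrap block length, ns (default 160).
#' @param nBlocks blocks per replicate (default 100).
#' @param nBootstrap bootstrap replicates over which the per-bin spread is
#'   taken (default 100).
#' @param seed integer seed.
#' @param frameIntervalNs frame interval; taken from \code{values} when it is
#'   a FeatureEnsemble.
#' @return a \linkS4class{FreeEnergyProfile}.
#' @export
freeEnergyProfile <- function(values, bins = 50, temperatureK = 310,
                              blockNs = 160, nBlocks = 100,
                              nBootstrap = 100, seed = 1,
                              frameIntervalNs = NULL) {
  if (is(values, "FeatureEnsemble")) {
    frameIntervalNs <- values@frameIntervalNs
    values <- values@trajs
  }
  if (!is.list(values)) values <- list(values)
  if (is.null(frameIntervalNs))
    .stopf("frameIntervalNs is required when values are plain vectors")
  asCols <- function(v) if (is.matrix(v)) v else matrix(v, ncol = 1)
  values <- lapply(values, asCols)
  d <- ncol(values[[1]])
  if (!d %in% 1:2) .stopf("profiles support 1 or 2 coordinates, got %d", d)
  if (!sum(vapply(values, nrow, integer(1))))
    .stopf("no data to histogram")
  pooled <- do.call(rbind, values)
  if (!all(is.finite(pooled))) .stopf("values must be finite")
  if (!is.list(bins)) {
    bins <- lapply(seq_len(d), function(j) {
      r <- range(pooled[, j])
      seq(r[1], r[2], length.out = bins + 1L)
    })
  }
  RT <- .R_KCAL * temperatureK
  cols <- function(m) lapply(seq_len(ncol(m)), function(j) m[, j])
  counts <- .binCounts(cols(pooled), bins)
  dG <- .countsToDG(counts, RT)

  blockFrames <- max(1L, as.integer(round(blockNs / frameIntervalNs)))
  starts <- lapply(values, function(v) max(0L, nrow(v) - blockFrames) + 1L)
  set.seed(seed)
  boots <- vector("list", nBootstrap)
  for (r in seq_len(nBootstrap)) {
    trIdx <- sample.int(length(values), nBlocks, replace = TRUE)
    rep <- do.call(rbind, lapply(trIdx, function(k) {
      v <- values[[k]]
      s <- sample.int(starts[[k]], 1L)
      v[s:min(nrow(v), s + blockFrames - 1L), , drop = FALSE]
    }))
    boots[[r]] <- .countsToDG(.binCounts(cols(rep), bins), RT)
  }
  bootArr <- simplify2array(boots)
  err <- apply(bootArr, seq_len(length(dim(bootArr)) - 1L), stats::sd,
               na.rm = TRUE)
  err[counts == 0] <- NA_real_
  mids <- lapply(bins, function(b) (b[-1] + b[-length(b)]) / 2)
  new("FreeEnergyProfile", breaks = bins, mids = mids, dG = dG,
      error = err, empty = counts == 0, temperatureK = temperatureK)
}
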