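#' @include AllClasses.R AllGenerics.R
NULL

.checkAB <- function(n, A, B) {
  A <- as.integer(A); B <- as.integer(B)
  if (!length(A) || !length(B)) .stopf("A and B must be non-empty")
  if (length(intersect(A, B))) .stopf("A and B must be disjoint")
  if (min(c(A, B)) < 1L || max(c(A, B)) > n)
    .stopf("A and B must be 1-based indices within the active set (1..%d)", n)
  list(A = A, B = B)
}

.committorsCore <- function(tpm, p, A, B) {
  n <- nrow(tpm)
  ab <- .checkAB(n, A, B)
  A <- ab$A; B <- ab$B
  U <- setdiff(seq_len(n), c(A, B))
  qplus <- numeric(n)
  qplus[B] <- 1
  if (length(U)) {
    M <- diag(length(U)) - tpm[U, U, drop = FALSE]
    rhs <- rowSums(tpm[U, B, drop = FALSE])
    sol <- tryCatch(solve(M, rhs), error = function(e) {
      g <- igraph::graph_from_adjacency_matrix((tpm > 0) * 1,
                                               mode = "directed")
      reach <- vapply(U, function(u) {
        d <- igraph::distances(g, v = u, to = B, mode = "out")
        any(is.finite(d))
      }, logical(1))
      .stopf("committor system is singular; states unreachable from the sink: %s",
             paste(U[!reach], collapse = ","))
    })
    qplus[U] <- sol
  }
  # backward committor from the time-reversed chain
  Trev <- t(tpm * p) / p
  qminus <- numeric(n)
  qminus[A] <- 1
  if (length(U)) {
    M <- diag(length(U)) - Trev[U, U, drop = FALSE]
    rhs <- rowSums(Trev[U, A, drop = FALSE])
    qminus[U] <- solve(M, rhs)
  }
  list(qplus = pmin(pmax(qplus, 0), 1), qminus = pmin(pmax(qminus, 0), 1))
}

.fluxCore <- function(tpm, p, A, B) {
  q <- .committorsCore(tpm, p, A, B)
  n <- nrow(tpm)
  gross <- (p * q$qminus) * tpm * matrix(q$qplus, n, n, byrow = TRUE)
  diag(gross) <- 0
  net <- pmax(gross - t(gross), 0)
  ab <- .checkAB(n, A, B)
  total <- sum(net[ab$A, , drop = FALSE])
  new("FluxNetwork", A = ab$A, B = ab$B, qplus = q$qplus,
      qminus = q$qminus, gross = gross, net = net, totalFlux = total,
      pi = p, tpm = tpm)
}

#' @describeIn committors on the microstate model's active set
setMethod("committors", "MarkovModel", function(model, A, B)
  .committorsCore(model@tpm, model@pi, A, B))

#' @describeIn committors on a macrostate model
setMethod("committors", "MacroModel", function(model, A, B)
  .committorsCore(model@tpm, model@pi, A, B))

#' @describeIn fluxNetwork on the microstate model's active set
setMethod("fluxNetwork", "MarkovModel", function(model, A, B)
  .fluxCore(model@tpm, model@pi, A, B))

#' @describeIn fluxNetwork on a macrostate model
setMethod("fluxNetwork", "MacroModel", function(model, A, B)
  .fluxCore(model@tpm, model@pi, A, B))

# widest (maximin-capacity) path from any state of A to any state of B on
# the capacity graph `cap`; ties broken by fewest hops, then by the
# lexicographically smallest state sequence. Returns NULL when no
# positive-capacity path exists. The bottleneck width is found by binary
# search over the distinct capacities; the tie-breaks then reduce to a BFS
# in the subgraph of edges at least that wide.
.widestPath <- function(cap, A, B) {
  n <- nrow(cap)
  reachesB <- function(adj) {
    seen <- rep(FALSE, n)
    seen[A] <- TRUE
    frontier <- A
    while (length(frontier)) {
      nxt <- integer(0)
      for (u in frontier) {
        vs <- which(adj[u, ] & !seen)
        seen[vs] <- TRUE
        nxt <- c(nxt, vs)
      }
      frontier <- nxt
    }
    any(seen[B])
  }
  caps <- sort(unique(cap[cap > 0]), decreasing = TRUE)
  if (!length(caps) || !reachesB(cap >= caps[length(caps)])) return(NULL)
  lo <- 1L; hi <- length(caps)       # caps[hi] always reaches; find largest
  while (lo < hi) {                  # capacity that still connects A to B
    mid <- (lo + hi) %/% 2L
    if (reachesB(cap >= caps[mid])) hi <- mid else lo <- mid + 1L
  }
  wstar <- caps[hi]
  adj <- cap >= wstar
  # fewest hops to B (BFS on reversed edges), then lexicographic greedy
  distB <- rep(Inf, n)
  distB[B] <- 0
  frontier <- B
  while (length(frontier)) {
    nxt <- integer(0)
    for (v in frontier) {
      us <- which(adj[, v] & is.infinite(distB))
      distB[us] <- distB[v] + 1
      nxt <- c(nxt, us)
    }
    frontier <- nxt
  }
  starts <- A[is.finite(distB[A])]
  L <- min(distB[starts])
  u <- min(starts[distB[starts] == L])
  path <- u
  while (!(u %in% B)) {
    u <- min(which(adj[u, ] & distB == distB[u] - 1))
    path <- c(path, u)
  }
  list(path = path, width = wstar)
}

#' Ranked pathway decomposition of a flux network
#'
#' Iterative bottleneck decomposition: repeatedly find the
#' highest-minimum-capacity (widest) A-to-B path on the net flux graph,
#' record it with its bottleneck flux, and subtract that flux along the
#' path. Stops after \code{maxPaths} pathways or when the flux is exhausted.
#' Ties in the widest-path search are broken by fewest hops, then lowest
#' state index.
#'
#' @param network a \linkS4class{FluxNetwork} with positive total flux.
#' @param maxPaths maximum number of pathways (default 10).
#' @return a \linkS4class{PathwayDecomposition}; fractions are relative to
#'   the network's total flux.
#' @export
topPathways <- function(network, maxPaths = 10) {
  if (network@totalFlux <= 0) .stopf("total flux is zero; no pathways")
  cap <- network@net
  paths <- list()
  fluxes <- numeric(0)
  for (k in seq_len(maxPaths)) {
    wp <- .widestPath(cap, network@A, network@B)
    if (is.null(wp)) break
    f <- wp$width
    path <- wp$path
    for (i in seq_len(length(path) - 1L))
      cap[path[i], path[i + 1L]] <- cap[path[i], path[i + 1L]] - f
    paths[[k]] <- path
    fluxes[k] <- f
  }
  fr <- fluxes / network@totalFlux
  tab <- data.frame(
    pathway = vapply(paths, paste, "", collapse = "->"),
    flux = fluxes, fraction = fr, cumulative = cumsum(fr),
    stringsAsFactors = FALSE)
  new("PathwayDecomposition", paths = paths, table = tab,
      totalFlux = network@totalFlux)
}

#' Group pathway fractions by state annotations
#'
#' Declarative grouping of a pathway decomposition: each pathway is labelled
#' by the sorted unique annotations of its intermediate states (pathways
#' with no intermediates are labelled \code{"direct"}), and fractions are
#' summed per label. Every state appearing as an intermediate must be
#' annotated.
#'
#' @param decomposition a \linkS4class{PathwayDecomposition}.
#' @param annotations named character vector: state index -> label.
#' @return data.frame with columns \code{group}, \code{fraction},
#'   \code{nPathways}, sorted by decreasing fraction.
#' @export
pathwayGrouping <- function(decomposition, annotations) {
  labels <- vapply(decomposition@paths, function(p) {
    inter <- p[-c(1L, length(p))]
    if (!length(inter)) return("direct")
    ann <- annotations[as.character(inter)]
    if (any(is.na(ann)))
      .stopf("state %s on a pathway has no annotation",
             inter[which(is.na(ann))[1]])
    paste(sort(unique(ann)), collapse = "+")
  }, "")
  agg <- stats::aggregate(decomposition@table$fraction,
                          by = list(group = labels), FUN = sum)
  cnt <- table(labels)
  out <- data.frame(group = agg$group, fraction = agg$x,
                    nPathways = as.integer(cnt[agg$group]),
                    stringsAsFactors = FALSE)
  out[order(-out$fraction), , drop = FALSE]
}
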