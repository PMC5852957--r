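# Independent brute-force references the implementation is checked against.

# exhaustive residue-pair minimum distance over all frames, trajectories and
# heavy-atom pairs — plain double loops, no vectorized shortcuts
naiveContactMin <- function(ensemble, keyA, keyB) {
  at <- msmflux::topology(ensemble)
  heavy <- at$element != "H" & !grepl("^H", at$atom)
  key <- paste0(at$segment, ":", at$resid)
  ia <- which(key == keyA & heavy)
  ib <- which(key == keyB & heavy)
  best <- Inf
  for (tr in msmflux::trajectories(ensemble)) {
    for (f in seq_len(dim(tr)[1])) {
      for (a in ia) for (b in ib) {
        d <- sqrt(sum((tr[f, a, ] - tr[f, b, ])^2))
        if (d < best) best <- d
      }
    }
  }
  best
}

# double-loop transition tally at a lag
bruteCountMatrix <- function(dtrajList, lag, nStates) {
  counts <- matrix(0, nStates, nStates)
  for (d in dtrajList) {
    n <- length(d)
    if (n <= lag) next
    for (t in seq_len(n - lag))
      counts[d[t] + 1L, d[t + lag] + 1L] <- counts[d[t] + 1L, d[t + lag] + 1L] + 1
  }
  counts
}

# stationary distribution by power iteration (independent of eigen())
oraclePi <- function(tpm, tol = 1e-14, maxit = 1e6) {
  p <- rep(1 / nrow(tpm), nrow(tpm))
  for (i in seq_len(maxit)) {
    p2 <- drop(p %*% tpm)
    if (max(abs(p2 - p)) < tol) return(p2 / sum(p2))
    p <- p2
  }
  p / sum(p)
}

# forward committor by fixed-point iteration of q <- T q with boundaries
oracleCommittor <- function(tpm, A, B, tol = 1e-14, maxit = 1e6) {
  n <- nrow(tpm)
  q <- rep(0.5, n)
  q[A] <- 0; q[B] <- 1
  U <- setdiff(seq_len(n), c(A, B))
  for (i in seq_len(maxit)) {
    q2 <- q
    q2[U] <- drop(tpm[U, , drop = FALSE] %*% q)
    if (max(abs(q2 - q)) < tol) return(q2)
    q <- q2
  }
  q
}

oracleBackwardCommittor <- function(tpm, p, A, B, tol = 1e-14) {
  Trev <- t(tpm * p) / p
  oracleCommittor(Trev, A = B, B = A, tol = tol)
}

# all simple paths from any state in A to any state in B (DFS)
allSimplePaths <- function(adj, A, B) {
  n <- nrow(adj)
  out <- list()
  walk <- function(path) {
    u <- path[length(path)]
    if (u %in% B) {
      out[[length(out) + 1L]] <<- path
      return()
    }
    for (v in seq_len(n))
      if (adj[u, v] > 0 && !(v %in% path)) walk(c(path, v))
  }
  for (a in A) walk(a)
  out
}

# widest-path flux decomposition by exhaustive enumeration; ties resolved by
# width desc, fewest hops, then lexicographically smallest path
oracleDecomposition <- function(net, A, B, maxPaths = 10) {
  cap <- net
  paths <- list(); fluxes <- numeric(0)
  for (k in seq_len(maxPaths)) {
    cand <- allSimplePaths(cap, A, B)
    if (!length(cand)) break
    widths <- vapply(cand, function(p) {
      w <- Inf
      for (i in seq_len(length(p) - 1L)) w <- min(w, cap[p[i], p[i + 1L]])
      w
    }, numeric(1))
    keep <- which(widths > 0)
    if (!length(keep)) break
    cand <- cand[keep]; widths <- widths[keep]
    best <- which(widths == max(widths))
    if (length(best) > 1) {
      hops <- lengths(cand[best])
      best <- best[hops == min(hops)]
      if (length(best) > 1) {
        keys <- vapply(cand[best], function(p)
          paste(sprintf("%04d", p), collapse = ","), "")
        best <- best[order(keys)][1]
      }
    }
    b <- best[1]
    p <- cand[[b]]; f <- widths[b]
    for (i in seq_len(length(p) - 1L))
      cap[p[i], p[i + 1L]] <- cap[p[i], p[i + 1L]] - f
    paths[[k]] <- p; fluxes[k] <- f
  }
  list(paths = paths, fluxes = fluxes)
}

# AR(1) series with fixed seed
ar1 <- function(n, phi, seed, sd = 1) {
  set.seed(seed)
  as.numeric(stats::filter(stats::rnorm(n, sd = sd), phi,
                           method = "recursive"))
}
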