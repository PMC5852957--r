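#' @include AllClasses.R msm.R
NULL

# simplex-vertex index search of PCCA+: pick m rows of the eigenvector
# matrix that span the membership simplex
.indexSearch <- function(X) {
  m <- ncol(X)
  idx <- integer(m)
  ortho <- X
  idx[1] <- which.max(rowSums(X^2))
  ortho <- sweep(X, 2, X[idx[1], ])
  for (j in seq_len(m - 1L) + 1L) {
    dist <- sqrt(rowSums(ortho^2))
    idx[j] <- which.max(dist)
    v <- ortho[idx[j], ]
    nv <- sqrt(sum(v^2))
    if (nv < 1e-14)
      .stopf("degenerate eigenvector structure: cannot span %d macrostates", m)
    v <- v / nv
    ortho <- ortho - (ortho %*% v) %*% t(v)
  }
  idx
}

#' Lump microstates into macrostates with PCCA+
#'
#' Robust Perron cluster analysis on the leading right eigenvectors of the
#' TPM: fuzzy memberships are obtained by mapping the eigenvector rows onto
#' the simplex spanned by the most spread-out rows (inner-simplex vertex
#' search), and the crisp assignment is the argmax membership. Membership
#' rows sum to 1 by construction. The macrostate TPM aggregates the
#' microstate TPM with stationary-distribution weights over the crisp
#' lumping:
#' \eqn{T_{ab} = \sum_{i \in a} \pi_i \sum_{j \in b} T_{ij} / \sum_{i \in a} \pi_i}.
#'
#' @param model a connected \linkS4class{MarkovModel}.
#' @param nMacrostates number of macrostates (default 15); must not exceed
#'   the number of TPM eigenvalues with positive real part.
#' @return a \linkS4class{MacroModel}.
#' @export
pccaLump <- function(model, nMacrostates = 15) {
  m <- as.integer(nMacrostates)
  n <- nrow(model@tpm)
  feasible <- sum(Re(model@eigenvalues) > 0)
  if (m > feasible)
    .stopf("requested %d macrostates but only %d eigenvalues have positive real part; largest feasible count is %d",
           m, feasible, feasible)
  if (m < 2L) .stopf("nMacrostates must be >= 2")
  ev <- model@eigenvalues[seq_len(m)]
  if (max(abs(Im(ev))) > 1e-8)
    .warnf("leading eigenvalues contain complex pairs; PCCA+ uses their real parts")
  X <- Re(model@rightVectors[, seq_len(m), drop = FALSE])
  X[, 1] <- 1
  idx <- .indexSearch(X)
  A <- solve(X[idx, , drop = FALSE])
  chi <- X %*% A
  crisp <- max.col(chi, ties.method = "first")
  # ensure every macrostate label is used (vertex rows guarantee this)
  relabel <- match(crisp, sort(unique(crisp)))
  if (length(unique(crisp)) < m)
    .stopf("crisp lumping collapsed to %d macrostates; reduce nMacrostates",
           length(unique(crisp)))
  p <- model@pi
  Tm <- matrix(0, m, m)
  macroPi <- numeric(m)
  for (a in seq_len(m)) {
    ia <- which(crisp == a)
    wa <- p[ia]
    macroPi[a] <- sum(wa)
    for (b in seq_len(m)) {
      ib <- which(crisp == b)
      Tm[a, b] <- sum(wa * rowSums(model@tpm[ia, ib, drop = FALSE])) /
        sum(wa)
    }
  }
  new("MacroModel", membership = as.integer(crisp), memberships = chi,
      nMacrostates = m, tpm = Tm, pi = macroPi / sum(macroPi),
      microActiveSet = model@activeSet)
}

#' Map per-frame microstates to macrostates
#'
#' @param dtrajs a \linkS4class{DiscreteTrajectories} (microstates, 0-based).
#' @param model the \linkS4class{MarkovModel} the lumping was built on.
#' @param macro a \linkS4class{MacroModel}.
#' @return list of per-trajectory integer macrostate sequences (1-based; NA
#'   for frames in trimmed microstates).
#' @export
macrostateAssignments <- function(dtrajs, model, macro) {
  lookup <- rep(NA_integer_, dtrajs@nStates)
  lookup[model@activeSet + 1L] <- macro@membership
  lapply(dtrajs@dtrajs, function(d) lookup[d + 1L])
}
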