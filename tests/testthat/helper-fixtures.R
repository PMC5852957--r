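# Shared fixtures, all built in code.

# dense random connected chain (all transition probabilities positive)
randomChain <- function(n, seed) {
  set.seed(seed)
  counts <- matrix(stats::runif(n * n, 0.05, 1), n, n)
  tpm <- counts / rowSums(counts)
  list(tpm = tpm, pi = oraclePi(tpm))
}

# detailed-balance chain from a symmetric weight matrix
reversibleChain <- function(n, seed) {
  set.seed(seed)
  w <- matrix(stats::runif(n * n, 0.05, 1), n, n)
  w <- (w + t(w)) / 2
  tpm <- w / rowSums(w)
  list(tpm = tpm, pi = rowSums(w) / sum(w))
}

# nearly block-diagonal metastable chain; `sizes` gives microstates per block
blockChain <- function(sizes, eps = 1e-3, seed = 1) {
  set.seed(seed)
  n <- sum(sizes)
  block <- rep(seq_along(sizes), sizes)
  w <- matrix(eps * stats::runif(n * n, 0.5, 1), n, n)
  for (b in seq_along(sizes)) {
    i <- which(block == b)
    w[i, i] <- stats::runif(length(i)^2, 0.5, 1)
  }
  w <- (w + t(w)) / 2   # detailed balance => real spectrum
  list(tpm = w / rowSums(w), block = block)
}

# wrap plain integer sequences as DiscreteTrajectories (0-based states)
asDtrajs <- function(seqs, nStates, dtNs = 1) {
  if (!is.list(seqs)) seqs <- list(seqs)
  new("DiscreteTrajectories", dtrajs = lapply(seqs, as.integer),
      nStates = as.integer(nStates),
      centers = matrix(0, nStates, 1), frameIntervalNs = dtNs)
}

# wrap matrices as a FeatureEnsemble
asFeatures <- function(mats, dtNs = 1, names = NULL) {
  if (!is.list(mats)) mats <- list(mats)
  mats <- lapply(mats, function(m) if (is.matrix(m)) m else cbind(m))
  if (is.null(names)) names <- paste0("f", seq_len(ncol(mats[[1]])))
  mats <- lapply(mats, function(m) { colnames(m) <- NULL; m })
  new("FeatureEnsemble", trajs = mats, featureNames = names,
      frameIntervalNs = dtNs)
}

# two-residue charged bead fixture with a scheduled pair distance per frame
pairBeads <- function(distances, dtNs = 0.8) {
  atoms <- data.frame(
    atom = c("CZ", "CG"), element = c("C", "C"),
    resname = c("ARG", "ASP"), resid = c(60L, 436L),
    segment = c("NTERM", "CORE"), stringsAsFactors = FALSE)
  nF <- length(distances)
  coords <- array(0, dim = c(nF, 2, 3))
  coords[, 2, 1] <- distances
  beadFrames(atoms, coords, frameIntervalNs = dtNs)
}

# the small release ensemble used across tests (features only unless asked)
smallRelease <- function(nTraj = 10L, nFrames = 500L, seed = 3L,
                         structures = FALSE, params = list()) {
  params <- utils::modifyList(list(includeStructures = structures), params)
  releaseSystem(syntheticSpec(nTrajectories = nTraj, nFrames = nFrames,
                              seed = seed, generator = "release_system",
                              params = params))
}
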