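test_that("markov chain sampling honours degenerate transition structures", {
  expect_identical(sampleMarkovChain(diag(2), 100, 0L, seed = 1),
                   rep(0L, 100))
  flip <- matrix(c(0, 1, 1, 0), 2, byrow = TRUE)
  expect_identical(sampleMarkovChain(flip, 7, 0L, seed = 5),
                   as.integer(rep_len(c(0, 1), 7)))
  bad <- matrix(c(0.5, 0.4, 0.2, 0.8), 2, byrow = TRUE)
  expect_error(sampleMarkovChain(bad, 10, 0L, seed = 1), "row 1")
})

test_that("empirical transition frequencies converge to the sampling TPM", {
  tpm <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE)
  ch <- sampleMarkovChain(tpm, 2e5, 0L, seed = 11)
  freq <- bruteCountMatrix(list(ch), 1, 2)
  freq <- freq / rowSums(freq)
  expect_lt(max(abs(freq - tpm)), 0.01)
})

test_that("chain sampling is a pure function of (spec, seed)", {
  tpm <- matrix(c(0.7, 0.3, 0.4, 0.6), 2, byrow = TRUE)
  expect_identical(sampleMarkovChain(tpm, 5000, 1L, seed = 9),
                   sampleMarkovChain(tpm, 5000, 1L, seed = 9))
  expect_false(identical(sampleMarkovChain(tpm, 5000, 1L, seed = 9),
                         sampleMarkovChain(tpm, 5000, 1L, seed = 10)))
})

test_that("gaussian emissions reproduce state means and spreads", {
  states <- c(0L, 1L, 0L, 1L, 1L)
  means <- rbind(c(1, 2), c(-3, 4))
  out <- emitGaussianFeatures(states, means, matrix(0, 2, 2), seed = 1)
  expect_equal(out, means[states + 1L, ])

  big <- emitGaussianFeatures(rep(0L, 1e5), matrix(0), matrix(1), seed = 2)
  expect_lt(abs(mean(big)), 0.02)
  expect_lt(abs(stats::var(as.numeric(big)) - 1), 0.05)

  expect_error(
    emitGaussianFeatures(0L, matrix(0), matrix(-1), seed = 1),
    "positive semi-definite")
})

test_that("well-separated emissions are recoverable by 2-means clustering", {
  states <- sampleMarkovChain(matrix(0.5, 2, 2), 2000, 0L, seed = 3)
  out <- emitGaussianFeatures(states, rbind(0, 20), matrix(0.5), seed = 4)
  km <- stats::kmeans(out, centers = rbind(0, 20))
  lab <- km$cluster - 1L
  agree <- max(mean(lab == states), mean(lab != states))
  expect_gt(agree, 0.999)
})

test_that("harmonic brownian dynamics samples the Boltzmann variance", {
  pot <- list(type = "harmonic", k = 2, center = 0, kT = 1, gamma = 1)
  x <- brownianWells(pot, nSteps = 5e5, dt = 0.02, seed = 42)
  expect_lt(abs(stats::var(x[, 1]) - 0.5) / 0.5, 0.05)  # kT/k = 0.5
})

test_that("zero-temperature dynamics from the well bottom stays put", {
  pot <- list(type = "harmonic", k = 1, center = 3, kT = 0, gamma = 1)
  x <- brownianWells(pot, nSteps = 100, dt = 0.01, seed = 1)
  expect_true(all(x == 3))
})

test_that("symmetric double well splits occupancy evenly", {
  pot <- list(type = "double_well", height = 1.5, halfSeparation = 1,
              kT = 1, gamma = 1)
  x <- brownianWells(pot, nSteps = 8e5, dt = 0.01, seed = 7)[, 1]
  crossings <- sum(diff(x > 0) != 0)
  expect_gte(crossings, 10)
  expect_lt(abs(mean(x > 0) - 0.5), 0.02)
})

test_that("unstable integration steps are rejected with a suggested dt", {
  pot <- list(type = "double_well", height = 1, halfSeparation = 0.1,
              kT = 1, gamma = 1)
  expect_error(brownianWells(pot, 100, dt = 0.05, seed = 1), "use dt <")
})

test_that("bead schedules are exact and duplicate atoms are rejected", {
  ens <- pairBeads(c(10, 10, 3, 3, 3))
  d <- trajectories(ens)[[1]]
  expect_equal(sqrt(sum((d[1, 1, ] - d[1, 2, ])^2)), 10)
  gs <- gateSeries(ens, residueSelection(resid = 60),
                   residueSelection(resid = 436), thresholdA = 7)
  expect_equal(which(gs@series[[1]] <= 7)[1], 3)  # contact appears at frame 3

  atoms <- topology(ens)
  atoms2 <- rbind(atoms, atoms[1, ])
  expect_error(beadFrames(atoms2, array(0, c(2, 3, 3))), "duplicate")
})

test_that("release ensembles regenerate identically from spec + seed", {
  a <- smallRelease(3L, 100L, seed = 21, structures = TRUE)
  b <- smallRelease(3L, 100L, seed = 21, structures = TRUE)
  expect_identical(a$features@trajs, b$features@trajs)
  expect_identical(a$structures@coords, b$structures@coords)
  expect_identical(a$groundTruth@stateLabels, b$groundTruth@stateLabels)
})

test_that("bead head-group distances reproduce the gate coordinates", {
  syn <- smallRelease(2L, 120L, seed = 5, structures = TRUE)
  at <- topology(syn$structures)
  for (g in c("R60-D436", "E428-R445", "K66-D345")) {
    res <- as.integer(sub("^[A-Z]+", "", strsplit(g, "-")[[1]]))
    tr <- trajectories(syn$structures)[[1]]
    ia <- which(at$resid == res[1] & at$segment == "CORE")
    ib <- which(at$resid == res[2] & at$segment == "CORE")
    d <- sqrt(rowSums((tr[, ia, ] - tr[, ib, ])^2))
    expect_equal(d, unname(syn$features@trajs[[1]][, g]))
  }
})

test_that("empirical first-passage times match the analytic ground truth", {
  syn <- smallRelease(200L, 2000L, seed = 17)
  gt <- syn$groundTruth
  ev <- detectReleaseEvents(lapply(syn$features@trajs, function(m) m[, 1]),
                            gt@metadata$releaseThresholdA,
                            gt@metadata$dwellFrames)
  expect_gt(nrow(ev), 150)
  expect_lt(abs(mean(ev$frame) - gt@trueMFPTFrames) / gt@trueMFPTFrames,
            0.15)
})

test_that("degenerate release control loses its two-basin structure", {
  syn <- smallRelease(5L, 400L, seed = 9,
                      params = list(releasedMeanA = 3.0, releasedSdA = 0.3))
  pooled <- unlist(lapply(syn$features@trajs, function(m) m[, 1]))
  d <- stats::density(pooled)
  peaks <- which(diff(sign(diff(d$y))) == -2) + 1L
  substantial <- peaks[d$y[peaks] > 0.1 * max(d$y)]
  expect_lte(length(substantial), 1L)
  # the default two-basin system, by contrast, is bimodal
  ref <- smallRelease(5L, 400L, seed = 9)
  dr <- stats::density(unlist(lapply(ref$features@trajs,
                                     function(m) m[, 1])))
  pr <- which(diff(sign(diff(dr$y))) == -2) + 1L
  expect_gte(length(pr[dr$y[pr] > 0.1 * max(dr$y)]), 2L)
})

test_that("emission fidelity: per-state means within three standard errors", {
  syn <- smallRelease(10L, 1000L, seed = 29)
  pooled <- unlist(lapply(syn$features@trajs, function(m) m[, 1]))
  lab <- unlist(syn$groundTruth@stateLabels)
  for (s in 0:1) {
    mu <- c(3.0, 12.0)[s + 1]
    sd <- c(0.3, 1.0)[s + 1]
    n <- sum(lab == s)
    expect_lt(abs(mean(pooled[lab == s]) - mu), 3 * sd / sqrt(n))
  }
})
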