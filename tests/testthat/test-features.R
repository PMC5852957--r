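test_that("contact map reproduces scheduled geometry and excludes self pairs", {
  ens <- pairBeads(c(6.9, 8.0, 12.0))
  cm <- contactMap(ens, residueSelection(segment = "NTERM"),
                   residueSelection(segment = "CORE"))
  expect_equal(cm@map["NTERM:60", "CORE:436"], 6.9)

  cm2 <- contactMap(ens, residueSelection(), residueSelection())
  expect_true(all(is.na(diag(cm2@map))))
  expect_error(contactMap(ens, residueSelection(segment = "NOPE"),
                          residueSelection()), "zero atoms")
})

test_that("contact map equals the exhaustive brute-force minimum", {
  # multi-atom residues with random scheduled coordinates over 100 frames
  set.seed(31)
  atoms <- data.frame(
    atom = c("N", "CA", "CB", "N", "CA", "OG", "H1"),
    element = c("N", "C", "C", "N", "C", "O", "H"),
    resname = c("ALA", "ALA", "ALA", "SER", "SER", "SER", "SER"),
    resid = c(1L, 1L, 1L, 2L, 2L, 2L, 2L),
    segment = c("A", "A", "A", "B", "B", "B", "B"))
  coords <- array(stats::rnorm(100 * 7 * 3, sd = 5), c(100, 7, 3))
  ens <- beadFrames(atoms, coords)
  cm <- contactMap(ens, residueSelection(segment = "A"),
                   residueSelection(segment = "B"))
  expect_equal(cm@map["A:1", "B:2"], naiveContactMin(ens, "A:1", "B:2"))
  # hydrogen must be ignored: recompute oracle including it and check the
  # implementation did not use it
  atH <- atoms; atH$element[7] <- "O"; atH$atom[7] <- "OX"
  ensH <- beadFrames(atH, coords)
  withH <- naiveContactMin(ensH, "A:1", "B:2")
  expect_gte(cm@map["A:1", "B:2"], withH)
})

test_that("interaction strength honours the inclusive 7 A boundary", {
  dt <- 0.8
  nF <- 50L
  spec <- list(pair = list(query = residueSelection(resid = 60),
                           target = residueSelection(resid = 436)))
  win <- c(0, (nF - 1) * dt)
  inside <- interactionStrength(pairBeads(rep(6.9, nF)), spec,
                                windowNs = win)
  expect_equal(inside$mean, nF)
  expect_equal(inside$sd, 0)
  at7 <- interactionStrength(pairBeads(rep(7.0, nF)), spec, windowNs = win)
  expect_equal(at7$mean, nF)
  outside <- interactionStrength(pairBeads(rep(7.1, nF)), spec,
                                 windowNs = win)
  expect_equal(outside$mean, 0)
})

test_that("interaction strength averages and spreads across trajectories", {
  # trajectory 1: 10 frames in contact; trajectory 2: 20 frames in contact
  d1 <- c(rep(3, 10), rep(20, 30))
  d2 <- c(rep(3, 20), rep(20, 20))
  atoms <- topology(pairBeads(1))
  mk <- function(d) { a <- array(0, c(length(d), 2, 3)); a[, 2, 1] <- d; a }
  ens <- beadFrames(atoms, list(mk(d1), mk(d2)), frameIntervalNs = 1)
  spec <- list(p = list(query = residueSelection(resid = 60),
                        target = residueSelection(resid = 436)))
  tab <- interactionStrength(ens, spec, windowNs = c(0, 39))
  expect_equal(tab$mean, 15)
  expect_equal(tab$sd, 5)           # population sd of {10, 20}
  # invariant to trajectory order
  ens2 <- beadFrames(atoms, list(mk(d2), mk(d1)), frameIntervalNs = 1)
  expect_equal(interactionStrength(ens2, spec, windowNs = c(0, 39))$mean, 15)
  # monotone non-decreasing in cutoff
  lo <- interactionStrength(ens, spec, cutoffA = 2, windowNs = c(0, 39))
  hi <- interactionStrength(ens, spec, cutoffA = 25, windowNs = c(0, 39))
  expect_lte(lo$mean, tab$mean)
  expect_lte(tab$mean, hi$mean)
})

test_that("interaction strength rejects bad residues and empty windows", {
  ens <- pairBeads(rep(3, 10))
  at <- topology(ens); at$resname[1] <- "GLY"
  bad <- beadFrames(at, trajectories(ens)[[1]])
  spec <- list(p = list(query = residueSelection(resid = 60),
                        target = residueSelection(resid = 436)))
  expect_error(interactionStrength(bad, spec, windowNs = c(0, 5)),
               "not a supported charged type")
  expect_error(interactionStrength(ens, spec, windowNs = c(500, 940)),
               "outside the trajectory span")
})

test_that("broken fraction handles degenerate and mixed gates", {
  allClosed <- newGateSeries(list(rep(3, 50), rep(4, 50)), thresholdA = 7)
  bf <- brokenFraction(allClosed, nBoot = 100, seed = 1)
  expect_equal(bf$fraction, 0)
  expect_equal(unname(bf$ci), c(0, 0))

  half <- newGateSeries(list(c(rep(3, 25), rep(9, 25))), thresholdA = 7)
  expect_equal(brokenFraction(half, nBoot = 10, seed = 1)$fraction, 50)
  expect_error(brokenFraction(half, nBoot = 0), "nBoot")
})

test_that("broken fraction stays in range with CI containing the estimate", {
  syn <- smallRelease(10L, 300L, seed = 41)
  for (g in 2:4) {
    gs <- newGateSeries(lapply(syn$features@trajs, function(m) m[, g]),
                        thresholdA = 7)
    bf <- brokenFraction(gs, nBoot = 200, seed = g)
    expect_gte(bf$fraction, 0); expect_lte(bf$fraction, 100)
    expect_gte(bf$fraction, bf$ci[1]); expect_lte(bf$fraction, bf$ci[2])
  }
})

test_that("release coordinate is the per-frame pair distance", {
  atoms <- data.frame(atom = c("NA", "NA"), element = c("NA", "NA"),
                      resname = "SOD", resid = c(901L, 902L),
                      segment = "ION")
  coords <- array(0, c(2, 2, 3))
  coords[2, 2, ] <- c(3, 4, 0)   # 3-4-5 right triangle
  ens <- beadFrames(atoms, coords)
  rc <- releaseCoordinate(ens, residueSelection(resid = 902),
                          residueSelection(resid = 901))
  expect_equal(rc@trajs[[1]][, 1], c(0, 5))
  expect_error(releaseCoordinate(ens, residueSelection(segment = "ION"),
                                 residueSelection(resid = 901)),
               "exactly one atom")
})

test_that("release events respect threshold and debounce", {
  ramp <- seq(0, 20, length.out = 21)      # crosses 10 at frame 12
  ev <- detectReleaseEvents(list(ramp), 10, dwellFrames = 1)
  expect_equal(ev$frame, 12L)
  spike <- c(rep(1, 10), 30, rep(1, 10))
  expect_equal(nrow(detectReleaseEvents(list(spike), 10, dwellFrames = 5)),
               0L)
  sustained <- c(rep(1, 10), rep(30, 6), rep(1, 5))
  expect_equal(detectReleaseEvents(list(sustained), 10, 5)$frame, 11L)
  expect_error(detectReleaseEvents(list(ramp), 10, dwellFrames = 0),
               "dwellFrames")
})

test_that("release events agree with ground-truth basin first passages", {
  syn <- smallRelease(40L, 1000L, seed = 53)
  gt <- syn$groundTruth
  ev <- detectReleaseEvents(lapply(syn$features@trajs, function(m) m[, 1]),
                            gt@metadata$releaseThresholdA,
                            gt@metadata$dwellFrames)
  truth <- vapply(gt@stateLabels, function(s) match(1L, s), integer(1))
  nTrue <- sum(!is.na(truth))
  expect_lt(abs(nrow(ev) - nTrue), max(3, 0.1 * nTrue))
})

test_that("free-energy differences follow -RT log population exactly", {
  # two occupied bins with equal counts: zero difference
  v <- c(rep(0.5, 100), rep(1.5, 100))
  pr <- freeEnergyProfile(list(v), bins = list(c(0, 1, 2)),
                          nBootstrap = 5, frameIntervalNs = 1, seed = 1)
  expect_equal(pr@dG[1], pr@dG[2])
  expect_equal(min(pr@dG), 0)
  # counts ratio 2: difference RT ln 2; back out RT and compare to R*T
  v2 <- c(rep(0.5, 2000), rep(1.5, 1000))
  pr2 <- freeEnergyProfile(list(v2), bins = list(c(0, 1, 2)),
                           temperatureK = 310, nBootstrap = 5,
                           frameIntervalNs = 1, seed = 1)
  RT <- (pr2@dG[2] - pr2@dG[1]) / log(2)
  expect_equal(RT, 0.0019872 * 310, tolerance = 1e-12)
  expect_error(freeEnergyProfile(list(numeric(0)), bins = 5,
                                 frameIntervalNs = 1), "no data")
})

test_that("empty bins are flagged, not assigned finite energies", {
  v <- c(rep(0.5, 50), rep(2.5, 50))
  pr <- freeEnergyProfile(list(v), bins = list(c(0, 1, 2, 3)),
                          nBootstrap = 5, frameIntervalNs = 1, seed = 2)
  expect_true(pr@empty[2])
  expect_true(is.na(pr@dG[2]))
  expect_false(any(is.na(pr@dG[!pr@empty])))
})

test_that("gaussian samples give a quadratic profile with kT curvature", {
  set.seed(61)
  sigma <- 1.3
  v <- stats::rnorm(2e5, sd = sigma)
  pr <- freeEnergyProfile(list(v), bins = list(seq(-2.5, 2.5, by = 0.25)),
                          temperatureK = 310, nBootstrap = 5,
                          frameIntervalNs = 1, seed = 3)
  mid <- pr@mids[[1]]
  fit <- stats::lm(pr@dG ~ mid + I(mid^2))
  RT <- 0.0019872 * 310
  expect_lt(abs(stats::coef(fit)[3] - RT / (2 * sigma^2)) /
              (RT / (2 * sigma^2)), 0.1)
})

test_that("2-d landscapes bin populations consistently with 1-d margins", {
  set.seed(71)
  xy <- cbind(stats::rnorm(5000), stats::rnorm(5000))
  br <- list(seq(-4, 4, by = 1), seq(-4, 4, by = 1))
  pr <- freeEnergyProfile(list(xy), bins = br, nBootstrap = 5,
                          frameIntervalNs = 1, seed = 4)
  expect_equal(dim(pr@dG), c(8L, 8L))
  expect_equal(min(pr@dG, na.rm = TRUE), 0)
  expect_equal(dim(pr@error), dim(pr@dG))
})
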