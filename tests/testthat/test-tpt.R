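# build a MarkovModel directly from a known TPM (counts scaled up)
modelFromTPM <- function(tpm, scale = 1e9) {
  transitionMatrix(tpm * scale, lagNs = 1, frameIntervalNs = 1)
}

test_that("PCCA+ recovers metastable blocks and degenerate limits", {
  bc <- blockChain(c(2, 2), eps = 1e-3, seed = 11)
  m <- modelFromTPM(bc$tpm)
  mac <- pccaLump(m, 2)
  expect_equal(length(unique(mac@membership[bc$block == 1])), 1L)
  expect_equal(length(unique(mac@membership[bc$block == 2])), 1L)
  expect_equal(rowSums(mac@memberships), rep(1, 4), tolerance = 1e-9)

  # identity lumping: as many macrostates as (metastable) microstates
  bi <- blockChain(c(1, 1, 1, 1), eps = 1e-3, seed = 12)
  maci <- pccaLump(modelFromTPM(bi$tpm), 4)
  expect_equal(sort(unique(maci@membership)), 1:4)

  expect_error(pccaLump(m, 10), "positive real part")
})

test_that("PCCA+ block recovery is exact for 2 to 5 blocks", {
  for (nb in 2:5) {
    sizes <- rep(3, nb)
    bc <- blockChain(sizes, eps = 1e-3, seed = 20 + nb)
    mac <- pccaLump(modelFromTPM(bc$tpm), nb)
    # crisp lumping equals the generating blocks up to label permutation
    expect_equal(length(unique(paste(mac@membership, bc$block))), nb)
    expect_equal(sum(mac@pi), 1, tolerance = 1e-9)
    checkStochasticMatrix(mac@tpm, tol = 1e-9)
  }
})

test_that("macrostate aggregation weights microstates by pi", {
  bc <- blockChain(c(2, 2), eps = 1e-2, seed = 31)
  m <- modelFromTPM(bc$tpm)
  mac <- pccaLump(m, 2)
  a <- which(mac@membership == 1)
  b <- which(mac@membership == 2)
  expect_equal(mac@pi[1], sum(m@pi[a]), tolerance = 1e-9)
  hand <- sum(m@pi[a] * rowSums(m@tpm[a, b, drop = FALSE])) / sum(m@pi[a])
  expect_equal(mac@tpm[1, 2], hand, tolerance = 1e-12)
})

test_that("committors solve symmetric and biased chains in closed form", {
  lin <- matrix(c(0.5, 0.5, 0.0,
                  0.5, 0.0, 0.5,
                  0.0, 0.5, 0.5), 3, byrow = TRUE)
  m <- modelFromTPM(lin)
  q <- committors(m, A = 1, B = 3)
  expect_equal(q$qplus, c(0, 0.5, 1), tolerance = 1e-12)

  biased <- matrix(c(0.5, 0.5, 0.0,
                     0.2, 0.0, 0.8,
                     0.0, 0.2, 0.8), 3, byrow = TRUE)
  qb <- committors(modelFromTPM(biased), A = 1, B = 3)
  expect_equal(qb$qplus[2], 0.8, tolerance = 1e-12)  # gambler's ruin

  expect_error(committors(m, A = 1, B = 1), "disjoint")
  expect_error(committors(m, A = integer(0), B = 3), "non-empty")
})

test_that("forward and backward committors sum to 1 for reversible chains", {
  for (s in 1:4) {
    ch <- reversibleChain(5, seed = 40 + s)
    m <- modelFromTPM(ch$tpm)
    q <- committors(m, A = 1, B = 5)
    expect_equal(q$qplus + q$qminus, rep(1, 5), tolerance = 1e-9)
  }
})

test_that("two-state flux equals pi_A T_AB and conservation holds", {
  tpm <- matrix(c(0.9, 0.1, 0.3, 0.7), 2, byrow = TRUE)
  m <- modelFromTPM(tpm)
  fx <- fluxNetwork(m, 1, 2)
  expect_equal(fx@totalFlux, m@pi[1] * tpm[1, 2], tolerance = 1e-12)

  for (s in 1:5) {
    ch <- randomChain(6, seed = 50 + s)
    m6 <- modelFromTPM(ch$tpm)
    fx6 <- fluxNetwork(m6, 1, 6)
    inter <- 2:5
    imbalance <- rowSums(fx6@net)[inter] - colSums(fx6@net)[inter]
    expect_lt(max(abs(imbalance)), 1e-9)
  }
})

test_that("total flux is symmetric under exchanging source and sink for reversible chains", {
  ch <- reversibleChain(5, seed = 61)
  m <- modelFromTPM(ch$tpm)
  f1 <- fluxNetwork(m, 1, 5)@totalFlux
  f2 <- fluxNetwork(m, 5, 1)@totalFlux
  expect_equal(f1, f2, tolerance = 1e-10)
})

test_that("pathway decomposition handles linear and branched networks", {
  lin <- matrix(c(0.9, 0.1, 0.0,
                  0.0, 0.9, 0.1,
                  0.1, 0.0, 0.9), 3, byrow = TRUE)
  m <- modelFromTPM(lin)
  pw <- topPathways(fluxNetwork(m, 1, 3), 5)
  expect_equal(nrow(pw@table), 1L)
  expect_equal(pw@table$fraction, 1, tolerance = 1e-9)
  expect_equal(pw@paths[[1]], c(1, 2, 3))

  # source -> {fast, slow} -> sink with 3:1 branch capacities
  eps <- 0.001
  br <- matrix(c(0.996, 3 * eps, eps, 0.0,
                 0.0,   0.999,   0.0, eps,
                 0.0,   0.0,     0.999, eps,
                 0.5,   0.0,     0.0, 0.5), 4, byrow = TRUE)
  pwb <- topPathways(fluxNetwork(modelFromTPM(br), 1, 4), 5)
  expect_equal(pwb@table$fraction[1], 0.75, tolerance = 1e-6)
  expect_equal(pwb@table$fraction[2], 0.25, tolerance = 1e-6)
  expect_true(all(diff(pwb@table$fraction) <= 1e-12))
})

test_that("TPT quantities match brute-force references on small chains", {
  for (s in 1:20) {
    n <- 3 + (s %% 4)
    ch <- randomChain(n, seed = 70 + s)
    m <- modelFromTPM(ch$tpm)
    A <- 1; B <- n
    q <- committors(m, A, B)
    expect_equal(q$qplus, oracleCommittor(ch$tpm, A, B), tolerance = 1e-9)
    expect_equal(q$qminus, oracleBackwardCommittor(ch$tpm, ch$pi, A, B),
                 tolerance = 1e-9)
    fx <- fluxNetwork(m, A, B)
    pw <- topPathways(fx, 10)
    oracle <- oracleDecomposition(fx@net, A, B, 10)
    expect_equal(length(pw@paths), length(oracle$paths))
    expect_equal(pw@table$flux, oracle$fluxes, tolerance = 1e-9)
    expect_equal(lapply(pw@paths, as.integer),
                 lapply(oracle$paths, as.integer))
  }
})

test_that("pathway grouping sums fractions by intermediate annotations", {
  eps <- 0.001
  br <- matrix(c(0.996, 3 * eps, eps, 0.0,
                 0.0,   0.999,   0.0, eps,
                 0.0,   0.0,     0.999, eps,
                 0.5,   0.0,     0.0, 0.5), 4, byrow = TRUE)
  pw <- topPathways(fluxNetwork(modelFromTPM(br), 1, 4), 5)
  g <- pathwayGrouping(pw, c(`2` = "gateA", `3` = "gateB"))
  expect_equal(g$fraction[g$group == "gateA"], 0.75, tolerance = 1e-6)
  expect_equal(g$fraction[g$group == "gateB"], 0.25, tolerance = 1e-6)
  one <- pathwayGrouping(pw, c(`2` = "all", `3` = "all"))
  expect_equal(sum(one$fraction), max(pw@table$cumulative),
               tolerance = 1e-12)
  expect_error(pathwayGrouping(pw, c(`2` = "gateA")), "no annotation")
})

test_that("three-channel release fluxes rank by ground-truth channel rates", {
  # A -> {c1, c2, c3} -> B with channel rates 5:3:1
  r <- c(0.005, 0.003, 0.001)
  tpm <- rbind(
    c(1 - sum(r), r, 0),
    c(0, 0.995, 0, 0, 0.005),
    c(0, 0, 0.995, 0, 0.005),
    c(0, 0, 0, 0.995, 0.005),
    c(0.05, 0, 0, 0, 0.95))
  pw <- topPathways(fluxNetwork(modelFromTPM(tpm), 1, 5), 10)
  g <- pathwayGrouping(pw, c(`2` = "c1", `3` = "c2", `4` = "c3"))
  expect_equal(g$group, c("c1", "c2", "c3"))
})
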