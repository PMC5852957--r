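#' @include AllClasses.R synthetic.R features.R tica.R msm.R pcca.R tpt.R io.R
NULL

.defaultPipelineConfig <- function() {
  list(
    synthetic = list(nTrajectories = 50L, nFrames = 1000L,
                     frameIntervalNs = 0.8, seed = 1L),
    input = NULL,
    gates = list(features = c("R60-D436", "E428-R445", "K66-D345"),
                 thresholdA = 7),
    release = list(coordinate = "na2_distance", thresholdA = 7.5,
                   dwellFrames = 5L),
    freeEnergy = list(bins = 50, temperatureK = 310, blockNs = 160,
                      nBlocks = 100, nBootstrap = 50, seed = 101L),
    tica = list(lagNs = 16, nComponents = 2),
    cluster = list(nStates = 100L, seed = 7L),
    msm = list(lagsNs = c(0.8, 1.6, 3.2, 4.8, 8, 16), lagNs = NULL,
               nTimescales = 3),
    macro = list(nMacrostates = 2L),
    tpt = list(maxPaths = 10),
    bootstrap = list(nBoot = 1000L, seed = 11L),
    outputDir = NULL)
}

#' Validate a pipeline configuration
#'
#' Fills defaults, then fails fast: every stage that draws random numbers
#' must carry an explicit seed, and every referenced feature name must be
#' resolvable before any computation starts.
#'
#' @param config list, or path to a YAML/JSON config file.
#' @return the completed config list.
#' @export
validatePipelineConfig <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(.defaultPipelineConfig(), config,
                           keep.null = TRUE)
  for (field in c("cluster", "bootstrap"))
    if (is.null(cfg[[field]]$seed))
      .stopf("config stage '%s' has no seed; every stochastic stage needs one",
             field)
  if (is.null(cfg$input) && is.null(cfg$synthetic$seed))
    .stopf("config stage 'synthetic' has no seed")
  cfg
}

.writeStage <- function(outputDir, name, obj) {
  if (is.null(outputDir)) return(invisible(NULL))
  dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
  f <- file.path(outputDir, paste0(name, if (is.data.frame(obj)) ".csv"
                                   else ".json"))
  if (is.data.frame(obj)) utils::write.csv(obj, f, row.names = FALSE)
  else jsonlite::write_json(obj, f, auto_unbox = TRUE, digits = NA,
                            force = TRUE)
  invisible(f)
}

#' Run the full trajectory-ensemble analysis pipeline
#'
#' Orchestrates, in order: input (synthetic generation or container read),
#' gate broken fractions with trajectory bootstrap, release-event detection,
#' a 1-d free-energy profile of the release coordinate, tICA reduction,
#' microstate clustering, implied-timescale validation and Markov-model
#' estimation, PCCA+ lumping, and transition-path flux/pathway analysis with
#' source/sink sets defined by the release coordinate averaged over each
#' macrostate. Every stage's tabular output is persisted to
#' \code{config$outputDir} as it completes, so a failed stage leaves prior
#' outputs intact.
#'
#' @param config list or config file path; see
#'   \code{\link{validatePipelineConfig}}.
#' @return a \linkS4class{ReportBundle}.
#' @export
runPipeline <- function(config) {
  cfg <- validatePipelineConfig(config)
  out <- cfg$outputDir
  res <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      .stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  inp <- stage("input", {
    if (!is.null(cfg$input)) {
      list(features = readEnsemble(cfg$input))
    } else {
      syn <- releaseSystem(syntheticSpec(
        nTrajectories = cfg$synthetic$nTrajectories,
        nFrames = cfg$synthetic$nFrames,
        frameIntervalNs = cfg$synthetic$frameIntervalNs,
        seed = cfg$synthetic$seed,
        generator = "release_system",
        params = cfg$synthetic$params %||% list()))
      list(features = syn$features, groundTruth = syn$groundTruth,
           structures = syn$structures)
    }
  })
  feats <- inp$features
  res$groundTruth <- inp$groundTruth
  res$structures <- inp$structures
  if (!is(feats, "FeatureEnsemble"))
    .stopf("pipeline stage 'input' must yield a feature ensemble")
  need <- c(cfg$gates$features, cfg$release$coordinate)
  missing <- setdiff(need, featureNames(feats))
  if (length(missing))
    .stopf("config references features absent from the ensemble: %s",
           paste(missing, collapse = ", "))
  res$features <- feats

  res$brokenFractions <- stage("gates", {
    rows <- lapply(seq_along(cfg$gates$features), function(i) {
      gname <- cfg$gates$features[i]
      gs <- newGateSeries(lapply(feats@trajs, function(m) m[, gname]),
                          thresholdA = cfg$gates$thresholdA, name = gname,
                          frameIntervalNs = feats@frameIntervalNs)
      bf <- brokenFraction(gs, nBoot = cfg$bootstrap$nBoot,
                           seed = deriveSeed(cfg$bootstrap$seed, i))
      data.frame(gate = gname, fraction_pct = bf$fraction,
                 ci_lo = bf$ci[1], ci_hi = bf$ci[2])
    })
    do.call(rbind, rows)
  })
  .writeStage(out, "broken_fractions", res$brokenFractions)

  coordSeries <- lapply(feats@trajs, function(m) m[, cfg$release$coordinate])
  res$releaseEvents <- stage("release_events",
    detectReleaseEvents(coordSeries, cfg$release$thresholdA,
                        cfg$release$dwellFrames))
  .writeStage(out, "release_events", res$releaseEvents)

  res$freeEnergy <- stage("free_energy", freeEnergyProfile(
    coordSeries, bins = cfg$freeEnergy$bins,
    temperatureK = cfg$freeEnergy$temperatureK,
    blockNs = cfg$freeEnergy$blockNs, nBlocks = cfg$freeEnergy$nBlocks,
    nBootstrap = cfg$freeEnergy$nBootstrap, seed = cfg$freeEnergy$seed,
    frameIntervalNs = feats@frameIntervalNs))
  .writeStage(out, "free_energy", data.frame(
    mid = res$freeEnergy@mids[[1]], dG_kcal_mol = res$freeEnergy@dG,
    error = res$freeEnergy@error))

  res$tica <- stage("tica", runTica(feats, lagNs = cfg$tica$lagNs))
  reduced <- stage("tica", projectTica(feats, res$tica,
                                       nComponents = cfg$tica$nComponents))
  res$reduced <- reduced

  res$dtrajs <- stage("cluster",
    clusterMicrostates(reduced, nStates = cfg$cluster$nStates,
                       seed = cfg$cluster$seed))

  res$impliedTimescales <- stage("msm",
    impliedTimescales(res$dtrajs, cfg$msm$lagsNs,
                      nTimescales = cfg$msm$nTimescales))
  .writeStage(out, "implied_timescales", res$impliedTimescales)
  res$markovianity <- stage("msm", suppressWarnings(
    markovianityCheck(res$impliedTimescales)))
  chosenLag <- cfg$msm$lagNs %||%
    (if (res$markovianity$found) res$markovianity$plateauLagNs
     else min(cfg$msm$lagsNs))
  res$chosenLagNs <- chosenLag
  res$model <- stage("msm", estimateMarkovModel(res$dtrajs, chosenLag))

  res$macro <- stage("pcca", pccaLump(res$model, cfg$macro$nMacrostates))

  res <- c(res, stage("tpt", {
    # mean release coordinate per active microstate, then per macrostate
    pooledStates <- unlist(lapply(res$dtrajs@dtrajs, identity))
    pooledCoord <- unlist(coordSeries)
    microMean <- vapply(res$model@activeSet, function(s)
      mean(pooledCoord[pooledStates == s]), numeric(1))
    p <- res$model@pi
    macroCoord <- vapply(seq_len(res$macro@nMacrostates), function(a) {
      ia <- which(res$macro@membership == a)
      sum(microMean[ia] * p[ia]) / sum(p[ia])
    }, numeric(1))
    A <- which(macroCoord <= cfg$release$thresholdA)
    B <- which(macroCoord > cfg$release$thresholdA)
    if (!length(A) || !length(B))
      .stopf("macrostates do not span both sides of the release threshold")
    fx <- fluxNetwork(res$macro, A, B)
    pw <- topPathways(fx, maxPaths = cfg$tpt$maxPaths)
    list(macroCoordinate = macroCoord, flux = fx, pathways = pw)
  }))
  .writeStage(out, "pathways", res$pathways@table)

  prov <- list(packageVersion = as.character(utils::packageVersion("msmflux")),
               seeds = list(synthetic = cfg$synthetic$seed,
                            cluster = cfg$cluster$seed,
                            bootstrap = cfg$bootstrap$seed),
               chosenLagNs = chosenLag)
  if (!is.null(out)) {
    cfgFile <- file.path(out, "config.json")
    jsonlite::write_json(cfg, cfgFile, auto_unbox = TRUE, digits = NA,
                         force = TRUE)
    prov$configHash <- unname(tools::md5sum(cfgFile))
  }
  new("ReportBundle", results = res, config = cfg, provenance = prov)
}

#' Compare pipeline report bundles across conditions
#'
#' Side-by-side tables of broken-gate fractions (with bootstrap CIs),
#' slowest implied timescales and pathway flux fractions for bundles run
#' under different conditions but shared definitions.
#'
#' @param bundles list of \linkS4class{ReportBundle}s.
#' @param labels character vector, one label per bundle.
#' @return list of data.frames: \code{brokenFractions},
#'   \code{slowestTimescaleNs}, \code{pathwayFractions}.
#' @export
compareConditions <- function(bundles, labels) {
  if (length(bundles) != length(labels))
    .stopf("got %d bundles but %d labels", length(bundles), length(labels))
  gateSets <- lapply(bundles, function(b) b@results$brokenFractions$gate)
  for (i in seq_along(bundles)[-1])
    if (!identical(gateSets[[i]], gateSets[[1]]))
      .stopf("bundle '%s' has gate definitions (%s) differing from '%s' (%s)",
             labels[i], paste(gateSets[[i]], collapse = ","),
             labels[1], paste(gateSets[[1]], collapse = ","))
  featSets <- lapply(bundles, function(b) featureNames(b@results$features))
  for (i in seq_along(bundles)[-1])
    if (!identical(featSets[[i]], featSets[[1]]))
      .stopf("bundle '%s' has feature definitions differing from '%s': %s vs %s",
             labels[i], labels[1], paste(featSets[[i]], collapse = ","),
             paste(featSets[[1]], collapse = ","))

  bf <- do.call(rbind, lapply(seq_along(bundles), function(i) {
    d <- bundles[[i]]@results$brokenFractions
    d$condition <- labels[i]
    d
  }))
  slow <- data.frame(
    condition = labels,
    lag_ns = vapply(bundles, function(b) b@results$chosenLagNs, numeric(1)),
    slowest_timescale_ns = vapply(bundles, function(b) {
      its <- b@results$impliedTimescales
      its$timescale_ns[its$index == 2 &
                         its$lag_ns == b@results$chosenLagNs][1]
    }, numeric(1)))
  pf <- do.call(rbind, lapply(seq_along(bundles), function(i) {
    d <- bundles[[i]]@results$pathways@table
    d$condition <- labels[i]
    d
  }))
  list(brokenFractions = bf, slowestTimescaleNs = slow,
       pathwayFractions = pf)
}
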