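#' @include AllClasses.R utils.R
NULL

.CONTAINER_VERSION <- "1.0"

#' Write a trajectory ensemble to the neutral directory container
#'
#' One directory per ensemble: \code{metadata.json} (kind, frame interval,
#' container version), \code{topology.tsv} for structure ensembles, and one
#' \code{traj_NNN.csv} per trajectory (feature matrices, or flattened
#' x/y/z coordinate columns). All files are plain text; the round-trip
#' contract on coordinates is 32-bit float precision.
#'
#' @param ensemble a \linkS4class{StructureEnsemble} or
#'   \linkS4class{FeatureEnsemble}.
#' @param path directory to create (overwritten if it exists).
#' @return \code{path}, invisibly.
#' @export
writeEnsemble <- function(ensemble, path) {
  ok <- dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) .stopf("cannot create container directory '%s'", path)
  isStruct <- is(ensemble, "StructureEnsemble")
  nT <- nTrajectories(ensemble)
  meta <- list(container_version = .CONTAINER_VERSION,
               kind = if (isStruct) "structure" else "feature",
               frame_interval_ns = ensemble@frameIntervalNs,
               n_trajectories = nT)
  if (isStruct) {
    at <- ensemble@topology@atoms
    meta$n_atoms <- nrow(at)
    utils::write.table(at, file.path(path, "topology.tsv"), sep = "\t",
                       row.names = FALSE, quote = TRUE)
  } else {
    meta$feature_names <- as.list(ensemble@featureNames)
  }
  jsonlite::write_json(meta, file.path(path, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  for (i in seq_len(nT)) {
    f <- file.path(path, sprintf("traj_%03d.csv", i))
    if (isStruct) {
      x <- ensemble@coords[[i]]
      flat <- matrix(aperm(x, c(1, 3, 2)), nrow = dim(x)[1])
      cn <- as.vector(t(outer(seq_len(dim(x)[2]), c("x", "y", "z"),
                              function(a, b) paste0("a", a, "_", b))))
      colnames(flat) <- cn
      utils::write.csv(flat, f, row.names = FALSE)
    } else {
      utils::write.csv(ensemble@trajs[[i]], f, row.names = FALSE)
    }
  }
  invisible(path)
}

#' Read a trajectory ensemble
#'
#' Reads either the neutral directory container written by
#' \code{\link{writeEnsemble}} (\code{format = "container"}) or, as an
#' optional adapter, a PDB topology plus coordinate files
#' (\code{format = "pdb"}, requires the \pkg{bio3d} package).
#'
#' @param paths for \code{"container"}: the container directory. For
#'   \code{"pdb"}: character vector whose first element is the PDB file and
#'   whose remainder are DCD coordinate files (one trajectory each).
#' @param format \code{"container"} (default) or \code{"pdb"}.
#' @param frameIntervalNs frame interval for adapter-read trajectories (the
#'   container stores its own).
#' @return a \linkS4class{StructureEnsemble} or \linkS4class{FeatureEnsemble}.
#' @export
readEnsemble <- function(paths, format = "container", frameIntervalNs = 1) {
  if (!format %in% c("container", "pdb"))
    .stopf("unknown format '%s'; supported formats: container, pdb", format)
  if (format == "pdb") return(.readPDBEnsemble(paths, frameIntervalNs))
  path <- paths[1]
  metaFile <- file.path(path, "metadata.json")
  if (!file.exists(metaFile))
    .stopf("'%s' is not an ensemble container (no metadata.json); supported formats: container, pdb",
           path)
  meta <- jsonlite::read_json(metaFile, simplifyVector = TRUE)
  files <- sort(list.files(path, pattern = "^traj_[0-9]+\\.csv$",
                           full.names = TRUE))
  if (length(files) != meta$n_trajectories)
    .stopf("container '%s' lists %d trajectories but has %d files",
           path, meta$n_trajectories, length(files))
  if (meta$kind == "structure") {
    at <- utils::read.table(file.path(path, "topology.tsv"), sep = "\t",
                            header = TRUE, colClasses = "character",
                            na.strings = character(0))
    at$resid <- as.integer(at$resid)
    nAtoms <- nrow(at)
    coords <- lapply(files, function(f) {
      flat <- as.matrix(utils::read.csv(f))
      if (ncol(flat) != 3L * nAtoms)
        .stopf("schema mismatch in '%s': %d coordinate columns, topology has %d atoms",
               f, ncol(flat), nAtoms)
      aperm(array(flat, dim = c(nrow(flat), 3, nAtoms)), c(1, 3, 2))
    })
    new("StructureEnsemble", coords = coords,
        topology = new("Topology", atoms = at),
        frameIntervalNs = meta$frame_interval_ns)
  } else {
    fn <- unlist(meta$feature_names)
    trajs <- lapply(files, function(f) {
      m <- as.matrix(utils::read.csv(f, check.names = FALSE))
      if (!identical(colnames(m), fn))
        .stopf("schema mismatch in '%s': features (%s) differ from container schema (%s)",
               f, paste(colnames(m), collapse = ","),
               paste(fn, collapse = ","))
      m
    })
    new("FeatureEnsemble", trajs = trajs, featureNames = fn,
        frameIntervalNs = meta$frame_interval_ns)
  }
}

# optional adapter: PDB topology (+ DCD coordinates) through bio3d
.readPDBEnsemble <- function(paths, frameIntervalNs) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    .stopf("format 'pdb' requires the bio3d package")
  pdb <- bio3d::read.pdb(paths[1])
  sel <- pdb$atom
  at <- data.frame(atom = sel$elety,
                   element = ifelse(is.na(sel$elesy) | sel$elesy == "",
                                    substr(sel$elety, 1, 1), sel$elesy),
                   resname = sel$resid, resid = sel$resno,
                   segment = ifelse(is.na(sel$chain) | sel$chain == "",
                                    "A", sel$chain),
                   stringsAsFactors = FALSE)
  coordFiles <- paths[-1]
  if (!length(coordFiles)) {
    xyz <- matrix(pdb$xyz, nrow = 1)
    coords <- list(aperm(array(t(xyz), dim = c(3, nrow(at), 1)), c(3, 2, 1)))
  } else {
    coords <- lapply(coordFiles, function(f) {
      xyz <- bio3d::read.dcd(f, verbose = FALSE)
      if (ncol(xyz) != 3L * nrow(at))
        .stopf("schema mismatch in '%s': %d coordinates for %d atoms",
               f, ncol(xyz), nrow(at))
      aperm(array(t(xyz), dim = c(3, nrow(at), nrow(xyz))), c(3, 2, 1))
    })
  }
  new("StructureEnsemble", coords = coords,
      topology = new("Topology", atoms = at),
      frameIntervalNs = frameIntervalNs)
}

#' Export a feature ensemble as per-trajectory CSV files
#'
#' @param ensemble a \linkS4class{FeatureEnsemble}.
#' @param dir output directory.
#' @return character vector of written file paths, invisibly.
#' @export
exportFeaturesCSV <- function(ensemble, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(nTrajectories(ensemble))
  for (i in seq_along(files)) {
    files[i] <- file.path(dir, sprintf("features_%03d.csv", i))
    utils::write.csv(ensemble@trajs[[i]], files[i], row.names = FALSE)
  }
  invisible(files)
}
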