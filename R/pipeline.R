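# Pipeline stage runners: each takes inputs plus tuning parameters, writes
# TSV/JSON outputs under an output directory, and records a JSON manifest
# (config snapshot, package version, output hashes, warnings). Stages are
# deterministic, so identical inputs and configuration reproduce identical
# output bytes; the manifest deliberately carries no timestamps.

.collectWarnings <- function(expr) {
  warns <- character(0)
  val <- withCallingHandlers(expr, warning = function(w) {
    warns <<- c(warns, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  list(value = val, warnings = warns)
}

.writeManifest <- function(outDir, stage, config, files, warnings) {
  man <- list(stage = stage,
              package = "gatemech",
              version = as.character(utils::packageVersion("gatemech")),
              config = config,
              outputs = as.list(tools::md5sum(files)),
              warnings = warnings)
  path <- file.path(outDir, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  path
}

.tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the GNM stage: structure -> modes, fluctuations, hinge report
#'
#' @param structure a \linkS4class{ProteinStructure} or path to a PDB file.
#' @param outDir output directory (created if needed).
#' @param rc contact cutoff, Angstrom.
#' @param zeroBand hinge near-zero band (fraction of max mode amplitude).
#' @param modeIndices modes used for shapes and hinge detection.
#' @param force analyse despite a disconnected network.
#' @return invisibly, a list with the per-residue report, the
#'   \linkS4class{GNMModes}, and the output paths.
#' @export
runGNM <- function(structure, outDir, rc = 7.3, zeroBand = 0.1,
                   modeIndices = c(1L, 2L), force = FALSE) {
  if (is.character(structure)) structure <- readPDB(structure)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  cw <- .collectWarnings({
    k <- buildKirchhoff(structure, rc = rc)
    if (k@nComponents > 1L && !force)
      stop("contact network is disconnected (", k@nComponents,
           " components); rerun with force = TRUE to analyse anyway")
    modes <- gnmModes(k)
    report <- gnmReport(modes, modeIndices, zeroBand, force = force)
    list(k = k, modes = modes, report = report)
  })
  res <- cw$value
  f1 <- .tsv(res$report, file.path(outDir, "gnm_report.tsv"))
  spec <- list(eigenvalues = res$modes@eigenvalues,
               n_zero = res$modes@nZero, rc = rc,
               n_components = res$k@nComponents)
  f2 <- file.path(outDir, "spectrum.json")
  jsonlite::write_json(spec, f2, auto_unbox = TRUE, digits = NA)
  config <- list(rc = rc, zeroBand = zeroBand, modeIndices = modeIndices,
                 force = force, nResidues = length(res$modes@nodeIds))
  mf <- .writeManifest(outDir, "gnm", config, c(f1, f2), cw$warnings)
  invisible(list(report = res$report, modes = res$modes,
                 files = c(f1, f2, mf), warnings = cw$warnings))
}

#' Run the gating stage: trajectories -> distance/rotamer reports
#'
#' Computes per-run centre-of-mass distance series for a gating pair,
#' pools them into a shared histogram, and (optionally) classifies the
#' chi1 rotamer of a selected residue and reports gate-closure times.
#'
#' @param trajectories named list of \linkS4class{CoordTrajectory} (names
#'   become run ids) or of paths to multi-model PDB files.
#' @param pair length-2 character: the two residue selectors of the gate.
#' @param outDir output directory.
#' @param atomScope COM atom scope (see \code{\link{comDistance}}).
#' @param binWidth histogram bin width, Angstrom.
#' @param rotamerResidue optional residue selector for chi1 analysis.
#' @param states rotamer state definitions.
#' @param closedThreshold optional closure threshold, Angstrom; when given,
#'   closure times are reported (requires dt on every trajectory).
#' @param dwellFrames closure dwell requirement, frames.
#' @param dt frame interval used when reading trajectories from paths.
#' @return invisibly, a list with the distance series, histogram,
#'   occupancies, closure table and output paths.
#' @export
runGates <- function(trajectories, pair, outDir,
                     atomScope = "sidechain", binWidth = 0.25,
                     rotamerResidue = NULL, states = rotamerStates(),
                     closedThreshold = NULL, dwellFrames = 5L,
                     dt = NA_real_) {
  stopifnot(length(pair) == 2L, length(trajectories) >= 1L)
  if (is.null(names(trajectories)) || any(!nzchar(names(trajectories))))
    names(trajectories) <- paste0("run", seq_along(trajectories))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  cw <- .collectWarnings({
    trajs <- lapply(trajectories, function(tr)
      if (is.character(tr)) readTrajectory(tr, dt = dt) else tr)
    series <- lapply(names(trajs), function(id)
      comDistance(trajs[[id]], pair[1L], pair[2L], atomScope = atomScope,
                  runId = id))
    hist <- pooledHistogram(series, binWidth = binWidth)
    closure <- NULL
    if (!is.null(closedThreshold)) {
      if (any(vapply(trajs, function(t) is.na(t@dt), logical(1))))
        stop("closure times requested but a trajectory has no frame ",
             "interval; supply dt")
      closure <- data.frame(
        run = names(trajs),
        closure_ns = vapply(series, gateClosureTime, numeric(1),
                            closedThreshold = closedThreshold,
                            dwellFrames = dwellFrames))
    }
    occ <- NULL
    if (!is.null(rotamerResidue)) {
      rot <- lapply(names(trajs), function(id)
        chi1Series(trajs[[id]], rotamerResidue, runId = id))
      cls <- lapply(rot, classifyRotamer, states = states)
      occ <- do.call(rbind, lapply(seq_along(cls), function(i)
        data.frame(run = names(trajs)[i],
                   state = names(cls[[i]]$occupancy),
                   occupancy = unname(cls[[i]]$occupancy))))
    }
    list(series = series, hist = hist, occ = occ, closure = closure)
  })
  res <- cw$value
  files <- character(0)
  for (s in res$series)
    files <- c(files, writeSeriesTSV(
      s, file.path(outDir, paste0("com_distance_", s@runId, ".tsv"))))
  files <- c(files, .tsv(histogramTable(res$hist),
                         file.path(outDir, "pooled_histogram.tsv")))
  files <- c(files, .tsv(histogramTable(res$hist, cumulative = TRUE),
                         file.path(outDir, "pooled_cdf.tsv")))
  if (!is.null(res$occ))
    files <- c(files, .tsv(res$occ, file.path(outDir, "occupancy.tsv")))
  if (!is.null(res$closure))
    files <- c(files, .tsv(res$closure,
                           file.path(outDir, "closure_times.tsv")))
  config <- list(pair = pair, atomScope = atomScope, binWidth = binWidth,
                 rotamerResidue = rotamerResidue,
                 closedThreshold = closedThreshold,
                 dwellFrames = dwellFrames,
                 runs = names(trajectories))
  mf <- .writeManifest(outDir, "gates", config, files, cw$warnings)
  invisible(c(res, list(files = c(files, mf), warnings = cw$warnings)))
}

#' Read a three-chain trimer model from a PDB file
#'
#' Splits the structure by chain into three monomers with matching
#' residue/atom rosters.
#'
#' @param path PDB file with exactly three chains.
#' @param membrane a \linkS4class{MembraneFrame}.
#' @param clusterId,clusterSize cluster metadata.
#' @return a \linkS4class{TrimerModel}.
#' @export
readTrimerPDB <- function(path, membrane = membraneFrame(),
                          clusterId = basename(path), clusterSize = 1L) {
  s <- readPDB(path)
  chains <- unique(s@atoms$chain)
  if (length(chains) != 3L)
    stop("trimer PDB must contain exactly 3 chains; found ",
         length(chains), " in ", path)
  monomers <- lapply(chains, function(ch) {
    rows <- s@atoms$chain == ch
    new("ProteinStructure", atoms = s@atoms[rows, , drop = FALSE],
        coords = s@coords[rows, , drop = FALSE], title = s@title)
  })
  new("TrimerModel", monomers = monomers, membrane = membrane,
      clusterId = as.character(clusterId),
      clusterSize = as.integer(clusterSize))
}

#' Run the trimer-filter stage: candidate models -> ranked filter report
#'
#' @param models list of \linkS4class{TrimerModel}s, or a manifest
#'   data.frame with columns model_path, cluster_id, cluster_size (model
#'   files read with \code{\link{readTrimerPDB}}).
#' @param outDir output directory.
#' @param membrane membrane frame used when reading models from paths.
#' @param ... passed to \code{\link{rankAndFilter}} (criteria, c3Bound,
#'   bandWidth, trpThreshold, nSpan, cSpan).
#' @return invisibly, the \code{\link{rankAndFilter}} result plus output
#'   paths.
#' @export
runTrimerFilter <- function(models, outDir, membrane = membraneFrame(),
                            ...) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (is.data.frame(models)) {
    need <- c("model_path", "cluster_id", "cluster_size")
    if (!all(need %in% names(models)))
      stop("model manifest must have columns: ", paste(need, collapse = ", "))
    if (nrow(models) == 0L) stop("empty model manifest")
    models <- lapply(seq_len(nrow(models)), function(i)
      readTrimerPDB(models$model_path[i], membrane,
                    models$cluster_id[i], models$cluster_size[i]))
  }
  cw <- .collectWarnings(rankAndFilter(models, ...))
  res <- cw$value
  f1 <- .tsv(res$report, file.path(outDir, "filter_report.tsv"))
  surv <- res$report[res$report$pass, c("rank", "cluster_id",
                                        "cluster_size"), drop = FALSE]
  f2 <- .tsv(surv, file.path(outDir, "survivors.tsv"))
  config <- c(list(nModels = length(models)), list(...))
  mf <- .writeManifest(outDir, "trimer_filter", config, c(f1, f2),
                       cw$warnings)
  invisible(c(res, list(files = c(f1, f2, mf), warnings = cw$warnings)))
}

#' Generate synthetic fixtures on disk
#'
#' Writes the requested fixture as PDB plus TSV ground truth and a JSON
#' manifest recording the generator parameters (including the seed), so a
#' fixture directory is self-describing and regenerable.
#'
#' @param what one of "dumbbell", "gate", "rotamer", "trimer_set",
#'   "path".
#' @param outDir output directory.
#' @param seed RNG seed.
#' @param ... generator parameters forwarded to the corresponding
#'   \code{make*} function.
#' @return invisibly, list of written paths.
#' @export
runSimulate <- function(what = c("dumbbell", "gate", "rotamer",
                                 "trimer_set", "path"),
                        outDir, seed = 1L, ...) {
  what <- match.arg(what)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  args <- list(...)
  files <- character(0)
  truth <- NULL
  switch(what,
    dumbbell = {
      g <- do.call(makeDumbbell, c(list(seed = seed), args))
      files <- writePDB(g$structure, file.path(outDir, "dumbbell.pdb"))
      truth <- data.frame(hinge_residue = g$hinge)
    },
    gate = {
      g <- do.call(makeGateTrajectory, c(list(seed = seed), args))
      files <- writePDB(g$trajectory, file.path(outDir, "gate.pdb"))
      truth <- data.frame(frame = seq_along(g$distances),
                          distance = g$distances, state = g$state)
    },
    rotamer = {
      g <- do.call(makeRotamerTrajectory, c(list(seed = seed), args))
      files <- writePDB(g$trajectory, file.path(outDir, "rotamer.pdb"))
      truth <- data.frame(frame = seq_along(g$chi1), chi1 = g$chi1,
                          state = g$state)
    },
    trimer_set = {
      ts <- makeTrimerTestSet(seed = seed)
      for (m in ts$models) {
        p <- file.path(outDir, paste0("trimer_", m@clusterId, ".pdb"))
        chains <- c("A", "B", "C")
        combined <- do.call(rbind, lapply(1:3, function(i) {
          a <- m@monomers[[i]]@atoms
          a$chain <- chains[i]
          a
        }))
        comb <- new("ProteinStructure", atoms = combined,
                    coords = do.call(rbind, lapply(m@monomers,
                                                   function(x) x@coords)),
                    title = m@clusterId)
        files <- c(files, writePDB(comb, p))
      }
      truth <- ts$manifest
      truth$model_path <- file.path(outDir,
                                    paste0("trimer_", truth$cluster_id,
                                           ".pdb"))
    },
    path = {
      g <- do.call(makePathStructure, args)
      files <- writePDB(g, file.path(outDir, "path.pdb"))
    })
  if (!is.null(truth))
    files <- c(files, .tsv(truth, file.path(outDir,
                                            paste0(what, "_truth.tsv"))))
  spec <- c(list(what = what, seed = seed), args)
  fman <- file.path(outDir, paste0(what, "_spec.json"))
  jsonlite::write_json(spec, fman, auto_unbox = TRUE, digits = NA)
  invisible(c(files, fman))
}
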