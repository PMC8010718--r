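#' @include AllClasses.R
NULL

#' Number of atoms
#' @param x a ProteinStructure or CoordTrajectory
#' @return integer atom count
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' Number of residues
#' @param x a ProteinStructure
#' @return integer residue count
#' @export
setGeneric("nResidues", function(x) standardGeneric("nResidues"))

#' Number of trajectory frames
#' @param x a CoordTrajectory
#' @return integer frame count
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Atom table
#' @param x a ProteinStructure
#' @return data.frame of per-atom metadata
#' @export
setGeneric("atomTable", function(x) standardGeneric("atomTable"))

#' Coordinates
#' @param x a ProteinStructure or CoordTrajectory
#' @param frame frame index (trajectories only)
#' @return numeric nAtoms x 3 matrix
#' @export
setGeneric("atomCoords", function(x, frame = 1L) standardGeneric("atomCoords"))

#' Per-frame values of a series
#' @param x a FrameSeries
#' @return numeric vector
#' @export
setGeneric("seriesValues", function(x) standardGeneric("seriesValues"))

#' Frame times in ns
#' @param x a FrameSeries or CoordTrajectory with dt set
#' @return numeric vector of times, first frame at 0 ns
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))

#' Residue identifiers of a structure or network
#' @param x a ProteinStructure, KirchhoffMatrix or GNMModes
#' @return character vector like "A:156"
#' @export
setGeneric("residueIds", function(x) standardGeneric("residueIds"))

#' @rdname nAtoms
setMethod("nAtoms", "ProteinStructure", function(x) nrow(x@atoms))
#' @rdname nAtoms
setMethod("nAtoms", "CoordTrajectory", function(x) dim(x@frames)[1L])

#' @rdname nResidues
setMethod("nResidues", "ProteinStructure", function(x)
  length(unique(paste(x@atoms$chain, x@atoms$resno, x@atoms$insert))))

#' @rdname nFrames
setMethod("nFrames", "CoordTrajectory", function(x) dim(x@frames)[3L])

#' @rdname atomTable
setMethod("atomTable", "ProteinStructure", function(x) x@atoms)

#' @rdname atomCoords
setMethod("atomCoords", "ProteinStructure", function(x, frame = 1L) x@coords)
#' @rdname atomCoords
setMethod("atomCoords", "CoordTrajectory", function(x, frame = 1L) {
  if (frame < 1L || frame > nFrames(x)) stop("frame index out of range")
  x@frames[, , frame, drop = TRUE]
})

#' @rdname seriesValues
setMethod("seriesValues", "FrameSeries", function(x) x@values)

#' @rdname frameTimes
setMethod("frameTimes", "FrameSeries", function(x) {
  if (is.na(x@dt)) stop("series has no frame interval (dt)")
  (seq_along(x@values) - 1) * x@dt
})
#' @rdname frameTimes
setMethod("frameTimes", "CoordTrajectory", function(x) {
  if (is.na(x@dt)) stop("trajectory has no frame interval (dt)")
  (seq_len(nFrames(x)) - 1) * x@dt
})

#' @rdname residueIds
setMethod("residueIds", "ProteinStructure", function(x) {
  a <- x@atoms
  unique(paste0(a$chain, ":", a$resno, ifelse(nzchar(a$insert), a$insert, "")))
})
#' @rdname residueIds
setMethod("residueIds", "KirchhoffMatrix", function(x) x@nodeIds)
#' @rdname residueIds
setMethod("residueIds", "GNMModes", function(x) x@nodeIds)

setMethod("show", "ProteinStructure", function(object) {
  cat("ProteinStructure:", nAtoms(object), "atoms,",
      nResidues(object), "residues")
  if (nzchar(object@title)) cat(" |", object@title)
  cat("\n  chains:", paste(unique(object@atoms$chain), collapse = ", "), "\n")
})

setMethod("show", "CoordTrajectory", function(object) {
  cat("CoordTrajectory:", nFrames(object), "frames x",
      nAtoms(object), "atoms")
  if (!is.na(object@dt)) cat(", dt =", object@dt, "ns")
  cat("\n")
})

setMethod("show", "KirchhoffMatrix", function(object) {
  cat("KirchhoffMatrix:", nrow(object@matrix), "nodes, rc =", object@rc,
      "A,", object@nComponents, "connected component(s)\n")
})

setMethod("show", "GNMModes", function(object) {
  n <- length(object@eigenvalues)
  cat("GNMModes:", n - object@nZero, "nonzero modes (", object@nZero,
      "zero );  lambda_1 =",
      signif(object@eigenvalues[object@nZero + 1L], 4), "\n")
})

setMethod("show", "FrameSeries", function(object) {
  cat("FrameSeries [", object@observable, "]: ", length(object@values),
      " frames, run '", object@runId, "'",
      if (!is.na(object@dt)) paste0(", dt = ", object@dt, " ns"), "\n",
      sep = "")
})

setMethod("show", "PooledHistogram", function(object) {
  cat("PooledHistogram:", length(object@pooled), "bins,",
      ncol(object@counts), "run(s), total",
      if (object@density) "density" else sum(object@pooled), "\n")
})

setMethod("show", "TrimerModel", function(object) {
  cat("TrimerModel: cluster", object@clusterId, "(size",
      object@clusterSize, "),", nAtoms(object@monomers[[1L]]),
      "atoms per monomer\n")
})

setMethod("show", "MembraneFrame", function(object) {
  cat("MembraneFrame: normal (", paste(signif(object@normal, 3),
      collapse = ", "), "), slab ", object@midplane, " +/- ",
      object@halfThickness, " A, IC side = ",
      ifelse(object@icSide > 0, "+", "-"), "normal\n", sep = "")
})
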