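#' @import methods
NULL

#' ProteinStructure: atoms grouped into residues with 3D coordinates
#'
#' Container for a single-conformer molecular structure. Atoms are stored in
#' file order together with per-atom metadata; residues are identified by the
#' author's (chain, residue number, insertion code) triple, so residue labels
#' in reports match the numbering used in the structural literature (e.g.
#' Y156, F320).
#'
#' @slot atoms data.frame with one row per atom: \code{elety} (atom name),
#'   \code{element}, \code{chain}, \code{resno}, \code{insert},
#'   \code{resid} (3-letter residue name), \code{occupancy}, \code{mass}
#'   (amu), \code{hydrogen} (logical).
#' @slot coords numeric matrix, nAtoms x 3, Angstrom.
#' @slot title free-text description.
#'
#' @exportClass ProteinStructure
setClass("ProteinStructure",
  representation(atoms = "data.frame", coords = "matrix", title = "character"))

setValidity("ProteinStructure", function(object) {
  a <- object@atoms
  need <- c("elety", "element", "chain", "resno", "insert", "resid",
            "occupancy", "mass", "hydrogen")
  if (!all(need %in% names(a)))
    return(paste("atoms is missing columns:",
                 paste(setdiff(need, names(a)), collapse = ", ")))
  if (nrow(a) < 1L) return("structure must contain at least one atom")
  if (nrow(object@coords) != nrow(a) || ncol(object@coords) != 3L)
    return("coords must be an nAtoms x 3 matrix")
  if (!all(is.finite(object@coords))) return("coordinates must be finite")
  if (any(!nzchar(a$elety))) return("atom names must be non-empty")
  if (any(!is.finite(a$mass)) || any(a$mass <= 0))
    return("atom masses must be positive and finite")
  key <- paste(a$chain, a$resno, a$insert, sep = "\r")
  dup <- tapply(a$elety, key, function(x) anyDuplicated(x) > 0L)
  if (any(dup))
    return(paste("duplicate atom names within residue(s):",
                 paste(gsub("\r", ":", names(dup)[dup]), collapse = ", ")))
  TRUE
})

#' CoordTrajectory: ordered coordinate frames over a fixed atom roster
#'
#' @slot topology a \linkS4class{ProteinStructure} defining the atom roster.
#' @slot frames numeric array nAtoms x 3 x nFrames, Angstrom.
#' @slot dt frame interval in ns (NA when unknown).
#'
#' @exportClass CoordTrajectory
setClass("CoordTrajectory",
  representation(topology = "ProteinStructure", frames = "array",
                 dt = "numeric"))

setValidity("CoordTrajectory", function(object) {
  d <- dim(object@frames)
  if (length(d) != 3L || d[2L] != 3L)
    return("frames must be an nAtoms x 3 x nFrames array")
  if (d[1L] != nrow(object@topology@atoms))
    return("frame atom count does not match topology")
  if (d[3L] < 1L) return("trajectory must contain at least one frame")
  if (length(object@dt) != 1L) return("dt must be a single value")
  if (!is.na(object@dt) && object@dt <= 0) return("dt must be > 0")
  TRUE
})

#' KirchhoffMatrix: connectivity Laplacian of a C-alpha contact network
#'
#' The Kirchhoff matrix has off-diagonal elements -1 for node pairs whose
#' node atoms lie within the cutoff rc, 0 otherwise, and node degree on the
#' diagonal; each row sums to zero.
#'
#' @slot matrix N x N symmetric Laplacian.
#' @slot rc cutoff distance, Angstrom.
#' @slot nodeIds character residue identifiers, one per node.
#' @slot nComponents connected-component count of the contact graph.
#'
#' @exportClass KirchhoffMatrix
setClass("KirchhoffMatrix",
  representation(matrix = "matrix", rc = "numeric", nodeIds = "character",
                 nComponents = "integer"))

setValidity("KirchhoffMatrix", function(object) {
  m <- object@matrix
  if (nrow(m) != ncol(m)) return("matrix must be square")
  if (length(object@nodeIds) != nrow(m))
    return("nodeIds length must equal matrix dimension")
  if (max(abs(m - t(m))) > 1e-12) return("matrix must be symmetric")
  off <- m[row(m) != col(m)]
  if (!all(off %in% c(0, -1)))
    return("off-diagonal elements must be 0 or -1")
  if (max(abs(rowSums(m))) > 1e-12) return("row sums must be zero")
  if (object@rc <= 0) return("rc must be > 0")
  TRUE
})

#' GNMModes: eigendecomposition of a Kirchhoff matrix
#'
#' Eigenvalues are sorted ascending; eigenvector columns are orthonormal,
#' with the global sign of each fixed so its first nonzero element is
#' positive. Nonzero modes are indexed 1..N-nZero in ascending eigenvalue
#' order (mode 1 = slowest, the global mode).
#'
#' @slot eigenvalues ascending, >= 0.
#' @slot vectors orthonormal eigenvector columns, same order.
#' @slot nZero number of numerically zero eigenvalues (= connected
#'   components of the network).
#' @slot zeroTol absolute tolerance used to call an eigenvalue zero.
#' @slot nodeIds residue identifiers, one per node.
#'
#' @exportClass GNMModes
setClass("GNMModes",
  representation(eigenvalues = "numeric", vectors = "matrix",
                 nZero = "integer", zeroTol = "numeric",
                 nodeIds = "character"))

setValidity("GNMModes", function(object) {
  n <- length(object@eigenvalues)
  if (nrow(object@vectors) != n || ncol(object@vectors) != n)
    return("vectors must be N x N")
  if (is.unsorted(object@eigenvalues)) return("eigenvalues must be ascending")
  if (object@nZero < 1L) return("a Laplacian has at least one zero mode")
  if (length(object@nodeIds) != n)
    return("nodeIds length must equal mode count")
  TRUE
})

#' FrameSeries: a per-frame scalar observable with run provenance
#'
#' Holds one observable sampled at every trajectory frame: a centre-of-mass
#' distance (Angstrom), a chi1 rotamer angle (degrees, (-180, 180]) or an
#' RMSD (Angstrom). The run identifier and frame interval travel with the
#' values so multi-run pooling and time conversion stay explicit.
#'
#' @slot values per-frame values.
#' @slot observable one of "com_distance", "chi1", "rmsd".
#' @slot unit "angstrom" or "degree".
#' @slot runId run label used in pooled outputs.
#' @slot dt frame interval, ns (NA when unknown).
#' @slot meta list of provenance details (selectors, atom scope, ...).
#'
#' @exportClass FrameSeries
setClass("FrameSeries",
  representation(values = "numeric", observable = "character",
                 unit = "character", runId = "character", dt = "numeric",
                 meta = "list"))

setValidity("FrameSeries", function(object) {
  if (length(object@values) < 1L) return("series must be non-empty")
  if (!object@observable %in% c("com_distance", "chi1", "rmsd"))
    return("unknown observable")
  if (!object@unit %in% c("angstrom", "degree")) return("unknown unit")
  if (object@unit == "angstrom" && any(object@values < 0, na.rm = TRUE))
    return("distances must be >= 0")
  if (object@unit == "degree" &&
      any(object@values <= -180 | object@values > 180, na.rm = TRUE))
    return("angles must lie in (-180, 180]")
  if (!is.na(object@dt) && object@dt <= 0) return("dt must be > 0")
  TRUE
})

#' PooledHistogram: per-run and pooled counts over shared bins
#'
#' @slot breaks bin edges (length nBins + 1).
#' @slot counts nBins x nRuns matrix of per-run counts.
#' @slot pooled bin-wise sum over runs.
#' @slot unit unit of the binned observable.
#' @slot density logical; TRUE when counts were normalised to densities.
#'
#' @exportClass PooledHistogram
setClass("PooledHistogram",
  representation(breaks = "numeric", counts = "matrix", pooled = "numeric",
                 unit = "character", density = "logical"))

setValidity("PooledHistogram", function(object) {
  nb <- length(object@breaks) - 1L
  if (nrow(object@counts) != nb || length(object@pooled) != nb)
    return("counts/pooled must have one entry per bin")
  if (max(abs(rowSums(object@counts) - object@pooled)) > 1e-9)
    return("pooled counts must equal the bin-wise sum over runs")
  TRUE
})

#' MembraneFrame: implicit membrane slab geometry
#'
#' Defines the membrane as a slab of half-thickness h centred at
#' \code{midplane} along the unit \code{normal}; \code{icSide} (+1 or -1)
#' states which direction along the normal is intracellular.
#'
#' @slot normal unit 3-vector.
#' @slot midplane offset of the slab midplane along the normal, Angstrom.
#' @slot halfThickness half the slab thickness, Angstrom.
#' @slot icSide +1 or -1.
#'
#' @exportClass MembraneFrame
setClass("MembraneFrame",
  representation(normal = "numeric", midplane = "numeric",
                 halfThickness = "numeric", icSide = "numeric"))

setValidity("MembraneFrame", function(object) {
  if (length(object@normal) != 3L ||
      abs(sqrt(sum(object@normal^2)) - 1) > 1e-8)
    return("normal must be a unit 3-vector")
  if (object@halfThickness <= 0) return("halfThickness must be > 0")
  if (!object@icSide %in% c(-1, 1)) return("icSide must be +1 or -1")
  TRUE
})

#' TrimerModel: three monomers sharing a residue roster, plus a membrane
#'
#' @slot monomers list of three \linkS4class{ProteinStructure}s with
#'   identical residue/atom rosters.
#' @slot membrane a \linkS4class{MembraneFrame}.
#' @slot clusterId label of the docking cluster the model represents.
#' @slot clusterSize member count of that cluster (used for ranking).
#'
#' @exportClass TrimerModel
setClass("TrimerModel",
  representation(monomers = "list", membrane = "MembraneFrame",
                 clusterId = "character", clusterSize = "integer"))

setValidity("TrimerModel", function(object) {
  if (length(object@monomers) != 3L) return("a trimer has three monomers")
  if (!all(vapply(object@monomers, is, logical(1), "ProteinStructure")))
    return("monomers must be ProteinStructure objects")
  # chains may differ (A/B/C of one file); the residue/atom roster must not
  ros <- lapply(object@monomers, function(m)
    paste(m@atoms$resno, m@atoms$insert, m@atoms$resid, m@atoms$elety))
  if (!identical(ros[[1L]], ros[[2L]]) || !identical(ros[[1L]], ros[[3L]]))
    return("monomer atom rosters must be identical")
  if (object@clusterSize < 1L) return("clusterSize must be >= 1")
  TRUE
})
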