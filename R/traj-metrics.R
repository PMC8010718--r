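# Gamma atom defining chi1 (N-CA-CB-Ggamma) per residue type. ALA and GLY
# have no chi1 and are rejected.
.CHI1_GAMMA <- c(
  ARG = "CG", ASN = "CG", ASP = "CG", CYS = "SG", GLN = "CG", GLU = "CG",
  HIS = "CG", ILE = "CG1", LEU = "CG", LYS = "CG", MET = "CG", PHE = "CG",
  PRO = "CG", SER = "OG", THR = "OG1", TRP = "CG", TYR = "CG", VAL = "CG1")

# Backbone atom names; everything else heavy is sidechain (CB inclusive).
.BACKBONE <- c("N", "CA", "C", "O", "OXT", "OT1", "OT2")

.scopeAtoms <- function(structure, resIdx, atomScope) {
  a <- structure@atoms
  key <- .resKey(a)
  ukey <- unique(key)
  rows <- which(key %in% ukey[resIdx])
  rows <- switch(atomScope,
    all = rows,
    heavy = rows[!a$hydrogen[rows]],
    sidechain = rows[!a$hydrogen[rows] & !(a$elety[rows] %in% .BACKBONE)],
    stop("unknown atomScope: ", atomScope))
  if (length(rows) == 0L)
    stop("no atoms in scope '", atomScope, "' for residue(s) ",
         paste(unique(.resId(a)[which(key %in% ukey[resIdx])]),
               collapse = ", "),
         " (glycine has no sidechain atoms)")
  rows
}

#' Centre-of-mass distance between two residue selections, per frame
#'
#' For each frame, computes the Euclidean distance between the
#' mass-weighted centres of the two selections. The default atom scope is
#' the heavy sidechain atoms (CB inclusive), appropriate for aromatic
#' gating pairs such as Y156-F320 whose interaction is carried by the
#' sidechains; \code{"heavy"} (whole residue, no hydrogens) and
#' \code{"all"} scopes are available.
#'
#' @param trajectory a \linkS4class{CoordTrajectory}.
#' @param selA,selB residue selectors (see \code{\link{selectResidues}}).
#' @param atomScope "sidechain" (default), "heavy" or "all".
#' @param runId run label carried into pooled histograms.
#' @return a \linkS4class{FrameSeries} of distances (Angstrom). Distances
#'   above 100 Angstrom trigger a warning as a probable periodic-wrapping
#'   artifact: inputs are assumed whole-molecule.
#' @export
comDistance <- function(trajectory, selA, selB,
                        atomScope = c("sidechain", "heavy", "all"),
                        runId = "run1") {
  stopifnot(is(trajectory, "CoordTrajectory"))
  atomScope <- match.arg(atomScope)
  topo <- trajectory@topology
  ia <- .scopeAtoms(topo, selectResidues(topo, selA), atomScope)
  ib <- .scopeAtoms(topo, selectResidues(topo, selB), atomScope)
  ma <- topo@atoms$mass[ia]
  mb <- topo@atoms$mass[ib]
  nf <- nFrames(trajectory)
  vals <- vapply(seq_len(nf), function(f) {
    xyz <- trajectory@frames[, , f]
    sqrt(sum((massCenter(xyz[ia, , drop = FALSE], ma) -
              massCenter(xyz[ib, , drop = FALSE], mb))^2))
  }, numeric(1))
  if (any(vals > 100))
    warning("COM distances exceed 100 Angstrom; possible periodic-boundary ",
            "wrapping artifact")
  new("FrameSeries", values = vals, observable = "com_distance",
      unit = "angstrom", runId = runId, dt = trajectory@dt,
      meta = list(selA = selA, selB = selB, atomScope = atomScope))
}

#' chi1 side-chain dihedral per frame
#'
#' Computes the signed N-CA-CB-Ggamma dihedral (IUPAC convention, degrees in
#' (-180, 180]) for the selected residue at every frame. The gamma atom is
#' taken from a built-in table (CG for Phe/Tyr/Leu/Trp/..., CG1 for Ile/Val,
#' OG for Ser, OG1 for Thr, SG for Cys).
#'
#' @param trajectory a \linkS4class{CoordTrajectory}.
#' @param residue residue selector, e.g. "A:155".
#' @param runId run label.
#' @return a \linkS4class{FrameSeries} of angles (degrees).
#' @export
chi1Series <- function(trajectory, residue, runId = "run1") {
  stopifnot(is(trajectory, "CoordTrajectory"))
  topo <- trajectory@topology
  ridx <- selectResidues(topo, residue)[1L]
  a <- topo@atoms
  key <- .resKey(a)
  rows <- which(key == unique(key)[ridx])
  rtype <- a$resid[rows[1L]]
  if (!rtype %in% names(.CHI1_GAMMA))
    stop("no chi1 definition for residue type '", rtype,
         "' (see the built-in gamma-atom table; ALA/GLY have no chi1)")
  need <- c("N", "CA", "CB", unname(.CHI1_GAMMA[rtype]))
  idx <- vapply(need, function(nm) {
    i <- rows[a$elety[rows] == nm]
    if (length(i)) i[1L] else NA_integer_
  }, integer(1))
  if (anyNA(idx))
    stop("residue ", names(ridx), " (", rtype, ") is missing chi1 atom(s): ",
         paste(need[is.na(idx)], collapse = ", "))
  nf <- nFrames(trajectory)
  vals <- vapply(seq_len(nf), function(f) {
    xyz <- as.vector(t(trajectory@frames[idx, , f]))
    bio3d::torsion.xyz(xyz, atm.inc = 4)
  }, numeric(1))
  new("FrameSeries", values = wrapAngle(vals), observable = "chi1",
      unit = "degree", runId = runId, dt = trajectory@dt,
      meta = list(residue = residue, restype = rtype))
}

#' Default rotamer state definitions for gating aromatics
#'
#' Circular chi1 intervals for the inward-facing-like (170 +/- 15 degrees)
#' and outward-facing-like (60 +/- 20 degrees) rotamers of the gating
#' phenylalanine.
#'
#' @return data.frame with columns label, center, halfwidth (degrees).
#' @export
rotamerStates <- function() {
  data.frame(label = c("IF-like", "OF-like"),
             center = c(170, 60), halfwidth = c(15, 20),
             stringsAsFactors = FALSE)
}

#' Classify rotamer angles into circular states
#'
#' Labels each frame with the state whose circular interval
#' [center - halfwidth, center + halfwidth] (modulo 360) contains its
#' angle, or "unassigned" when no state matches. State intervals must be
#' circularly disjoint.
#'
#' @param series a chi1 \linkS4class{FrameSeries} (or numeric vector of
#'   degrees).
#' @param states data.frame with label, center, halfwidth columns; default
#'   \code{\link{rotamerStates}()}.
#' @return list with \code{labels} (character per frame) and
#'   \code{occupancy} (named fractions over states plus "unassigned",
#'   summing to 1).
#' @export
classifyRotamer <- function(series, states = rotamerStates()) {
  vals <- if (is(series, "FrameSeries")) series@values else as.numeric(series)
  stopifnot(all(c("label", "center", "halfwidth") %in% names(states)))
  if (any(states$halfwidth <= 0 | states$halfwidth >= 180))
    stop("halfwidth must lie in (0, 180)")
  ns <- nrow(states)
  if (ns > 1L) {
    for (i in seq_len(ns - 1L)) for (j in (i + 1L):ns) {
      if (circularDiff(states$center[i], states$center[j]) <=
          states$halfwidth[i] + states$halfwidth[j])
        stop("state intervals '", states$label[i], "' and '",
             states$label[j], "' overlap circularly")
    }
  }
  labels <- rep("unassigned", length(vals))
  for (i in seq_len(ns)) {
    hit <- circularDiff(vals, states$center[i]) <= states$halfwidth[i]
    labels[hit] <- states$label[i]
  }
  lev <- c(states$label, "unassigned")
  occ <- table(factor(labels, levels = lev)) / length(vals)
  list(labels = labels, occupancy = stats::setNames(as.numeric(occ), lev))
}

#' Pool per-frame observables from several runs into one histogram
#'
#' Builds a shared set of fixed-width bins over the pooled data range and
#' counts each run separately; the pooled counts are the bin-wise sum, so
#' pooling n runs is identical to histogramming their concatenation. This
#' is the multi-run aggregation used for gate-distance distributions
#' reported across independent trajectories.
#'
#' @param seriesList list of \linkS4class{FrameSeries} sharing observable
#'   and unit.
#' @param binWidth bin width (default 0.25, in the series unit).
#' @param breaks optional explicit bin edges (overrides binWidth).
#' @return a \linkS4class{PooledHistogram}.
#' @export
pooledHistogram <- function(seriesList, binWidth = 0.25, breaks = NULL) {
  if (length(seriesList) == 0L) stop("empty series list")
  obs <- vapply(seriesList, function(s) s@observable, character(1))
  unit <- vapply(seriesList, function(s) s@unit, character(1))
  if (length(unique(obs)) != 1L || length(unique(unit)) != 1L)
    stop("all series must share observable type and unit")
  allv <- unlist(lapply(seriesList, seriesValues))
  if (is.null(breaks)) {
    lo <- floor(min(allv) / binWidth) * binWidth
    hi <- ceiling(max(allv) / binWidth) * binWidth
    if (hi <= lo) hi <- lo + binWidth
    breaks <- seq(lo, hi, by = binWidth)
    if (max(allv) >= breaks[length(breaks)])
      breaks <- c(breaks, breaks[length(breaks)] + binWidth)
  }
  counts <- vapply(seriesList, function(s)
    graphics::hist(s@values, breaks = breaks, right = FALSE,
                   plot = FALSE)$counts,
    numeric(length(breaks) - 1L))
  counts <- matrix(counts, ncol = length(seriesList))
  colnames(counts) <- vapply(seriesList, function(s) s@runId, character(1))
  new("PooledHistogram", breaks = breaks, counts = counts,
      pooled = rowSums(counts), unit = unit[1L], density = FALSE)
}

#' Tabulate a pooled histogram
#'
#' @param x a \linkS4class{PooledHistogram}.
#' @param cumulative return running (cumulative distribution) fractions
#'   instead of raw counts.
#' @return data.frame: bin_lo, bin_hi, one column per run, pooled.
#' @export
histogramTable <- function(x, cumulative = FALSE) {
  stopifnot(is(x, "PooledHistogram"))
  nb <- length(x@pooled)
  out <- data.frame(bin_lo = x@breaks[-(nb + 1L)], bin_hi = x@breaks[-1L])
  cnt <- x@counts
  pooled <- x@pooled
  if (cumulative) {
    cnt <- apply(cnt, 2, function(v) cumsum(v) / sum(v))
    pooled <- cumsum(pooled) / sum(pooled)
  }
  cbind(out, cnt, pooled = pooled)
}

#' Plot a pooled histogram
#'
#' @param x a \linkS4class{PooledHistogram}.
#' @param ... passed to \code{barplot}.
#' @return invisibly, the bin midpoints.
#' @export
plotPooledHistogram <- function(x, ...) {
  mids <- (x@breaks[-1L] + x@breaks[-length(x@breaks)]) / 2
  graphics::barplot(x@pooled, names.arg = signif(mids, 3),
                    xlab = x@unit, ylab = "pooled count", ...)
  invisible(mids)
}

#' First sustained gate closure time
#'
#' Returns the earliest time t (ns) such that the observable stays below
#' \code{closedThreshold} for \code{dwellFrames} consecutive frames starting
#' at t; NA when the gate never closes. The dwell requirement (default 5
#' frames) suppresses single-frame threshold crossings.
#'
#' @param series a distance \linkS4class{FrameSeries} with dt set.
#' @param closedThreshold closure threshold, Angstrom (> 0).
#' @param dwellFrames minimum consecutive frames below threshold (>= 1).
#' @return closure time in ns, or NA_real_ if never closed.
#' @export
gateClosureTime <- function(series, closedThreshold, dwellFrames = 5L) {
  stopifnot(is(series, "FrameSeries"))
  if (closedThreshold <= 0) stop("closedThreshold must be > 0")
  if (dwellFrames < 1L) stop("dwellFrames must be >= 1")
  if (is.na(series@dt))
    stop("series has no frame interval (dt); closure time needs one")
  below <- series@values < closedThreshold
  n <- length(below)
  if (dwellFrames > n) return(NA_real_)
  run <- 0L
  for (i in seq_len(n)) {
    run <- if (below[i]) run + 1L else 0L
    if (run >= dwellFrames) return((i - dwellFrames) * series@dt)
  }
  NA_real_
}

#' Per-frame RMSD from a reference structure
#'
#' Computes the root-mean-square deviation of each frame from the
#' reference over the selected atoms. With \code{superpose = TRUE}
#' (default) each frame is first optimally superposed on the reference by
#' least-squares rigid-body fitting, so rigid transforms contribute zero
#' RMSD and the series reports internal deformation only (the usual
#' equilibration diagnostic).
#'
#' @param trajectory a \linkS4class{CoordTrajectory}.
#' @param reference a \linkS4class{ProteinStructure} (default: the
#'   trajectory topology, i.e. the starting structure).
#' @param selection residue selectors restricting the atom set (default:
#'   all atoms).
#' @param superpose apply optimal superposition first.
#' @param runId run label.
#' @return a \linkS4class{FrameSeries} of RMSD values (Angstrom).
#' @export
rmsdSeries <- function(trajectory, reference = NULL, selection = NULL,
                       superpose = TRUE, runId = "run1") {
  stopifnot(is(trajectory, "CoordTrajectory"))
  topo <- trajectory@topology
  if (is.null(reference)) reference <- topo
  if (nAtoms(reference) != nAtoms(topo))
    stop("reference atom count (", nAtoms(reference),
         ") does not match trajectory (", nAtoms(topo), ")")
  rows <- if (is.null(selection)) seq_len(nAtoms(topo))
          else .scopeAtoms(topo, selectResidues(topo, selection), "all")
  refxyz <- as.vector(t(reference@coords[rows, , drop = FALSE]))
  nf <- nFrames(trajectory)
  fr <- t(vapply(seq_len(nf), function(f)
    as.vector(t(trajectory@frames[rows, , f])), numeric(3 * length(rows))))
  vals <- as.numeric(bio3d::rmsd(a = refxyz, b = fr, fit = superpose))
  new("FrameSeries", values = vals, observable = "rmsd",
      unit = "angstrom", runId = runId, dt = trajectory@dt,
      meta = list(superpose = superpose, nAtomsUsed = length(rows)))
}

#' Detect an RMSD plateau
#'
#' Slides a window along the series and reports the earliest window whose
#' least-squares slope magnitude falls below \code{slopeTol}; the plateau
#' mean is taken over everything from that window onward. Used to decide
#' whether a trajectory has structurally equilibrated (RMSD "flat" after an
#' initial rise).
#'
#' @param series an RMSD \linkS4class{FrameSeries}.
#' @param window window length in frames (default 20).
#' @param slopeTol slope tolerance, Angstrom per ns when dt is set,
#'   Angstrom per frame otherwise (default 0.01).
#' @return list: \code{plateau_reached} (logical), \code{plateau_start}
#'   (ns, or frames when dt is NA; NA when not reached),
#'   \code{plateau_mean} (Angstrom; NA when not reached).
#' @export
plateauCheck <- function(series, window = 20L, slopeTol = 0.01) {
  stopifnot(is(series, "FrameSeries"))
  v <- series@values
  n <- length(v)
  if (n <= window) stop("series must be longer than the window")
  dt <- if (is.na(series@dt)) 1 else series@dt
  x <- (seq_len(window) - 1) * dt
  sxx <- sum((x - mean(x))^2)
  for (s in seq_len(n - window + 1L)) {
    y <- v[s:(s + window - 1L)]
    slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
    if (abs(slope) < slopeTol) {
      start <- (s - 1) * dt
      return(list(plateau_reached = TRUE, plateau_start = start,
                  plateau_mean = mean(v[s:n])))
    }
  }
  list(plateau_reached = FALSE, plateau_start = NA_real_,
       plateau_mean = NA_real_)
}

#' Write a FrameSeries as a TSV time-series table
#'
#' @param series a \linkS4class{FrameSeries}.
#' @param path output path.
#' @param labels optional per-frame labels (e.g. rotamer states).
#' @return invisibly, the path.
#' @export
writeSeriesTSV <- function(series, path, labels = NULL) {
  tab <- data.frame(frame = seq_along(series@values),
                    time_ns = if (is.na(series@dt)) NA_real_
                              else (seq_along(series@values) - 1) * series@dt,
                    value = series@values)
  if (!is.null(labels)) tab$label <- labels
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
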