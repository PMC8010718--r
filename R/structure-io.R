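#' Read a PDB file into a ProteinStructure
#'
#' Parses ATOM (and optionally HETATM) records. Alternate locations are
#' resolved by keeping the highest-occupancy copy of each atom (tie: first
#' encountered). Hydrogens are retained and flagged in the atom table;
#' waters and hetero groups are excluded by default.
#'
#' @param path path to a PDB file.
#' @param includeHetero keep HETATM records (waters always follow this flag).
#' @param model model number to read for multi-model files (default 1); use
#'   \code{\link{readTrajectory}} to read all models.
#' @return a \linkS4class{ProteinStructure}.
#' @examples
#' pdb <- tempfile(fileext = ".pdb")
#' writePDB(makePathStructure(3), pdb)
#' readPDB(pdb)
#' @export
readPDB <- function(path, includeHetero = FALSE, model = 1L) {
  if (!file.exists(path)) stop("file not found: ", path)
  .validatePDBLines(readLines(path, warn = FALSE))
  pdb <- bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                         verbose = FALSE)
  at <- pdb$atom
  if (nrow(at) == 0L) stop("no ATOM records in ", path)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  water <- at$resid %in% c("HOH", "WAT", "TIP3", "TIP", "SOL")
  keep <- if (includeHetero) rep(TRUE, nrow(at))
          else at$type == "ATOM" & !water
  if (!any(keep)) stop("no atoms retained from ", path,
                       " (all records hetero/water?)")
  at <- at[keep, , drop = FALSE]
  xyz <- xyz[keep, , drop = FALSE]

  # altloc resolution: highest occupancy wins, tie -> first encountered
  occ <- ifelse(is.na(at$o), 1, at$o)
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
  ord <- order(factor(key, levels = unique(key)), -occ,
               seq_along(key))
  first <- !duplicated(key[ord])
  sel <- sort(ord[first])
  at <- at[sel, , drop = FALSE]
  xyz <- xyz[sel, , drop = FALSE]
  occ <- occ[sel]

  element <- trimws(ifelse(is.na(at$elesy) | !nzchar(trimws(at$elesy)),
                           "", at$elesy))
  miss <- !nzchar(element)
  element[miss] <- elementFromName(at$elety[miss])

  newStructure(elety = trimws(at$elety), element = element,
               chain = ifelse(is.na(at$chain), "A", at$chain),
               resno = at$resno,
               insert = ifelse(is.na(at$insert), "", at$insert),
               resid = trimws(at$resid), occupancy = occ, coords = xyz,
               title = basename(path))
}

# Light pre-scan so malformed coordinate records are reported with a line
# number (the downstream reader is more permissive).
.validatePDBLines <- function(lines) {
  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (any(rec)) {
    for (i in which(rec)) {
      ln <- lines[i]
      if (nchar(ln) < 54L)
        stop("unparseable PDB record at line ", i, ": record too short")
      xyz <- suppressWarnings(as.numeric(
        c(substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54))))
      if (anyNA(xyz))
        stop("unparseable PDB record at line ", i,
             ": non-numeric coordinates")
    }
  }
  invisible(TRUE)
}

#' Write a ProteinStructure (or CoordTrajectory) to a PDB file
#'
#' Coordinates are written at the standard 3-decimal PDB precision.
#' Trajectories are written as multi-model PDB (MODEL/ENDMDL blocks).
#'
#' @param x a \linkS4class{ProteinStructure} or
#'   \linkS4class{CoordTrajectory}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writePDB <- function(x, path) {
  if (is(x, "CoordTrajectory")) {
    con <- file(path, "w")
    on.exit(close(con))
    topo <- x@topology
    for (f in seq_len(nFrames(x))) {
      writeLines(sprintf("MODEL     %4d", f), con)
      writeLines(.pdbLines(topo, x@frames[, , f]), con)
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
    return(invisible(path))
  }
  stopifnot(is(x, "ProteinStructure"))
  writeLines(c(.pdbLines(x, x@coords), "END"), path)
  invisible(path)
}

.pdbLines <- function(structure, coords) {
  a <- structure@atoms
  nm <- a$elety
  # PDB atom-name column alignment: 1-letter elements start in column 14
  nm <- ifelse(nchar(nm) < 4L & nchar(a$element) == 1L,
               paste0(" ", nm), nm)
  sprintf("ATOM  %5d %-4s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          seq_len(nrow(a)) %% 100000L, substr(nm, 1, 4), a$resid,
          substr(a$chain, 1, 1), a$resno,
          ifelse(nzchar(a$insert), a$insert, " "),
          coords[, 1], coords[, 2], coords[, 3],
          a$occupancy, 0, toupper(a$element))
}

#' Read a trajectory from a multi-model PDB file
#'
#' Frames are returned in file MODEL order. Every model must contain the
#' same number of atoms as the first (or as the supplied topology);
#' a mismatch is reported with the offending model index.
#'
#' @param path multi-model (or single-model) PDB file.
#' @param topology optional \linkS4class{ProteinStructure} giving the atom
#'   roster; defaults to the first model.
#' @param dt frame interval in ns (NA if unknown).
#' @return a \linkS4class{CoordTrajectory}.
#' @export
readTrajectory <- function(path, topology = NULL, dt = NA_real_) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^MODEL", lines)
  if (length(starts) == 0L) {
    topo1 <- readPDB(path)
    if (!is.null(topology) && nAtoms(topology) != nAtoms(topo1))
      stop("atom count in file (", nAtoms(topo1),
           ") does not match topology (", nAtoms(topology), ")")
    topo <- if (is.null(topology)) topo1 else topology
    return(new("CoordTrajectory", topology = topo,
               frames = array(topo1@coords, c(nAtoms(topo1), 3, 1)),
               dt = as.numeric(dt)))
  }
  ends <- grep("^ENDMDL", lines)
  if (length(ends) != length(starts))
    stop("unbalanced MODEL/ENDMDL records in ", path)
  blocks <- lapply(seq_along(starts), function(i)
    lines[(starts[i] + 1L):(ends[i] - 1L)])
  counts <- vapply(blocks, function(b)
    sum(grepl("^(ATOM  |HETATM)", b)), integer(1))
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  writeLines(blocks[[1L]], tmp)
  topo1 <- readPDB(tmp)
  topo <- if (is.null(topology)) topo1 else topology
  bad <- which(counts != counts[1L])
  if (length(bad))
    stop("atom-count mismatch in model ", bad[1L], ": ", counts[bad[1L]],
         " atoms vs ", counts[1L], " in model 1")
  if (nAtoms(topo) != nAtoms(topo1))
    stop("atom count in models (", nAtoms(topo1),
         ") does not match topology (", nAtoms(topo), ")")
  frames <- array(NA_real_, c(nAtoms(topo1), 3, length(blocks)))
  frames[, , 1L] <- topo1@coords
  if (length(blocks) > 1L) {
    for (i in 2L:length(blocks)) {
      writeLines(blocks[[i]], tmp)
      si <- readPDB(tmp)
      frames[, , i] <- si@coords
    }
  }
  new("CoordTrajectory", topology = topo, frames = frames,
      dt = as.numeric(dt))
}

#' Read a plain per-frame coordinate table as a trajectory
#'
#' Accepts whitespace- or comma-delimited tables with columns
#' \code{frame, atom_index, x, y, z} (header optional; \code{#} comments
#' allowed). Atom indices are 1-based over the topology roster.
#'
#' @param path table path.
#' @param topology \linkS4class{ProteinStructure} giving the atom roster.
#' @param dt frame interval, ns.
#' @return a \linkS4class{CoordTrajectory}.
#' @export
readCoordTable <- function(path, topology, dt = NA_real_) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first)) "," else ""
  header <- grepl("[A-Za-z]", sub("^#\\s*", "", first))
  tab <- utils::read.table(path, sep = sep, header = header,
                           comment.char = "#",
                           col.names = c("frame", "atom_index",
                                         "x", "y", "z"))
  nat <- nAtoms(topology)
  frames.id <- sort(unique(tab$frame))
  arr <- array(NA_real_, c(nat, 3, length(frames.id)))
  for (i in seq_along(frames.id)) {
    sub <- tab[tab$frame == frames.id[i], , drop = FALSE]
    if (nrow(sub) != nat)
      stop("frame ", frames.id[i], " has ", nrow(sub),
           " atoms; topology has ", nat)
    arr[sub$atom_index, , i] <- as.matrix(sub[, c("x", "y", "z")])
  }
  if (any(!is.finite(arr))) stop("missing or non-finite coordinates in ", path)
  new("CoordTrajectory", topology = topology, frames = arr,
      dt = as.numeric(dt))
}

#' Select residues by chain and author residue number
#'
#' Selectors take the form \code{"<chain>:<resno>"} or
#' \code{"<chain>:<resno>:<resname>"} (e.g. \code{"A:156"},
#' \code{"A:156:TYR"}). When a residue name is given and disagrees with the
#' structure, the residue is still returned with a warning, so a selection
#' written against one numbering variant fails loudly rather than silently.
#'
#' @param structure a \linkS4class{ProteinStructure}.
#' @param selector character selector, or a vector of selectors.
#' @return integer vector of residue indices (1-based, residue order of
#'   appearance), named by residue id.
#' @export
selectResidues <- function(structure, selector) {
  a <- structure@atoms
  key <- .resKey(a)
  ukey <- unique(key)
  ids <- .resId(a)[!duplicated(key)]
  names.res <- a$resid[!duplicated(key)]
  out <- integer(0)
  for (sel in selector) {
    parts <- strsplit(sel, ":", fixed = TRUE)[[1L]]
    if (length(parts) < 2L)
      stop("selector must be 'chain:resno' or 'chain:resno:resname': ", sel)
    want <- paste0(parts[1L], ":", parts[2L])
    hit <- which(ids == want)
    if (length(hit) == 0L)
      stop("no residue matches selector '", sel, "'")
    if (length(parts) >= 3L && names.res[hit[1L]] != toupper(parts[3L]))
      warning("selector '", sel, "' names ", toupper(parts[3L]),
              " but residue ", want, " is ", names.res[hit[1L]])
    out <- c(out, hit)
  }
  names(out) <- ids[out]
  out
}
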