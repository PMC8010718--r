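# Fixtures are built in code at test time; nothing is read from disk that a
# helper did not just write.

pdbLine <- function(serial, name, alt, resid, chain, resno, x, y, z,
                    occ = 1, elem = substr(name, 1, 1)) {
  nm <- if (nchar(elem) == 1L && nchar(name) < 4L) paste0(" ", name) else name
  sprintf("ATOM  %5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, nm, alt, resid, chain, resno, x, y, z, occ, 0, elem)
}

# minimal 3-residue poly-Gly backbone, plus a TYR at A:156 for selectors
writePolyGlyPDB <- function(path) {
  lines <- c(
    pdbLine(1, "N",  " ", "GLY", "A", 1, 0.0, 0.0, 0.0),
    pdbLine(2, "CA", " ", "GLY", "A", 1, 1.5, 0.0, 0.0),
    pdbLine(3, "C",  " ", "GLY", "A", 1, 2.2, 1.3, 0.0),
    pdbLine(4, "N",  " ", "GLY", "A", 2, 3.5, 1.3, 0.0),
    pdbLine(5, "CA", " ", "GLY", "A", 2, 4.3, 2.5, 0.0),
    pdbLine(6, "C",  " ", "GLY", "A", 2, 5.7, 2.2, 0.0),
    pdbLine(7, "N",  " ", "GLY", "A", 3, 6.6, 3.2, 0.0),
    pdbLine(8, "CA", " ", "GLY", "A", 3, 8.0, 3.0, 0.0),
    pdbLine(9, "C",  " ", "GLY", "A", 3, 8.8, 4.3, 0.0),
    "END")
  writeLines(lines, path)
  path
}

writeAltlocPDB <- function(path, occA = 0.6, occB = 0.4) {
  lines <- c(
    pdbLine(1, "N",  " ", "TYR", "A", 156, 0.0, 0.0, 0.0),
    pdbLine(2, "CA", "A", "TYR", "A", 156, 1.0, 0.0, 0.0, occ = occA),
    pdbLine(3, "CA", "B", "TYR", "A", 156, 2.0, 0.0, 0.0, occ = occB),
    pdbLine(4, "C",  " ", "TYR", "A", 156, 2.2, 1.3, 0.0),
    "END")
  writeLines(lines, path)
  path
}

# multi-model PDB: nModels copies of the poly-Gly fixture translated in x;
# dropAtomInModel removes one atom from that model
writeMultiModelPDB <- function(path, nModels = 5, dropAtomInModel = NA) {
  body <- readLines(writePolyGlyPDB(tempfile(fileext = ".pdb")))
  body <- body[body != "END"]
  out <- character(0)
  for (m in seq_len(nModels)) {
    shift <- vapply(body, function(ln) {
      x <- as.numeric(substr(ln, 31, 38)) + (m - 1)
      paste0(substr(ln, 1, 30), sprintf("%8.3f", x), substr(ln, 39, 200))
    }, character(1), USE.NAMES = FALSE)
    if (!is.na(dropAtomInModel) && m == dropAtomInModel)
      shift <- shift[-1]
    out <- c(out, sprintf("MODEL     %4d", m), shift, "ENDMDL")
  }
  writeLines(c(out, "END"), path)
  path
}

# random geometric structure: n CA pseudo-residues uniform in a cube
makeGeometricStructure <- function(n, box = 20, seed = 1) {
  set.seed(seed)
  gatemech:::newStructure(
    elety = rep("CA", n), element = rep("C", n), chain = rep("A", n),
    resno = seq_len(n), insert = rep("", n), resid = rep("ALA", n),
    occupancy = rep(1, n), coords = matrix(runif(3 * n, 0, box), ncol = 3))
}

# geometric structure with a known number of well-separated clusters
makeClusteredStructure <- function(ncomp, perComp = 6, seed = 1) {
  set.seed(seed)
  coords <- do.call(rbind, lapply(seq_len(ncomp), function(k)
    matrix(runif(3 * perComp, 0, 5), ncol = 3) +
      matrix(rep(c(50 * k, 0, 0), each = perComp), ncol = 3)))
  n <- nrow(coords)
  gatemech:::newStructure(
    elety = rep("CA", n), element = rep("C", n), chain = rep("A", n),
    resno = seq_len(n), insert = rep("", n), resid = rep("ALA", n),
    occupancy = rep(1, n), coords = coords)
}

# keep drawing geometric structures until connected at rc
makeConnectedStructure <- function(n, rc = 7.3, seed = 1) {
  for (i in 0:50) {
    # box side scaled so expected degree stays moderate
    s <- makeGeometricStructure(n, box = 2.2 * n^(1/3) * 2.5,
                                seed = seed + 1000 * i)
    k <- suppressWarnings(buildKirchhoff(s, rc = rc))
    if (k@nComponents == 1L) return(s)
  }
  stop("no connected draw found")
}

# build a GNMModes object by hand (for synthetic eigenvector edge cases);
# trailing columns are padded so the matrix is square as the class requires
syntheticModes <- function(vectors, eigenvalues, nZero = 1L) {
  n <- nrow(vectors)
  if (ncol(vectors) < n)
    vectors <- cbind(vectors, matrix(0, n, n - ncol(vectors)))
  if (length(eigenvalues) < n)
    eigenvalues <- c(eigenvalues,
                     seq_len(n - length(eigenvalues)) +
                       max(eigenvalues))
  new("GNMModes", eigenvalues = eigenvalues, vectors = vectors,
      nZero = as.integer(nZero), zeroTol = 1e-8,
      nodeIds = paste0("A:", seq_len(n)))
}

# apply a rigid transform to every frame of a trajectory
transformTrajectory <- function(traj, R, tvec) {
  fr <- traj@frames
  for (f in seq_len(dim(fr)[3]))
    fr[, , f] <- sweep(fr[, , f] %*% t(R), 2, -tvec)
  new("CoordTrajectory", topology = traj@topology, frames = fr,
      dt = traj@dt)
}

randomRotation <- function(seed) {
  set.seed(seed)
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  matrix(c(1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]),
           2 * (q[2] * q[4] + q[1] * q[3]),
           2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2),
           2 * (q[3] * q[4] - q[1] * q[2]),
           2 * (q[2] * q[4] - q[1] * q[3]),
           2 * (q[3] * q[4] + q[1] * q[2]),
           1 - 2 * (q[2]^2 + q[3]^2)), 3, 3, byrow = TRUE)
}

# rotamer fixture at one exact angle (sd = 0 single state)
rotamerAt <- function(angle, nFrames = 1, seed = 1) {
  makeRotamerTrajectory(
    nFrames = nFrames,
    states = data.frame(label = "s", mean = angle, sd = 0, weight = 1),
    seed = seed)
}
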