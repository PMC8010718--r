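# Internal geometry and chemistry helpers shared across modules.

# Atomic masses (amu) for elements that occur in protein structures and
# common hetero groups. Unknown elements raise an error rather than being
# silently assigned a default.
.ELEMENT_MASS <- c(
  H = 1.008, D = 2.014, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, SE = 78.971, F = 18.998, CL = 35.45, BR = 79.904, I = 126.904,
  NA. = 22.990, K = 39.098, MG = 24.305, CA = 40.078, MN = 54.938,
  FE = 55.845, ZN = 65.38, CU = 63.546, CO = 58.933, NI = 58.693)

elementMass <- function(element) {
  key <- toupper(trimws(element))
  key[key == "NA"] <- "NA."
  m <- .ELEMENT_MASS[key]
  if (anyNA(m))
    stop("unknown element(s): ",
         paste(unique(element[is.na(m)]), collapse = ", "),
         "; no mass available")
  unname(m)
}

# Infer the element symbol from a PDB atom name when the element column is
# absent: strip leading digits and take the leading alphabetic token,
# preferring two-letter symbols that are in the mass table.
elementFromName <- function(elety) {
  vapply(elety, function(nm) {
    s <- toupper(gsub("^[0-9']+", "", trimws(nm)))
    s <- gsub("[^A-Z].*$", "", s)
    if (nchar(s) >= 2L) {
      two <- substr(s, 1L, 2L)
      if (two %in% names(.ELEMENT_MASS) && !two %in% c("CA", "CO", "NI"))
        return(two)
    }
    substr(s, 1L, 1L)
  }, character(1), USE.NAMES = FALSE)
}

# Residue grouping key and display id ("<chain>:<resno><insert>").
.resKey <- function(atoms)
  paste(atoms$chain, atoms$resno, atoms$insert, sep = "\r")

.resId <- function(atoms)
  paste0(atoms$chain, ":", atoms$resno,
         ifelse(nzchar(atoms$insert), atoms$insert, ""))

# Row indices of atoms belonging to each residue, in order of appearance.
residueAtomIndex <- function(structure) {
  key <- .resKey(structure@atoms)
  split(seq_along(key), factor(key, levels = unique(key)))
}

# Mass-weighted centre of a coordinate block.
massCenter <- function(coords, mass) {
  colSums(coords * mass) / sum(mass)
}

# Rodrigues rotation matrix: rotate by angle (radians) about unit axis.
rotationMatrix <- function(axis, angle) {
  k <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# Place atom D given positions A, B, C, the C-D bond length, the B-C-D bond
# angle (degrees) and the A-B-C-D dihedral (degrees); standard internal-to-
# Cartesian construction.
placeAtom <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180
  dih <- dihedral * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- bond * c(-cos(ang), sin(ang) * cos(dih), sin(ang) * sin(dih))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Wrap angles (degrees) into (-180, 180].
wrapAngle <- function(x) {
  y <- x %% 360
  y[y > 180] <- y[y > 180] - 360
  y[y == -180] <- 180
  y
}

# Shortest circular distance between two angles, degrees.
circularDiff <- function(a, b) {
  d <- wrapAngle(a - b)
  abs(d)
}

# Random rigid-body transform (proper rotation + translation), for
# invariance checks and perturbation machinery.
randomRigidTransform <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  R <- matrix(c(
    1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]),
    2 * (q[2] * q[4] + q[1] * q[3]),
    2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2),
    2 * (q[3] * q[4] - q[1] * q[2]),
    2 * (q[2] * q[4] - q[1] * q[3]), 2 * (q[3] * q[4] + q[1] * q[2]),
    1 - 2 * (q[2]^2 + q[3]^2)), 3, 3, byrow = TRUE)
  list(R = R, t = stats::rnorm(3, sd = 10))
}

applyTransform <- function(coords, tr) {
  sweep(coords %*% t(tr$R), 2, -tr$t)
}

# Build a ProteinStructure from parallel vectors; internal constructor used
# by the readers and generators.
newStructure <- function(elety, element, chain, resno, insert, resid,
                         occupancy, coords, title = "") {
  atoms <- data.frame(
    elety = as.character(elety), element = as.character(element),
    chain = as.character(chain), resno = as.integer(resno),
    insert = as.character(insert), resid = as.character(resid),
    occupancy = as.numeric(occupancy),
    mass = elementMass(element),
    hydrogen = toupper(element) %in% c("H", "D"),
    stringsAsFactors = FALSE)
  new("ProteinStructure", atoms = atoms,
      coords = matrix(as.numeric(coords), ncol = 3,
                      dimnames = list(NULL, c("x", "y", "z"))),
      title = title)
}
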