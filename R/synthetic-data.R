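# Seed-deterministic generators for every fixture the pipeline needs: toy
# elastic networks with a designed hinge, two-state gate trajectories,
# rotamer trajectories with prescribed circular chi1 distributions, and
# exact or perturbed C3 trimers. Each generator returns its ground truth
# alongside the coordinates so downstream operations are checkable without
# reference outputs.

#' Collinear C-alpha chain (path-graph fixture)
#'
#' \code{n} C-alpha pseudo-residues on a line at the given spacing. With
#' spacing s and a cutoff rc chosen so s < rc < 2s, only nearest
#' neighbours connect and the Kirchhoff matrix is the path-graph Laplacian,
#' whose spectrum 2 - 2 cos(k pi / n) is known in closed form.
#'
#' @param n number of residues (>= 2).
#' @param spacing inter-residue spacing, Angstrom (default 4).
#' @return a \linkS4class{ProteinStructure}.
#' @export
makePathStructure <- function(n, spacing = 4) {
  stopifnot(n >= 2L, spacing > 0)
  coords <- cbind((seq_len(n) - 1) * spacing, 0, 0)
  newStructure(elety = rep("CA", n), element = rep("C", n),
               chain = rep("A", n), resno = seq_len(n),
               insert = rep("", n), resid = rep("ALA", n),
               occupancy = rep(1, n), coords = coords,
               title = sprintf("path fixture n=%d spacing=%g", n, spacing))
}

#' Two-domain dumbbell with a designed hinge linker
#'
#' Builds two compact random C-alpha clusters joined by a near-linear
#' linker. The returned \code{hinge} indices are the linker residues: by
#' construction the slowest GNM mode moves the two domains in counterphase
#' and its sign crossover falls in the linker, giving a ground-truth hinge
#' for detection tests. Connectivity at the default rc = 7.3 Angstrom is
#' verified (not assumed); disconnected draws are regenerated up to
#' \code{retries} times before erroring.
#'
#' @param nPerDomain residues per domain (>= 4).
#' @param linkerLen linker residues (>= 1).
#' @param domainRadius domain packing radius, Angstrom.
#' @param separation centre-to-centre domain distance, Angstrom; linker
#'   spacing is derived from it. Default gives ~3.6 Angstrom linker steps.
#' @param seed RNG seed.
#' @param rc cutoff used for the connectivity check.
#' @param retries regeneration attempts for disconnected draws.
#' @return list: \code{structure}, \code{hinge} (linker residue indices).
#' @export
makeDumbbell <- function(nPerDomain = 20L, linkerLen = 6L,
                         domainRadius = 6, separation = 37, seed = 1L,
                         rc = 7.3, retries = 10L) {
  stopifnot(nPerDomain >= 4L, linkerLen >= 1L)
  ls <- (separation - 2 * domainRadius) / (linkerLen + 1)
  if (ls <= 0 || ls >= rc)
    stop("separation/linkerLen give linker spacing ", signif(ls, 3),
         "; must be in (0, rc)")
  ballPoint <- function(center, r) {
    repeat {
      p <- stats::runif(3, -r, r)
      if (sum(p^2) <= r^2) return(center + p)
    }
  }
  for (attempt in seq_len(retries)) {
    set.seed(as.integer(seed) + (attempt - 1L) * 100003L)
    cA <- c(0, 0, 0)
    cB <- c(separation, 0, 0)
    domA <- t(vapply(seq_len(nPerDomain - 1L),
                     function(i) ballPoint(cA, domainRadius), numeric(3)))
    domB <- t(vapply(seq_len(nPerDomain - 1L),
                     function(i) ballPoint(cB, domainRadius), numeric(3)))
    # deterministic anchors at the domain faces so the linker always docks
    anchorA <- c(domainRadius, 0, 0)
    anchorB <- c(separation - domainRadius, 0, 0)
    linker <- cbind(domainRadius + ls * seq_len(linkerLen), 0, 0)
    coords <- rbind(domA, anchorA, linker, anchorB, domB)
    n <- nrow(coords)
    s <- newStructure(elety = rep("CA", n), element = rep("C", n),
                      chain = rep("A", n), resno = seq_len(n),
                      insert = rep("", n), resid = rep("ALA", n),
                      occupancy = rep(1, n), coords = coords,
                      title = sprintf("dumbbell seed=%d", seed))
    k <- suppressWarnings(buildKirchhoff(s, rc = rc))
    if (k@nComponents == 1L) {
      hinge <- (nPerDomain + 1L):(nPerDomain + linkerLen)
      return(list(structure = s, hinge = hinge))
    }
  }
  stop("could not generate a connected dumbbell in ", retries, " attempts")
}

#' Two-state gate-distance trajectory
#'
#' Emulates the centre-of-mass distance behaviour of a gating residue pair:
#' two single-atom pseudo-residues placed along x at a per-frame distance
#' drawn from the active state's normal distribution (truncated at 0). The
#' gate starts open and switches to the closed state at
#' \code{switchFrame} (0-based: frames 0..switchFrame-1 open), so the
#' ground-truth closure time is switchFrame * dt. Defaults emulate a 200 ns
#' run (400 frames x 0.5 ns) with closed/open distances of 5 and 9
#' Angstrom and closure at 60 ns, the scale reported for extracellular
#' gate closure after substrate binding.
#'
#' @param nFrames frame count.
#' @param dt frame interval, ns.
#' @param openMean,openSd open-state distance distribution, Angstrom.
#' @param closedMean,closedSd closed-state distance distribution, Angstrom.
#' @param switchFrame 0-based index of the first closed frame (default:
#'   30\% into the run, i.e. 60 ns under the default frame layout); use
#'   \code{nFrames} for a gate that never closes.
#' @param seed RNG seed.
#' @param runId run label.
#' @return list: \code{trajectory} (\linkS4class{CoordTrajectory}),
#'   \code{distances} (ground-truth series), \code{state} (per-frame
#'   "open"/"closed").
#' @export
makeGateTrajectory <- function(nFrames = 400L, dt = 0.5, openMean = 9,
                               openSd = 0.5, closedMean = 5, closedSd = 0.5,
                               switchFrame = round(nFrames * 0.3),
                               seed = 1L, runId = "run1") {
  stopifnot(openMean > 0, closedMean > 0, openSd >= 0, closedSd >= 0,
            switchFrame >= 0L, switchFrame <= nFrames)
  set.seed(as.integer(seed))
  state <- rep(c("open", "closed"), c(switchFrame, nFrames - switchFrame))
  mu <- ifelse(state == "open", openMean, closedMean)
  sd <- ifelse(state == "open", openSd, closedSd)
  d <- stats::rnorm(nFrames, mu, sd)
  while (any(d <= 0)) {
    bad <- d <= 0
    d[bad] <- stats::rnorm(sum(bad), mu[bad], sd[bad])
  }
  topo <- newStructure(elety = c("CA", "CA"), element = c("C", "C"),
                       chain = c("A", "A"), resno = 1:2,
                       insert = c("", ""), resid = c("GLY", "GLY"),
                       occupancy = c(1, 1),
                       coords = rbind(c(0, 0, 0), c(d[1L], 0, 0)),
                       title = sprintf("gate fixture seed=%d", seed))
  frames <- array(0, c(2, 3, nFrames))
  frames[2, 1, ] <- d
  traj <- new("CoordTrajectory", topology = topo, frames = frames, dt = dt)
  list(trajectory = traj, distances = d, state = state)
}

#' Rotamer trajectory with prescribed circular chi1 states
#'
#' Builds a four-atom (N, CA, CB, CG) phenylalanine-like fragment on an
#' idealised scaffold (N-CA 1.46, CA-CB 1.53, CB-CG 1.50 Angstrom,
#' tetrahedral-like angles) and, per frame, places CG by rotating the cis
#' reference position about the CA-CB axis by a chi1 angle sampled from a
#' wrapped-normal mixture. Defaults are the two gating-rotamer states,
#' IF-like 170 +/- 15 degrees and OF-like 60 +/- 20 degrees, at equal
#' weight. The sampled chi1 values are returned as ground truth.
#'
#' @param nFrames frame count (default 2000).
#' @param states data.frame with columns label, mean, sd (degrees), weight
#'   (weights sum to 1).
#' @param seed RNG seed.
#' @param dt frame interval, ns.
#' @param runId run label.
#' @return list: \code{trajectory}, \code{chi1} (ground truth, degrees in
#'   (-180, 180]), \code{state} (per-frame sampled state label).
#' @export
makeRotamerTrajectory <- function(nFrames = 2000L,
                                  states = data.frame(
                                    label = c("IF-like", "OF-like"),
                                    mean = c(170, 60), sd = c(15, 20),
                                    weight = c(0.5, 0.5)),
                                  seed = 1L, dt = 0.1, runId = "run1") {
  stopifnot(abs(sum(states$weight) - 1) < 1e-9, all(states$sd >= 0))
  set.seed(as.integer(seed))
  pick <- sample.int(nrow(states), nFrames, replace = TRUE,
                     prob = states$weight)
  chi <- wrapAngle(stats::rnorm(nFrames, states$mean[pick],
                                states$sd[pick]))
  nPos <- 1.46 * c(sin(110 * pi / 180), 0, cos(110 * pi / 180))
  caPos <- c(0, 0, 0)
  cbPos <- c(0, 0, 1.53)
  frames <- array(0, c(4, 3, nFrames))
  for (f in seq_len(nFrames)) {
    cg <- placeAtom(nPos, caPos, cbPos, bond = 1.50, angle = 114,
                    dihedral = chi[f])
    frames[, , f] <- rbind(nPos, caPos, cbPos, cg)
  }
  topo <- newStructure(elety = c("N", "CA", "CB", "CG"),
                       element = c("N", "C", "C", "C"),
                       chain = rep("A", 4), resno = rep(155L, 4),
                       insert = rep("", 4), resid = rep("PHE", 4),
                       occupancy = rep(1, 4), coords = frames[, , 1L],
                       title = sprintf("rotamer fixture seed=%d", seed))
  traj <- new("CoordTrajectory", topology = topo, frames = frames, dt = dt)
  list(trajectory = traj, chi1 = chi, state = states$label[pick])
}

#' Coarse membrane-spanning monomer for trimer fixtures
#'
#' A C-alpha trace that descends from the membrane, crosses it twice
#' (hairpin: up and back down), so both termini sit on one side of the
#' slab. Tryptophans are placed at the four interface crossings (or at the
#' membrane core, for a deliberately mis-anchored control). Centred around
#' \code{xOffset} off the z axis so three rotated copies form a trimer.
#'
#' @param nRes residue count (default 40).
#' @param xOffset lateral offset from the membrane normal axis, Angstrom.
#' @param terminiSide "IC" (termini at z = -22, intracellular with the
#'   default membrane) or "EC" (flipped hairpin, termini extracellular).
#' @param trpAtInterface place Trp at |z| = 15 (TRUE) or at the membrane
#'   core z = 0 (FALSE).
#' @param seed RNG seed for small lateral jitter.
#' @return a \linkS4class{ProteinStructure}.
#' @export
makeMembraneMonomer <- function(nRes = 40L, xOffset = 15,
                                terminiSide = c("IC", "EC"),
                                trpAtInterface = TRUE, seed = 1L) {
  terminiSide <- match.arg(terminiSide)
  stopifnot(nRes >= 12L)
  set.seed(as.integer(seed))
  half <- nRes %/% 2L
  z <- c(seq(-22, 20, length.out = half),
         seq(20, -22, length.out = nRes - half))
  if (terminiSide == "EC") z <- -z
  x <- xOffset + stats::rnorm(nRes, sd = 1)
  y <- stats::rnorm(nRes, sd = 1)
  resid <- rep("ALA", nRes)
  target <- if (trpAtInterface) 15 else 0
  # one Trp per membrane crossing of the target plane(s)
  planes <- if (trpAtInterface) c(-15, 15) else 0
  for (p in planes) {
    cross <- which(diff(sign(z - p)) != 0)
    for (cc in cross) resid[cc] <- "TRP"
  }
  newStructure(elety = rep("CA", nRes), element = rep("C", nRes),
               chain = rep("A", nRes), resno = seq_len(nRes),
               insert = rep("", nRes), resid = resid,
               occupancy = rep(1, nRes), coords = cbind(x, y, z),
               title = sprintf("membrane monomer (%s termini)", terminiSide))
}

#' Build a (possibly perturbed) C3 trimer from a monomer
#'
#' Copies the monomer at 0, 120 and 240 degrees about the membrane normal
#' axis (z by default) and optionally adds independent Gaussian noise of
#' standard deviation \code{perturbSd} to every coordinate of the rotated
#' copies. With \code{perturbSd = 0} the model is exactly C3 and
#' \code{\link{c3Score}} is zero.
#'
#' @param monomer a \linkS4class{ProteinStructure}, laterally offset from
#'   the z axis.
#' @param perturbSd per-coordinate noise SD, Angstrom (default 0).
#' @param seed RNG seed (used only when perturbSd > 0).
#' @param membrane a \linkS4class{MembraneFrame}.
#' @param clusterId,clusterSize cluster metadata for ranking.
#' @return a \linkS4class{TrimerModel}.
#' @export
makeC3Trimer <- function(monomer, perturbSd = 0, seed = 1L,
                         membrane = membraneFrame(), clusterId = "c1",
                         clusterSize = 1L) {
  stopifnot(is(monomer, "ProteinStructure"))
  set.seed(as.integer(seed))
  monomers <- lapply(0:2, function(i) {
    R <- rotationMatrix(c(0, 0, 1), i * 2 * pi / 3)
    m <- monomer
    xyz <- monomer@coords %*% t(R)
    if (perturbSd > 0)
      xyz <- xyz + matrix(stats::rnorm(length(xyz), sd = perturbSd),
                          ncol = 3)
    m@coords <- xyz
    m
  })
  new("TrimerModel", monomers = monomers, membrane = membrane,
      clusterId = clusterId, clusterSize = as.integer(clusterSize))
}

#' Three-model trimer test set
#'
#' A small, fully synthetic candidate set exercising every filter outcome:
#' \itemize{
#'   \item \code{c1} (size 120): exact C3, IC termini, interfacial Trp --
#'     passes all criteria;
#'   \item \code{c2} (size 120): exact C3 but extracellular termini --
#'     fails the termini criterion (and ties \code{c1} on size, so rank
#'     order exercises the id tie-break);
#'   \item \code{c3} (size 40): three translated (unrotated) copies with
#'     collinear centroids -- the symmetry axis is degenerate, recorded as
#'     a criterion failure with the error message as reason.
#' }
#'
#' @param seed RNG seed.
#' @return list: \code{models} (list of \linkS4class{TrimerModel}) and
#'   \code{manifest} (data.frame cluster_id, cluster_size, expected).
#' @export
makeTrimerTestSet <- function(seed = 1L) {
  seed <- as.integer(seed)
  monoIC <- makeMembraneMonomer(terminiSide = "IC", seed = seed)
  monoEC <- makeMembraneMonomer(terminiSide = "EC", seed = seed + 1L)
  m1 <- makeC3Trimer(monoIC, perturbSd = 0, seed = seed,
                     clusterId = "c1", clusterSize = 120L)
  m2 <- makeC3Trimer(monoEC, perturbSd = 0, seed = seed,
                     clusterId = "c2", clusterSize = 120L)
  shift <- function(s, dx) { s@coords <- sweep(s@coords, 2, -c(dx, 0, 0)); s }
  m3 <- new("TrimerModel",
            monomers = list(monoIC, shift(monoIC, 30), shift(monoIC, 60)),
            membrane = membraneFrame(), clusterId = "c3",
            clusterSize = 40L)
  list(models = list(m1, m2, m3),
       manifest = data.frame(
         cluster_id = c("c1", "c2", "c3"),
         cluster_size = c(120L, 120L, 40L),
         expected = c("pass", "fail_termini", "fail_degenerate_axis"),
         stringsAsFactors = FALSE))
}
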