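#' Default membrane frame
#'
#' Implicit slab: normal along +z, midplane at z = 0, half-thickness 15
#' Angstrom, intracellular side toward -z, matching the usual orientation
#' convention for membrane-protein models.
#'
#' @param normal unit normal (default +z).
#' @param midplane midplane offset along the normal, Angstrom.
#' @param halfThickness half slab thickness, Angstrom.
#' @param icSide +1 or -1: which direction along the normal is
#'   intracellular (default -1).
#' @return a \linkS4class{MembraneFrame}.
#' @export
membraneFrame <- function(normal = c(0, 0, 1), midplane = 0,
                          halfThickness = 15, icSide = -1) {
  new("MembraneFrame", normal = normal / sqrt(sum(normal^2)),
      midplane = midplane, halfThickness = halfThickness, icSide = icSide)
}

.monomerCentroids <- function(trimer) {
  t(vapply(trimer@monomers, function(m)
    massCenter(m@coords, m@atoms$mass), numeric(3)))
}

# Signed coordinate along the membrane normal, midplane at 0.
.normalCoord <- function(points, membrane) {
  drop(points %*% membrane@normal) - membrane@midplane
}

#' Symmetry axis of a trimer
#'
#' The axis is the normal of the plane through the three monomer
#' centroids, anchored at their mean and oriented along the membrane
#' normal. This closed-form construction is exact for C3 trimers and
#' adequate for near-symmetric models; it degrades for badly broken
#' symmetry (see the package vignette).
#'
#' @param trimer a \linkS4class{TrimerModel}.
#' @return list with unit \code{axis} and \code{center}.
#' @export
symmetryAxis <- function(trimer) {
  stopifnot(is(trimer, "TrimerModel"))
  cen <- .monomerCentroids(trimer)
  v1 <- cen[2L, ] - cen[1L, ]
  v2 <- cen[3L, ] - cen[1L, ]
  ax <- c(v1[2] * v2[3] - v1[3] * v2[2],
          v1[3] * v2[1] - v1[1] * v2[3],
          v1[1] * v2[2] - v1[2] * v2[1])
  nrm <- sqrt(sum(ax^2))
  scale <- sqrt(sum(v1^2)) * sqrt(sum(v2^2))
  if (nrm < 1e-8 * max(scale, 1))
    stop("monomer centroids are collinear; symmetry axis undefined")
  ax <- ax / nrm
  if (sum(ax * trimer@membrane@normal) < 0) ax <- -ax
  list(axis = ax, center = colMeans(cen))
}

#' Deviation from exact three-fold symmetry, in Angstrom
#'
#' Rotates monomer i by +120 degrees about the trimer symmetry axis and
#' measures the coordinate RMSD against monomer i+1 (mod 3) with no
#' further fitting; the score is the mean over the three ordered pairs.
#' Zero for an exact C3 trimer; grows with the magnitude of any symmetry-
#' breaking perturbation. Invariant under whole-trimer rigid transforms
#' (the membrane frame is assumed co-transformed).
#'
#' @param trimer a \linkS4class{TrimerModel}.
#' @return score in Angstrom (>= 0).
#' @export
c3Score <- function(trimer) {
  ax <- symmetryAxis(trimer)
  # +120 degrees about the membrane-oriented axis must map monomer i onto
  # i+1 (mod 3); monomer order is part of the model definition, so a
  # reversed labelling scores poorly by design
  R <- rotationMatrix(ax$axis, 2 * pi / 3)
  tot <- 0
  for (i in 1:3) {
    j <- i %% 3L + 1L
    xi <- sweep(trimer@monomers[[i]]@coords, 2, ax$center)
    xj <- sweep(trimer@monomers[[j]]@coords, 2, ax$center)
    ri <- xi %*% t(R)
    tot <- tot + sqrt(mean(rowSums((ri - xj)^2)))
  }
  tot / 3
}


#' Intracellular exposure of the chain termini
#'
#' For each monomer, the centroids of the first \code{nSpan} and last
#' \code{cSpan} residues must lie on the intracellular side of the
#' membrane, beyond the slab (|signed normal coordinate| > half-thickness,
#' with the sign of the IC side). Multi-residue spans are used because
#' single-atom termini are noise-sensitive.
#'
#' @param trimer a \linkS4class{TrimerModel}.
#' @param nSpan,cSpan number of terminal residues in each span (default 3).
#' @return data.frame: monomer, n_pass, c_pass, pass; attribute
#'   \code{"pass"} gives the overall verdict.
#' @export
terminiCheck <- function(trimer, nSpan = 3L, cSpan = 3L) {
  stopifnot(is(trimer, "TrimerModel"))
  mem <- trimer@membrane
  res <- lapply(seq_len(3L), function(i) {
    m <- trimer@monomers[[i]]
    ridx <- residueAtomIndex(m)
    if (nSpan < 1L || cSpan < 1L || nSpan + cSpan > length(ridx))
      stop("terminal spans are empty or overlap (monomer has ",
           length(ridx), " residues)")
    nRows <- unlist(ridx[seq_len(nSpan)])
    cRows <- unlist(ridx[(length(ridx) - cSpan + 1L):length(ridx)])
    zc <- function(rows) {
      cen <- massCenter(m@coords[rows, , drop = FALSE], m@atoms$mass[rows])
      .normalCoord(matrix(cen, 1), mem)
    }
    zn <- zc(nRows); zcc <- zc(cRows)
    ok <- function(z) (z * mem@icSide) > mem@halfThickness
    data.frame(monomer = i, n_z = zn, c_z = zcc,
               n_pass = ok(zn), c_pass = ok(zcc),
               pass = ok(zn) && ok(zcc))
  })
  out <- do.call(rbind, res)
  attr(out, "pass") <- all(out$pass)
  out
}

#' Tryptophan membrane-anchoring score
#'
#' Tryptophans anchor membrane proteins at the lipid headgroup interfaces;
#' a well-oriented model places their sidechains in bands around the two
#' membrane surfaces. The score is the fraction of Trp sidechain centroids
#' whose distance from the nearer membrane surface (|normal coordinate| =
#' half-thickness) is at most \code{bandWidth / 2}.
#'
#' @param trimer a \linkS4class{TrimerModel}.
#' @param bandWidth interfacial band width, Angstrom (default 6).
#' @param threshold pass when the fraction >= threshold (default 0.5).
#' @return list: \code{fraction}, \code{nTrp}, \code{pass} (NA when the
#'   trimer has no tryptophan: criterion not applicable).
#' @export
trpAnchorScore <- function(trimer, bandWidth = 6, threshold = 0.5) {
  stopifnot(is(trimer, "TrimerModel"))
  mem <- trimer@membrane
  zs <- numeric(0)
  for (m in trimer@monomers) {
    a <- m@atoms
    key <- .resKey(a)
    for (k in unique(key[a$resid == "TRP"])) {
      rows <- which(key == k & !a$hydrogen)
      side <- rows[!(a$elety[rows] %in% .BACKBONE)]
      if (length(side) == 0L) side <- rows   # CA-only coarse models
      cen <- massCenter(m@coords[side, , drop = FALSE], a$mass[side])
      zs <- c(zs, .normalCoord(matrix(cen, 1), mem))
    }
  }
  if (length(zs) == 0L)
    return(list(fraction = NA_real_, nTrp = 0L, pass = NA))
  inband <- abs(abs(zs) - mem@halfThickness) <= bandWidth / 2
  frac <- mean(inband)
  list(fraction = frac, nTrp = length(zs), pass = frac >= threshold)
}

#' Rank trimer models by cluster size and filter by structural criteria
#'
#' Models are sorted by cluster size, largest first (ties broken by
#' cluster id, ascending), then each is evaluated against the enabled
#' criteria: (1) pseudo-three-fold symmetry (\code{\link{c3Score}} below
#' \code{c3Bound}); (2) intracellular exposure of both termini
#' (\code{\link{terminiCheck}}); (3) interfacial tryptophan anchoring
#' (\code{\link{trpAnchorScore}}). A criterion that errors on a model
#' (e.g. a degenerate symmetry axis) marks the model failed with the error
#' message as the reason. Survivors retain rank order.
#'
#' @param models list of \linkS4class{TrimerModel}s.
#' @param criteria character subset of c("c3", "termini", "trp");
#'   empty vector disables filtering (all models survive, ranked).
#' @param c3Bound pseudo-symmetry pass bound for the C3 score, Angstrom
#'   (default 5).
#' @param bandWidth,trpThreshold see \code{\link{trpAnchorScore}}.
#' @param nSpan,cSpan see \code{\link{terminiCheck}}.
#' @return list: \code{report} data.frame (one row per model, rank order,
#'   per-criterion score/pass/reason columns, overall \code{pass}) and
#'   \code{survivors}, the passing models in rank order.
#' @export
rankAndFilter <- function(models, criteria = c("c3", "termini", "trp"),
                          c3Bound = 5, bandWidth = 6, trpThreshold = 0.5,
                          nSpan = 3L, cSpan = 3L) {
  if (length(models) == 0L) stop("no models supplied")
  stopifnot(all(vapply(models, is, logical(1), "TrimerModel")))
  if (length(criteria))
    criteria <- match.arg(criteria, c("c3", "termini", "trp"),
                          several.ok = TRUE)
  sizes <- vapply(models, function(m) m@clusterSize, integer(1))
  ids <- vapply(models, function(m) m@clusterId, character(1))
  ord <- order(-sizes, ids)
  rows <- list()
  survivors <- list()
  for (r in seq_along(ord)) {
    m <- models[[ord[r]]]
    row <- data.frame(rank = r, cluster_id = m@clusterId,
                      cluster_size = m@clusterSize,
                      c3_score = NA_real_, c3_pass = NA,
                      termini_pass = NA, trp_fraction = NA_real_,
                      trp_pass = NA, pass = TRUE, reason = "",
                      stringsAsFactors = FALSE)
    fail <- character(0)
    eval1 <- function(expr) tryCatch(list(ok = TRUE, val = expr),
                                     error = function(e)
                                       list(ok = FALSE, val = conditionMessage(e)))
    if ("c3" %in% criteria) {
      res <- eval1(c3Score(m))
      if (res$ok) {
        row$c3_score <- res$val
        row$c3_pass <- res$val <= c3Bound
        if (!row$c3_pass) fail <- c(fail, sprintf(
          "c3_score %.2f > %.2f", res$val, c3Bound))
      } else {
        row$c3_pass <- FALSE
        fail <- c(fail, paste0("c3: ", res$val))
      }
    }
    if ("termini" %in% criteria) {
      res <- eval1(terminiCheck(m, nSpan, cSpan))
      if (res$ok) {
        row$termini_pass <- attr(res$val, "pass")
        if (!row$termini_pass) fail <- c(fail, "termini not IC-exposed")
      } else {
        row$termini_pass <- FALSE
        fail <- c(fail, paste0("termini: ", res$val))
      }
    }
    if ("trp" %in% criteria) {
      res <- eval1(trpAnchorScore(m, bandWidth, trpThreshold))
      if (res$ok) {
        row$trp_fraction <- res$val$fraction
        if (is.na(res$val$pass)) {
          row$trp_pass <- NA        # no Trp: criterion not applicable
        } else {
          row$trp_pass <- res$val$pass
          if (!res$val$pass) fail <- c(fail, sprintf(
            "trp fraction %.2f < %.2f", res$val$fraction, trpThreshold))
        }
      } else {
        row$trp_pass <- FALSE
        fail <- c(fail, paste0("trp: ", res$val))
      }
    }
    row$pass <- length(fail) == 0L
    row$reason <- paste(fail, collapse = "; ")
    rows[[r]] <- row
    if (row$pass) survivors[[length(survivors) + 1L]] <- m
  }
  list(report = do.call(rbind, rows), survivors = survivors)
}
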