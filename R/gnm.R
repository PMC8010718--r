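#' Build the Kirchhoff (connectivity Laplacian) matrix of a structure
#'
#' The protein is reduced to a network of nodes (one atom per residue, by
#' default the C-alpha) connected by uniform springs. Off-diagonal element
#' (i, j) of the Kirchhoff matrix is -1 when the node atoms of residues i
#' and j lie strictly within the cutoff \code{rc}, 0 otherwise; the diagonal
#' carries the node degree, so every row sums to zero. The default cutoff of
#' 7.3 Angstrom sits at the midpoint of the 7.0-7.5 Angstrom range commonly
#' used for folded proteins.
#'
#' @param structure a \linkS4class{ProteinStructure}.
#' @param rc contact cutoff, Angstrom (contact iff distance < rc).
#' @param nodeAtom atom name defining each residue's node (default "CA").
#' @return a \linkS4class{KirchhoffMatrix}; a warning is raised (and carried
#'   downstream via the component count) when the network is disconnected.
#' @examples
#' k <- buildKirchhoff(makePathStructure(3, spacing = 4), rc = 7.3)
#' k@matrix
#' @export
buildKirchhoff <- function(structure, rc = 7.3, nodeAtom = "CA") {
  stopifnot(is(structure, "ProteinStructure"))
  if (rc <= 0) stop("rc must be > 0")
  a <- structure@atoms
  key <- .resKey(a)
  ukey <- unique(key)
  nodeRow <- vapply(ukey, function(k) {
    i <- which(key == k & a$elety == nodeAtom)
    if (length(i)) i[1L] else NA_integer_
  }, integer(1))
  if (anyNA(nodeRow)) {
    ids <- .resId(a)[!duplicated(key)]
    stop("residue(s) missing node atom '", nodeAtom, "': ",
         paste(ids[is.na(nodeRow)], collapse = ", "))
  }
  xyz <- structure@coords[nodeRow, , drop = FALSE]
  n <- nrow(xyz)
  D <- as.matrix(stats::dist(xyz))
  A <- (D < rc) * 1
  diag(A) <- 0
  G <- diag(rowSums(A)) - A
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  ncomp <- igraph::components(g)$no
  if (ncomp > 1L)
    warning("contact network is disconnected (", ncomp,
            " components) at rc = ", rc)
  new("KirchhoffMatrix", matrix = unname(G), rc = rc,
      nodeIds = .resId(a)[nodeRow], nComponents = as.integer(ncomp))
}

#' Decompose a Kirchhoff matrix into GNM normal modes
#'
#' Returns the full spectrum of the Kirchhoff matrix, eigenvalues ascending.
#' A connected network of N nodes yields one zero eigenvalue and N-1 normal
#' modes; the number of numerically zero eigenvalues equals the number of
#' connected components. Eigenvector signs are fixed deterministically
#' (first nonzero element positive) so mode shapes are reproducible across
#' eigensolver implementations.
#'
#' @param kirchhoff a \linkS4class{KirchhoffMatrix}.
#' @param zeroTol relative tolerance: eigenvalues below
#'   \code{zeroTol * max(eigenvalue)} count as zero.
#' @return a \linkS4class{GNMModes}.
#' @export
gnmModes <- function(kirchhoff, zeroTol = 1e-8) {
  stopifnot(is(kirchhoff, "KirchhoffMatrix"))
  e <- eigen(kirchhoff@matrix, symmetric = TRUE)
  ord <- order(e$values)
  vals <- e$values[ord]
  vecs <- e$vectors[, ord, drop = FALSE]
  vals[abs(vals) < zeroTol * max(abs(vals), 1)] <- 0
  vals <- pmax(vals, 0)
  for (j in seq_len(ncol(vecs))) {
    nz <- which(abs(vecs[, j]) > 1e-12)
    if (length(nz) && vecs[nz[1L], j] < 0) vecs[, j] <- -vecs[, j]
  }
  nzero <- sum(vals == 0)
  if (nzero != kirchhoff@nComponents)
    warning("zero-mode count (", nzero, ") differs from component count (",
            kirchhoff@nComponents, "); check zeroTol")
  new("GNMModes", eigenvalues = vals, vectors = vecs,
      nZero = as.integer(nzero),
      zeroTol = zeroTol * max(abs(vals), 1), nodeIds = kirchhoff@nodeIds)
}

.assertConnected <- function(modes, force = FALSE, what = "analysis") {
  if (modes@nZero > 1L && !force)
    stop(what, " requires a connected network (", modes@nZero,
         " zero modes found); pass force = TRUE to override")
  invisible(TRUE)
}

#' Cross-correlations between residue fluctuations
#'
#' Computes \code{scale * pseudo-inverse(Kirchhoff)} from the spectral form,
#' excluding zero modes: element (i, j) is the cross-correlation
#' <dRi . dRj> in units of 3kBT/gamma. With the default \code{scale = 1}
#' results are in reduced units; supply \code{scale = 3*kB*T/gamma} for
#' physical units.
#'
#' @param modes a \linkS4class{GNMModes} from a connected network.
#' @param scale prefactor (default 1).
#' @param force proceed despite a disconnected network.
#' @return symmetric N x N matrix with residue ids as dimnames.
#' @export
crossCorrelations <- function(modes, scale = 1, force = FALSE) {
  stopifnot(is(modes, "GNMModes"))
  .assertConnected(modes, force, "cross-correlation")
  keep <- which(modes@eigenvalues > 0)
  U <- modes@vectors[, keep, drop = FALSE]
  C <- U %*% (t(U) / modes@eigenvalues[keep]) * scale
  C <- (C + t(C)) / 2
  dimnames(C) <- list(modes@nodeIds, modes@nodeIds)
  C
}

#' Per-residue mean-square fluctuations
#'
#' Diagonal of the cross-correlation matrix: <dRi^2> in units of 3kBT/gamma.
#'
#' @inheritParams crossCorrelations
#' @return named numeric vector, one value per residue, all > 0 for a
#'   connected network.
#' @export
squareFluctuations <- function(modes, scale = 1, force = FALSE) {
  diag(crossCorrelations(modes, scale = scale, force = force))
}

#' Shape of a GNM mode
#'
#' Returns eigenvector k (1 = slowest nonzero mode) mapped to residue
#' identifiers. The sign convention (first nonzero element positive) is
#' applied at decomposition time, so repeated calls and different
#' eigensolvers agree.
#'
#' @param modes a \linkS4class{GNMModes}.
#' @param k nonzero-mode index, 1..(N - nZero).
#' @return named numeric vector of per-residue amplitudes.
#' @export
modeShape <- function(modes, k = 1L) {
  stopifnot(is(modes, "GNMModes"))
  nmodes <- length(modes@eigenvalues) - modes@nZero
  if (k < 1L || k > nmodes)
    stop("mode index k must be in 1..", nmodes, " (got ", k, ")")
  v <- modes@vectors[, modes@nZero + k]
  names(v) <- modes@nodeIds
  v
}

#' Identify global hinge residues from slow-mode shapes
#'
#' Global hinges are the regions where the slowest modes change sign:
#' a residue is flagged when (a) it sits at a sign crossover between
#' consecutive sequence neighbours of the mode eigenvector, or (b) its
#' amplitude is within \code{zeroBand * max|u_k|} of zero. Modes are
#' analysed independently (defaults: modes 1 and 2, the two slowest) and
#' combined as the union or the intersection of per-mode hinge sets, with
#' per-mode provenance retained either way.
#'
#' @param modes a \linkS4class{GNMModes} from a connected network.
#' @param modeIndices nonzero-mode indices to analyse (default 1:2).
#' @param zeroBand near-zero band as a fraction of the mode's max
#'   amplitude (default 0.1).
#' @param combine "union" (hinge in any requested mode) or "intersection"
#'   (hinge in all requested modes).
#' @param force proceed despite a disconnected network.
#' @return data.frame with columns \code{node} (index), \code{residue},
#'   \code{mode}, \code{rule} ("crossover", "zero_band" or both), and
#'   \code{amplitude}; zero rows when no hinge is found.
#' @export
findHinges <- function(modes, modeIndices = c(1L, 2L), zeroBand = 0.1,
                       combine = c("union", "intersection"), force = FALSE) {
  stopifnot(is(modes, "GNMModes"))
  combine <- match.arg(combine)
  .assertConnected(modes, force, "hinge analysis")
  perMode <- list()
  for (k in modeIndices) {
    u <- modeShape(modes, k)
    if (max(abs(u)) < 1e-12) stop("mode ", k, " is degenerate (all zero)")
    n <- length(u)
    cross <- rep(FALSE, n)
    sc <- which(u[-n] * u[-1L] < 0)
    cross[sc] <- TRUE
    cross[sc + 1L] <- TRUE
    zb <- abs(u) < zeroBand * max(abs(u))
    hit <- cross | zb
    if (any(hit)) {
      rule <- ifelse(cross & zb, "crossover+zero_band",
                     ifelse(cross, "crossover", "zero_band"))
      perMode[[as.character(k)]] <- data.frame(
        node = which(hit), residue = modes@nodeIds[hit], mode = k,
        rule = rule[hit], amplitude = unname(u[hit]),
        stringsAsFactors = FALSE)
    } else {
      perMode[[as.character(k)]] <- data.frame(
        node = integer(0), residue = character(0), mode = integer(0),
        rule = character(0), amplitude = numeric(0))
    }
  }
  out <- do.call(rbind, perMode)
  rownames(out) <- NULL
  if (combine == "intersection" && length(modeIndices) > 1L) {
    tab <- table(unique(out[, c("node", "mode")])$node)
    keep <- as.integer(names(tab)[tab == length(modeIndices)])
    out <- out[out$node %in% keep, , drop = FALSE]
  }
  out[order(out$node, out$mode), , drop = FALSE]
}

#' Tabulate a GNM analysis as a per-residue report
#'
#' Convenience wrapper combining mode shapes, square fluctuations and hinge
#' flags into one table (the per-residue analogue of a slow-mode shape plot
#' with hinge residues marked).
#'
#' @param modes a \linkS4class{GNMModes}.
#' @param modeIndices modes to tabulate and to use for hinge detection.
#' @param zeroBand see \code{\link{findHinges}}.
#' @param force proceed despite a disconnected network.
#' @return data.frame: residue_id, mode<k>_amplitude columns, sq_fluct,
#'   hinge_flag, hinge_rule.
#' @export
gnmReport <- function(modes, modeIndices = c(1L, 2L), zeroBand = 0.1,
                      force = FALSE) {
  shapes <- sapply(modeIndices, function(k) modeShape(modes, k))
  colnames(shapes) <- paste0("mode", modeIndices, "_amplitude")
  hinges <- findHinges(modes, modeIndices, zeroBand, force = force)
  n <- length(modes@nodeIds)
  flag <- seq_len(n) %in% hinges$node
  rule <- vapply(seq_len(n), function(i) {
    r <- hinges[hinges$node == i, ]
    if (nrow(r) == 0L) return("")
    paste(paste0("m", r$mode, ":", r$rule), collapse = ";")
  }, character(1))
  data.frame(residue_id = modes@nodeIds, shapes,
             sq_fluct = unname(squareFluctuations(modes, force = force)),
             hinge_flag = flag, hinge_rule = rule,
             stringsAsFactors = FALSE)
}

#' Plot the shape of a GNM mode with hinges highlighted
#'
#' @param modes a \linkS4class{GNMModes}.
#' @param k mode index (default 1, the global mode).
#' @param zeroBand hinge near-zero band (fraction of max amplitude).
#' @param ... passed to \code{plot}.
#' @return invisibly, the hinge table for mode k.
#' @export
plotModeShape <- function(modes, k = 1L, zeroBand = 0.1, ...) {
  u <- modeShape(modes, k)
  graphics::plot(seq_along(u), u, type = "l",
                 xlab = "residue index", ylab = paste0("mode ", k,
                 " amplitude"), ...)
  graphics::abline(h = 0, lty = 2, col = "grey50")
  h <- findHinges(modes, modeIndices = k, zeroBand = zeroBand)
  if (nrow(h))
    graphics::points(h$node, h$amplitude, pch = 15, col = "red")
  invisible(h)
}
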