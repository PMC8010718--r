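test_that("Kirchhoff matrix matches hand-built contact topologies", {
  # 3 collinear nodes, 4 A spacing: ends 8 A apart are beyond rc
  k <- buildKirchhoff(makePathStructure(3, spacing = 4), rc = 7.3)
  expect_equal(k@matrix,
               matrix(c(1, -1, 0, -1, 2, -1, 0, -1, 1), 3, 3))
  expect_equal(k@nComponents, 1L)

  # equilateral triangle side 5: complete graph
  tri <- gatemech:::newStructure(
    elety = rep("CA", 3), element = rep("C", 3), chain = rep("A", 3),
    resno = 1:3, insert = rep("", 3), resid = rep("ALA", 3),
    occupancy = rep(1, 3),
    coords = rbind(c(0, 0, 0), c(5, 0, 0), c(2.5, 5 * sqrt(3) / 2, 0)))
  kt <- buildKirchhoff(tri, rc = 7.3)
  expect_equal(diag(kt@matrix), rep(2, 3))
  expect_true(all(kt@matrix[row(kt@matrix) != col(kt@matrix)] == -1))

  # two isolated nodes: zero matrix plus disconnection warning
  far <- makePathStructure(2, spacing = 10)
  expect_warning(kf <- buildKirchhoff(far, rc = 7.3), "disconnected")
  expect_equal(kf@matrix, matrix(0, 2, 2))
  expect_equal(kf@nComponents, 2L)
})

test_that("residues lacking the node atom are listed in the error", {
  s <- gatemech:::newStructure(
    elety = c("CA", "N"), element = c("C", "N"), chain = c("A", "A"),
    resno = 1:2, insert = c("", ""), resid = c("ALA", "ALA"),
    occupancy = c(1, 1), coords = rbind(c(0, 0, 0), c(4, 0, 0)))
  expect_error(buildKirchhoff(s), "A:2")
})

test_that("path-graph spectra match the closed form 2 - 2 cos(k pi / N)", {
  for (n in 3:12) {
    m <- gnmModes(buildKirchhoff(makePathStructure(n, 4), rc = 7.3))
    expect_equal(m@eigenvalues, 2 - 2 * cos((0:(n - 1)) * pi / n),
                 tolerance = 1e-10)
    expect_equal(m@nZero, 1L)
  }
})

test_that("eigenvectors are orthonormal and reconstruct the Kirchhoff matrix", {
  s <- makeConnectedStructure(30, seed = 4)
  k <- buildKirchhoff(s)
  m <- gnmModes(k)
  U <- m@vectors
  expect_lt(max(abs(crossprod(U) - diag(nrow(U)))), 1e-8)
  recon <- U %*% diag(m@eigenvalues) %*% t(U)
  expect_lt(norm(recon - k@matrix, "F") / norm(k@matrix, "F"), 1e-8)
  # eigen residual per mode
  for (j in c(1, 5, 15))
    expect_lt(max(abs(k@matrix %*% U[, j] - m@eigenvalues[j] * U[, j])),
              1e-8)
})

test_that("cross-correlations equal the dense pseudo-inverse oracle", {
  skip_if_not_installed("MASS")
  # hand-derived P3 pseudo-inverse from its spectral form
  m3 <- gnmModes(buildKirchhoff(makePathStructure(3, 4), rc = 7.3))
  C3 <- crossCorrelations(m3)
  expect_equal(unname(C3),
               matrix(c(5, -1, -4, -1, 2, -1, -4, -1, 5), 3, 3) / 9,
               tolerance = 1e-12)
  expect_equal(unname(diag(C3)), c(5, 2, 5) / 9, tolerance = 1e-12)

  for (seed in 1:5) {
    s <- makeConnectedStructure(8 + 5 * seed, seed = seed)
    k <- buildKirchhoff(s)
    m <- gnmModes(k)
    C <- crossCorrelations(m)
    G <- MASS::ginv(k@matrix)
    expect_lt(norm(unname(C) - G, "F") / norm(G, "F"), 1e-8)
    expect_lt(max(abs(C - t(C))), 1e-12)
    expect_equal(unname(diag(C)), unname(squareFluctuations(m)))
  }
  # scale propagates linearly
  expect_equal(crossCorrelations(m3, scale = 2.5), 2.5 * C3)
})

test_that("GNM agrees with an independent elastic-network implementation", {
  db <- makeDumbbell(seed = 5)
  tmp <- tempfile(fileext = ".pdb")
  writePDB(db$structure, tmp)
  # the reference implementation warns about the coarse fixture's
  # non-peptide geometry; irrelevant to the spectral comparison
  ref <- suppressWarnings(bio3d::gnm(bio3d::read.pdb(tmp), cutoff = 7.3))
  m <- gnmModes(buildKirchhoff(db$structure, rc = 7.3))
  expect_equal(sort(ref$L), m@eigenvalues, tolerance = 1e-8)
  # fluctuations proportional (reference applies a physical 3kBT/gamma)
  f <- squareFluctuations(m)
  ratio <- ref$fluctuations / f
  expect_lt(diff(range(ratio)) / mean(ratio), 1e-8)
})

test_that("disconnected networks are refused unless forced", {
  s <- makeClusteredStructure(2, seed = 1)
  k <- suppressWarnings(buildKirchhoff(s))
  m <- suppressWarnings(gnmModes(k))
  expect_equal(m@nZero, 2L)
  expect_error(crossCorrelations(m), "connected")
  expect_error(findHinges(m), "connected")
  expect_true(all(squareFluctuations(m, force = TRUE) > 0 |
                  abs(squareFluctuations(m, force = TRUE)) < 1e-12))
})

test_that("square fluctuations are uniform on the symmetric complete graph", {
  tri <- makeClusteredStructure(1, perComp = 3, seed = 3)
  # force a complete graph with a generous cutoff
  m <- gnmModes(buildKirchhoff(tri, rc = 20))
  f <- squareFluctuations(m)
  expect_lt(diff(range(f)), 1e-10)
  expect_true(all(f > 0))
})

test_that("mode shapes follow the sign convention and path-cosine profile", {
  m <- gnmModes(buildKirchhoff(makePathStructure(5, 4)))
  u1 <- modeShape(m, 1)
  expect_gt(u1[[1]], 0)                      # first nonzero element positive
  expect_true(all(diff(u1) < 0))             # sampled cosine is monotone
  expect_equal(u1[[3]], 0, tolerance = 1e-12) # central node is the zero
  expect_error(modeShape(m, 5), "mode index")
  expect_error(modeShape(m, 0), "mode index")
})

test_that("hinges sit at slow-mode sign crossovers", {
  # even-N path: mode 1 crosses zero between N/2 and N/2+1
  n <- 10
  m <- gnmModes(buildKirchhoff(makePathStructure(n, 4)))
  h <- findHinges(m, modeIndices = 1, zeroBand = 0.05)
  expect_setequal(h$node[h$rule == "crossover"], c(n / 2, n / 2 + 1))

  # dumbbell: designed linker recovered
  db <- makeDumbbell(seed = 11)
  md <- gnmModes(buildKirchhoff(db$structure))
  hd <- findHinges(md, modeIndices = 1)
  band <- (min(db$hinge) - 1):(max(db$hinge) + 1)
  expect_gt(length(intersect(hd$node, band)), 0)

  # union vs intersection combination over modes 1 and 2
  hu <- findHinges(md, modeIndices = c(1, 2), combine = "union")
  hi <- findHinges(md, modeIndices = c(1, 2), combine = "intersection")
  expect_true(all(unique(hi$node) %in% unique(hu$node)))
  expect_true(all(c(1, 2) %in% hu$mode))
})

test_that("degenerate and hinge-free mode vectors are handled", {
  # all elements same sign, none near zero: empty hinge set
  v <- cbind(rep(1, 4) / 2, c(0.7, 0.5, 0.4, 0.32) /
               sqrt(sum(c(0.7, 0.5, 0.4, 0.32)^2)))
  fake <- syntheticModes(v, c(0, 1))
  h <- findHinges(fake, modeIndices = 1)
  expect_equal(nrow(h), 0L)
  # all-zero mode vector errors
  zero <- syntheticModes(cbind(rep(0.5, 4), rep(0, 4)), c(0, 1))
  expect_error(findHinges(zero, modeIndices = 1), "degenerate")
})

test_that("the per-residue report combines shapes, fluctuations and hinges", {
  db <- makeDumbbell(seed = 7)
  m <- gnmModes(buildKirchhoff(db$structure))
  rep <- gnmReport(m)
  expect_equal(nrow(rep), length(residueIds(m)))
  expect_true(all(c("residue_id", "mode1_amplitude", "mode2_amplitude",
                    "sq_fluct", "hinge_flag", "hinge_rule") %in% names(rep)))
  expect_true(all(rep$sq_fluct > 0))
  expect_true(any(rep$hinge_flag))
  expect_true(all(nzchar(rep$hinge_rule[rep$hinge_flag])))
})
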