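test_that("COM distances are exact on single-atom residues and isometric", {
  g <- makeGateTrajectory(nFrames = 10, openSd = 0, closedSd = 0,
                          openMean = 5, switchFrame = 10, seed = 1)
  # place second atom at (3,4,0): 3-4-5 triangle
  tr <- g$trajectory
  tr@frames[2, , ] <- c(3, 4, 0)
  d <- comDistance(tr, "A:1", "A:2", atomScope = "all")
  expect_equal(seriesValues(d), rep(5, 10))

  # frame-wise rigid transform leaves distances unchanged
  R <- randomRotation(3)
  tr2 <- transformTrajectory(tr, R, c(12, -3, 7))
  expect_equal(seriesValues(comDistance(tr2, "A:1", "A:2",
                                        atomScope = "all")),
               seriesValues(d), tolerance = 1e-9)
})

test_that("COM uses true mass weighting (brute-force oracle)", {
  s <- gatemech:::newStructure(
    elety = c("CA", "CB", "OG", "CA", "CB", "SG"),
    element = c("C", "C", "O", "C", "C", "S"),
    chain = rep("A", 6), resno = c(1, 1, 1, 2, 2, 2),
    insert = rep("", 6), resid = c("SER", "SER", "SER",
                                   "CYS", "CYS", "CYS"),
    occupancy = rep(1, 6),
    coords = rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0),
                   c(8, 0, 0), c(9, 0, 0), c(9, 2, 0)))
  tr <- new("CoordTrajectory", topology = s,
            frames = array(s@coords, c(6, 3, 1)), dt = NA_real_)
  d <- comDistance(tr, "A:1", "A:2", atomScope = "heavy")
  # independent brute force: sum(m_i r_i) / sum(m_i)
  m <- atomTable(s)$mass
  comA <- colSums(s@coords[1:3, ] * m[1:3]) / sum(m[1:3])
  comB <- colSums(s@coords[4:6, ] * m[4:6]) / sum(m[4:6])
  expect_equal(seriesValues(d), sqrt(sum((comA - comB)^2)),
               tolerance = 1e-12)

  # sidechain scope drops the backbone CA
  ds <- comDistance(tr, "A:1", "A:2", atomScope = "sidechain")
  comAs <- colSums(s@coords[2:3, ] * m[2:3]) / sum(m[2:3])
  comBs <- colSums(s@coords[5:6, ] * m[5:6]) / sum(m[5:6])
  expect_equal(seriesValues(ds), sqrt(sum((comAs - comBs)^2)),
               tolerance = 1e-12)
})

test_that("sidechain scope on glycine errors with the residue named", {
  g <- makeGateTrajectory(nFrames = 3, seed = 1)   # GLY pseudo-residues
  expect_error(comDistance(g$trajectory, "A:1", "A:2"), "A:1")
})

test_that("chi1 hits planar limits, prescribed rotations, and chirality", {
  expect_equal(seriesValues(chi1Series(rotamerAt(0)$trajectory, "A:155")),
               0, tolerance = 1e-9)
  expect_equal(seriesValues(chi1Series(rotamerAt(180)$trajectory, "A:155")),
               180, tolerance = 1e-9)
  expect_equal(seriesValues(chi1Series(rotamerAt(60)$trajectory, "A:155")),
               60, tolerance = 1e-9)
  expect_equal(seriesValues(chi1Series(rotamerAt(-100)$trajectory, "A:155")),
               -100, tolerance = 1e-9)

  # proper rigid transform: unchanged; reflection: sign flips
  tr <- rotamerAt(60, nFrames = 3)$trajectory
  tr2 <- transformTrajectory(tr, randomRotation(5), c(3, 4, 5))
  expect_equal(seriesValues(chi1Series(tr2, "A:155")), rep(60, 3),
               tolerance = 1e-6)
  mir <- tr
  mir@frames[, 1, ] <- -mir@frames[, 1, ]
  expect_equal(seriesValues(chi1Series(mir, "A:155")), rep(-60, 3),
               tolerance = 1e-6)
})

test_that("chi1 validates residue type and required atoms", {
  g <- makeGateTrajectory(nFrames = 2, seed = 1)   # GLY: no chi1
  expect_error(chi1Series(g$trajectory, "A:1"), "GLY")
  rot <- rotamerAt(60)$trajectory
  topo <- rot@topology
  topo@atoms$elety[4] <- "CD"   # break the gamma atom
  broken <- new("CoordTrajectory", topology = topo, frames = rot@frames,
                dt = rot@dt)
  expect_error(chi1Series(broken, "A:155"), "CG")
})

test_that("rotamer classification uses the circular state intervals", {
  cl <- classifyRotamer(c(170, 60, 120, -175, 85))
  expect_equal(cl$labels, c("IF-like", "OF-like", "unassigned",
                            "IF-like", "unassigned"))
  # -175 is 15 degrees from +170 circularly: inside the IF interval
  expect_equal(sum(cl$occupancy), 1)
  expect_error(classifyRotamer(
    c(0), states = data.frame(label = c("a", "b"), center = c(0, 20),
                              halfwidth = c(15, 15))), "overlap")
})

test_that("pooled histograms are additive, conservative and order-free", {
  runs <- lapply(1:3, function(i)
    comDistance(makeGateTrajectory(nFrames = 100, seed = i,
                                   switchFrame = 50)$trajectory,
                "A:1", "A:2", atomScope = "all", runId = paste0("r", i)))
  ph <- pooledHistogram(runs)
  expect_equal(sum(ph@pooled), 300)
  expect_equal(rowSums(ph@counts), ph@pooled)

  # pooling equals histogram of the concatenation, bin-wise
  concat <- new("FrameSeries",
                values = unlist(lapply(runs, seriesValues)),
                observable = "com_distance", unit = "angstrom",
                runId = "all", dt = 0.5, meta = list())
  ph1 <- pooledHistogram(list(concat), breaks = ph@breaks)
  expect_equal(unname(ph1@pooled), unname(ph@pooled))

  # permutation invariance of the source list
  ph2 <- pooledHistogram(runs[c(3, 1, 2)], breaks = ph@breaks)
  expect_equal(ph2@pooled, ph@pooled)

  # bimodal two-state fixture: argmax bins contain the two state means
  mids <- (ph@breaks[-1] + ph@breaks[-length(ph@breaks)]) / 2
  top2 <- order(ph@pooled, decreasing = TRUE)[1:2]
  expect_true(any(abs(mids[top2] - 5) <= 0.25))
  expect_true(any(abs(mids[top2] - 9) <= 0.25))

  expect_error(pooledHistogram(list()), "empty")
  tab <- histogramTable(ph, cumulative = TRUE)
  expect_equal(tab$pooled[nrow(tab)], 1)
})

test_that("gate closure time finds the first sustained crossing", {
  mk <- function(vals, dt = 0.5) new("FrameSeries", values = vals,
    observable = "com_distance", unit = "angstrom", runId = "r",
    dt = dt, meta = list())
  expect_equal(gateClosureTime(mk(rep(2, 20)), 5), 0)          # closed at t=0
  expect_true(is.na(gateClosureTime(mk(rep(9, 20)), 5)))       # never closes
  # single-frame dip suppressed by the dwell requirement
  dip <- rep(9, 20); dip[8] <- 2
  expect_true(is.na(gateClosureTime(mk(dip), 5, dwellFrames = 5)))
  expect_equal(gateClosureTime(mk(dip), 5, dwellFrames = 1), 7 * 0.5)
  expect_error(gateClosureTime(mk(rep(2, 5)), -1), "> 0")
  expect_error(gateClosureTime(mk(rep(2, 5), dt = NA_real_), 5), "dt")

  # noiseless generator switch: closure exactly at switchFrame * dt
  g <- makeGateTrajectory(nFrames = 60, dt = 0.5, switchFrame = 25,
                          openSd = 0, closedSd = 0, seed = 3)
  d <- comDistance(g$trajectory, "A:1", "A:2", atomScope = "all")
  expect_equal(gateClosureTime(d, closedThreshold = 7), 25 * 0.5)
})

test_that("RMSD is zero on identity and rigid copies, exact on the 4-atom fixture", {
  db <- makeDumbbell(seed = 9)$structure
  frames <- array(db@coords, c(nAtoms(db), 3, 2))
  tr <- new("CoordTrajectory", topology = db, frames = frames, dt = 1)
  expect_equal(seriesValues(rmsdSeries(tr)), c(0, 0), tolerance = 1e-10)

  # rigidly transformed copy superposes back to zero
  tr2 <- transformTrajectory(tr, randomRotation(2), c(5, -8, 2))
  expect_lt(max(seriesValues(rmsdSeries(tr2, reference = db,
                                        superpose = TRUE))), 1e-8)
  expect_gt(min(seriesValues(rmsdSeries(tr2, reference = db,
                                        superpose = FALSE))), 1)

  # 4 atoms, one displaced by 2 A, no fitting: sqrt(4/4) = 1
  ref <- makePathStructure(4, spacing = 10)
  fr <- array(ref@coords, c(4, 3, 1))
  fr[1, 2, 1] <- fr[1, 2, 1] + 2
  tr3 <- new("CoordTrajectory", topology = ref, frames = fr, dt = NA_real_)
  expect_equal(seriesValues(rmsdSeries(tr3, reference = ref,
                                       superpose = FALSE)), 1)

  expect_error(rmsdSeries(tr3, reference = makePathStructure(3)),
               "atom count")
})

test_that("plateau detection finds flat tails and rejects ramps", {
  mk <- function(vals) new("FrameSeries", values = vals,
    observable = "rmsd", unit = "angstrom", runId = "r", dt = 1,
    meta = list())
  const <- plateauCheck(mk(rep(2, 50)), window = 10)
  expect_true(const$plateau_reached)
  expect_equal(const$plateau_start, 0)
  expect_equal(const$plateau_mean, 2)

  # ramp to frame 30 then flat: plateau within one window of the breakpoint
  ramp <- c(seq(0, 2, length.out = 30), rep(2, 40))
  pr <- plateauCheck(mk(ramp), window = 10, slopeTol = 0.005)
  expect_true(pr$plateau_reached)
  expect_lte(abs(pr$plateau_start - 30), 10)
  # the earliest flat window may start just inside the ramp tail
  expect_equal(pr$plateau_mean, 2, tolerance = 1e-2)

  up <- plateauCheck(mk(seq(0, 5, length.out = 60)), window = 10,
                     slopeTol = 0.005)
  expect_false(up$plateau_reached)
  expect_error(plateauCheck(mk(rep(1, 5)), window = 10), "longer")
})

test_that("observables carry provenance for pooling and TSV export", {
  g <- makeGateTrajectory(nFrames = 20, seed = 4, runId = "ofr2")
  d <- comDistance(g$trajectory, "A:1", "A:2", atomScope = "all",
                   runId = "ofr2")
  expect_equal(d@runId, "ofr2")
  path <- tempfile(fileext = ".tsv")
  writeSeriesTSV(d, path, labels = g$state)
  tab <- read.delim(path)
  expect_equal(nrow(tab), 20)
  expect_equal(tab$value, seriesValues(d), tolerance = 1e-9)
  expect_equal(tab$label, g$state)
})
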