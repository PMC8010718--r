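monoIC <- makeMembraneMonomer(seed = 1)

test_that("the symmetry axis is the centroid-plane normal, membrane-oriented", {
  tm <- makeC3Trimer(monoIC)
  ax <- symmetryAxis(tm)
  expect_equal(abs(sum(ax$axis * c(0, 0, 1))), 1, tolerance = 1e-8)
  expect_gt(sum(ax$axis * c(0, 0, 1)), 0)   # aligned with membrane normal

  # equivariance: rotating the whole trimer rotates the axis
  R <- randomRotation(7)
  tm2 <- tm
  tm2@monomers <- lapply(tm@monomers, function(m) {
    m@coords <- m@coords %*% t(R); m })
  tm2@membrane <- membraneFrame(normal = as.vector(R %*% c(0, 0, 1)))
  ax2 <- symmetryAxis(tm2)
  expect_equal(ax2$axis, as.vector(R %*% ax$axis), tolerance = 1e-8)
  expect_equal(ax2$center, as.vector(R %*% ax$center), tolerance = 1e-8)

  # collinear centroids are degenerate
  shift <- function(s, dx) { s@coords <- sweep(s@coords, 2, -c(dx, 0, 0)); s }
  bad <- new("TrimerModel",
             monomers = list(monoIC, shift(monoIC, 30), shift(monoIC, 60)),
             membrane = membraneFrame(), clusterId = "x", clusterSize = 1L)
  expect_error(symmetryAxis(bad), "collinear")
})

test_that("the C3 score is zero for exact trimers and rigid-invariant", {
  tm <- makeC3Trimer(monoIC, perturbSd = 0)
  expect_lt(c3Score(tm), 1e-8)

  R <- randomRotation(11)
  tm2 <- tm
  tm2@monomers <- lapply(tm@monomers, function(m) {
    m@coords <- sweep(m@coords %*% t(R), 2, -c(4, -2, 9)); m })
  tm2@membrane <- membraneFrame(normal = as.vector(R %*% c(0, 0, 1)))
  expect_lt(abs(c3Score(tm2) - c3Score(tm)), 1e-8)
})

test_that("the C3 score grows with the symmetry-breaking perturbation", {
  meanScore <- function(sd) mean(vapply(1:8, function(s)
    c3Score(makeC3Trimer(monoIC, perturbSd = sd, seed = s)), numeric(1)))
  s05 <- meanScore(0.5); s1 <- meanScore(1); s2 <- meanScore(2)
  expect_lt(s05, s1)
  expect_lt(s1, s2)
})

test_that("termini exposure is judged against the membrane slab", {
  pass <- terminiCheck(makeC3Trimer(monoIC))
  expect_true(attr(pass, "pass"))
  expect_true(all(pass$n_pass & pass$c_pass))

  ec <- terminiCheck(makeC3Trimer(
    makeMembraneMonomer(terminiSide = "EC", seed = 2)))
  expect_false(attr(ec, "pass"))

  # termini inside the slab are not exposed
  flat <- monoIC
  flat@coords[, 3] <- 0
  inside <- terminiCheck(makeC3Trimer(flat))
  expect_false(attr(inside, "pass"))

  expect_error(terminiCheck(makeC3Trimer(monoIC), nSpan = 30, cSpan = 30),
               "overlap")
})

test_that("tryptophan anchoring counts interfacial sidechain centroids", {
  good <- trpAnchorScore(makeC3Trimer(monoIC))
  expect_gt(good$nTrp, 0)
  expect_equal(good$fraction, 1)
  expect_true(good$pass)

  core <- trpAnchorScore(makeC3Trimer(
    makeMembraneMonomer(trpAtInterface = FALSE, seed = 3)))
  expect_equal(core$fraction, 0)
  expect_false(core$pass)

  # half interfacial / half core -> 0.5
  mono <- makeMembraneMonomer(seed = 4)
  a <- atomTable(mono)
  trp <- which(a$resid == "TRP")
  mono@coords[trp[1:2], 3] <- 0   # drag two of four Trp to the core
  half <- trpAnchorScore(makeC3Trimer(mono))
  expect_equal(half$fraction, 0.5)

  # no tryptophan: criterion not applicable
  noTrp <- mono
  noTrp@atoms$resid[trp] <- "ALA"
  na <- trpAnchorScore(makeC3Trimer(noTrp))
  expect_true(is.na(na$pass))
  expect_equal(na$nTrp, 0L)
})

test_that("models are ranked by cluster size with deterministic tie-breaks", {
  mk <- function(id, size) makeC3Trimer(monoIC, clusterId = id,
                                        clusterSize = size)
  res <- rankAndFilter(list(mk("c3", 40), mk("c1", 120), mk("c2", 120)),
                       criteria = character(0))
  expect_equal(res$report$cluster_id, c("c1", "c2", "c3"))
  expect_true(all(res$report$pass))          # empty criteria: identity filter
  expect_equal(length(res$survivors), 3L)
  # determinism: identical inputs, identical order
  res2 <- rankAndFilter(list(mk("c3", 40), mk("c1", 120), mk("c2", 120)),
                        criteria = character(0))
  expect_identical(res$report, res2$report)
})

test_that("the three-model synthetic set yields one survivor with reasons", {
  ts <- makeTrimerTestSet(seed = 1)
  res <- rankAndFilter(ts$models)
  expect_equal(length(res$survivors), 1L)
  expect_equal(res$survivors[[1]]@clusterId, "c1")
  rep <- res$report
  expect_equal(rep$cluster_id, c("c1", "c2", "c3"))  # size desc, id tie-break
  expect_true(rep$pass[rep$cluster_id == "c1"])
  expect_match(rep$reason[rep$cluster_id == "c2"], "termini")
  expect_match(rep$reason[rep$cluster_id == "c3"], "collinear")
})

test_that("mismatched monomer rosters are rejected at construction", {
  other <- makeMembraneMonomer(nRes = 30, seed = 5)
  expect_error(new("TrimerModel",
                   monomers = list(monoIC, monoIC, other),
                   membrane = membraneFrame(), clusterId = "x",
                   clusterSize = 1L),
               "roster")
  expect_error(rankAndFilter(list()), "no models")
})
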