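test_that("circularity scores discs high, lines low, squares near pi/4", {
  d <- outer((-25:25) + 0, (-25:25) + 0,
             function(a, b) a^2 + b^2) <= 20^2
  expect_gte(circularity(d), 0.85)
  ln <- matrix(FALSE, 5, 44); ln[3, 3:42] <- TRUE
  expect_lt(circularity(ln), 0.3)
  sq <- matrix(FALSE, 30, 30); sq[6:25, 6:25] <- TRUE
  expect_lt(abs(circularity(sq) - pi / 4), 0.1)
  expect_error(circularity(matrix(FALSE, 3, 3)), "empty")
  expect_lte(circularity(d), 1)
})

test_that("screening returns nothing for an empty mask", {
  expect_identical(screenCandidates(array(FALSE, c(8, 8, 8))), list())
})

test_that("a phantom 8 mm sphere yields exactly one retained candidate", {
  ph <- generatePhantom(phantomSpec(shape = c(32, 48, 48), noiseSigma = 0,
                                    seed = 3,
                                    nodules = list(noduleSpec(8))))
  cands <- screenCandidates(ph$noduleMask, c(1, 1, 1))
  expect_length(cands, 1)
  expect_true(cands[[1]]@retained)
  expect_lt(abs(cands[[1]]@equivDiameterMm - 8), 1)
})

test_that("an elongated cylinder is rejected by the multiposition rule", {
  g <- analyticCylSphere()
  cands <- screenCandidates(g$cyl | g$sph, c(1, 1, 1), returnAll = TRUE)
  expect_length(cands, 2)
  byVol <- order(vapply(cands, function(x) nrow(x@voxelIndex), numeric(1)))
  sphere <- cands[[byVol[1]]]; cyl <- cands[[byVol[2]]]
  expect_true(sphere@retained)
  expect_false(cyl@retained)
  # the cylinder passes circularity axially but fails in the other positions
  expect_gte(cyl@circularity[["axial"]], 0.6)
  expect_lt(cyl@circularity[["coronal"]], 0.6)
  expect_lt(cyl@circularity[["sagittal"]], 0.6)
})

test_that("raising the circularity threshold never adds candidates", {
  set.seed(30)
  m <- array(runif(20 * 24 * 24) > 0.93, c(20, 24, 24))
  ids <- function(minCirc) {
    vapply(screenCandidates(m, c(1, 1, 1), minCirc = minCirc,
                            diamRangeMm = c(0.5, 50)),
           function(x) x@id, integer(1))
  }
  prev <- ids(0)
  for (thr in c(0.2, 0.4, 0.6, 0.8, 1.0)) {
    cur <- ids(thr)
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("candidate components are 26-connected and nonempty", {
  ph <- nodulePhantom(44, shape = c(32L, 48L, 48L), spiculated = TRUE)
  cands <- screenCandidates(ph$noduleMask, c(1, 1, 1), returnAll = TRUE)
  expect_length(cands, 1)  # spikes stay attached to their sphere
  expect_gt(nrow(cands[[1]]@voxelIndex), 0)
})

test_that("segmentNodules enforces aligned inputs and complete networks", {
  ph <- generatePhantom(phantomSpec(shape = c(8, 8, 8), seed = 1))
  set.seed(31)
  tiny <- buildNoduleNet(levels = 3, baseChannels = 1, pyramidWidth = 1)
  nets <- list(axial = tiny, coronal = tiny, sagittal = tiny)
  expect_error(segmentNodules(ph$volume, array(TRUE, c(4, 4, 4)), nets),
               "aligned")
  expect_error(
    segmentNodules(ph$volume, ph$parenchyma,
                   list(axial = tiny, coronal = tiny)),
    "missing network for position: sagittal")
})

test_that("an empty parenchyma mask gives an empty nodule mask", {
  ph <- generatePhantom(phantomSpec(shape = c(8, 8, 8), seed = 1))
  set.seed(32)
  tiny <- buildNoduleNet(levels = 3, baseChannels = 1, pyramidWidth = 1)
  nets <- list(axial = tiny, coronal = tiny, sagittal = tiny)
  res <- segmentNodules(ph$volume, array(FALSE, dim(ph$volume)), nets)
  expect_equal(sum(res$mask), 0)
  expect_length(res$candidates, 0)
})

test_that("segmentation is deterministic for fixed networks and volume", {
  ph <- generatePhantom(phantomSpec(shape = c(16, 16, 16), seed = 2,
                                    nodules = list(noduleSpec(6))))
  set.seed(33)
  tiny <- buildNoduleNet(levels = 3, baseChannels = 1, pyramidWidth = 1)
  nets <- list(axial = tiny, coronal = tiny, sagittal = tiny)
  r1 <- segmentNodules(ph$volume, ph$parenchyma, nets)
  r2 <- segmentNodules(ph$volume, ph$parenchyma, nets)
  expect_identical(r1$mask, r2$mask)
})
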