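test_that("phantom with no nodules has an empty nodule mask", {
  ph <- generatePhantom(phantomSpec(shape = c(16, 24, 24), noiseSigma = 0,
                                    seed = 1))
  expect_equal(sum(ph$noduleMask), 0)
  expect_gt(sum(ph$parenchyma), 0)
})

test_that("an isolated 8 mm sphere voxelizes to the analytic volume", {
  ph <- generatePhantom(phantomSpec(shape = c(32, 48, 48), noiseSigma = 0,
                                    seed = 3,
                                    nodules = list(noduleSpec(8))))
  analytic <- 4 / 3 * pi * 4^3            # ~268 voxels at 1 mm iso
  expect_lt(abs(sum(ph$noduleMask) - analytic) / analytic, 0.10)
})

test_that("identical seeds give bit-identical phantoms", {
  spec <- phantomSpec(shape = c(16, 24, 24), seed = 9,
                      nodules = list(noduleSpec(6)))
  a <- generatePhantom(spec)
  b <- generatePhantom(spec)
  expect_identical(a$volume@voxels, b$volume@voxels)
  expect_identical(a$noduleMask, b$noduleMask)
  expect_identical(a$parenchyma, b$parenchyma)
})

test_that("isolated nodules lie entirely inside the parenchyma", {
  for (seed in 1:5) {
    ph <- nodulePhantom(seed, shape = c(32L, 48L, 48L))
    expect_true(all(ph$parenchyma[ph$noduleMask]))
  }
})

test_that("lung-field mean intensity matches the configured HU level", {
  spec <- phantomSpec(shape = c(32, 48, 48), noiseSigma = 15, seed = 4)
  ph <- generatePhantom(spec)
  hu <- ph$volume@voxels[ph$parenchyma]
  tol <- 3 * spec@noiseSigma / sqrt(length(hu)) + 0.5  # +0.5: integer rounding
  expect_lt(abs(mean(hu) - spec@lungHu), tol)
})

test_that("a nodule centred outside the lung fields is rejected by name", {
  spec <- phantomSpec(shape = c(32, 48, 48), seed = 1,
                      nodules = list(noduleSpec(6, center = c(2, 2, 2))))
  expect_error(generatePhantom(spec), "nodule 1")
})

test_that("invalid phantom specs fail validity checks", {
  expect_error(phantomSpec(shape = c(0, 8, 8)), "shape")
  expect_error(phantomSpec(bodyHu = -900, lungHu = -800), "darker")
  expect_error(noduleSpec(diameterMm = -1), "diameterMm")
  expect_error(noduleSpec(6, spiculated = FALSE, spikeCount = 3),
               "spikeCount")
})

test_that("spiculation is an identity for zero spikes and a superset otherwise", {
  ph <- generatePhantom(phantomSpec(shape = c(32, 48, 48), noiseSigma = 0,
                                    seed = 3,
                                    nodules = list(noduleSpec(8))))
  m <- ph$noduleMasks[[1]]
  expect_identical(spiculateBoundary(m, 0L, 3), m)
  sp <- spiculateBoundary(m, 8L, 3, seed = 5)
  expect_true(all(sp[m]))
  expect_gt(sum(sp), sum(m))
  expect_error(spiculateBoundary(array(FALSE, c(4, 4, 4)), 4L, 3), "empty")
})

test_that("spiculation lowers the max-area-slice circularity", {
  ph <- generatePhantom(phantomSpec(shape = c(32, 48, 48), noiseSigma = 0,
                                    seed = 3,
                                    nodules = list(noduleSpec(8))))
  m <- ph$noduleMasks[[1]]
  sp <- spiculateBoundary(m, 8L, 3, seed = 5)
  maxSlice <- function(mask) {
    k <- which.max(apply(mask, 1, sum))
    mask[k, , ]
  }
  expect_lt(circularity(maxSlice(sp)), circularity(maxSlice(m)))
})

test_that("wall-adherent nodules touch the lung-field boundary", {
  ph <- nodulePhantom(17, shape = c(32L, 48L, 48L), attachment = "wall")
  nd <- ph$noduleMask
  expect_gt(sum(nd), 0)
  expect_true(any(nd & ph$parenchyma))   # part inside the lung field
  expect_true(any(nd & !ph$parenchyma))  # part embedded in the wall
})

test_that("phantoms round-trip to disk with masks aligned voxel-for-voxel", {
  ph <- generatePhantom(phantomSpec(shape = c(12, 16, 16), seed = 2,
                                    nodules = list(noduleSpec(6))))
  dir <- withr::local_tempdir()
  writePhantom(ph, dir)
  v <- readVolume(file.path(dir, "volume.nii.gz"))
  expect_true(all(v@voxels == ph$volume@voxels))
  m <- readMask(file.path(dir, "nodules.nii.gz"))
  expect_identical(unname(m > 0), unname(ph$noduleMask))
  lab <- jsonlite::read_json(file.path(dir, "labels.json"),
                             simplifyVector = TRUE)
  expect_equal(nrow(lab), 1)
  expect_equal(lab$diameterMm, 6)
})
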