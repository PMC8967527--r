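test_that("a uniform-intensity sphere has zero variance and entropy", {
  ph <- generatePhantom(phantomSpec(shape = c(32, 48, 48), noiseSigma = 0,
                                    seed = 3,
                                    nodules = list(noduleSpec(8))))
  cand <- screenCandidates(ph$noduleMask, c(1, 1, 1))[[1]]
  fv <- extractFeatures(ph$volume, cand)
  expect_equal(fv[["fo_var"]], 0)
  expect_equal(fv[["fo_entropy"]], 0)
  expect_equal(fv[["fo_mean"]], 20)          # the nodule HU level
  expect_false(anyNA(fv))
  expect_gte(fv[["fo_entropy"]], 0)
  expect_true(fv[["sphericity"]] > 0 && fv[["sphericity"]] <= 1)
})

test_that("an analytic sphere is near-spherical despite discretization", {
  ph <- generatePhantom(phantomSpec(shape = c(32, 48, 48), noiseSigma = 0,
                                    seed = 3,
                                    nodules = list(noduleSpec(8))))
  cand <- screenCandidates(ph$noduleMask, c(1, 1, 1))[[1]]
  fv <- extractFeatures(ph$volume, cand)
  expect_gte(fv[["sphericity"]], 0.9)
  expect_lt(abs(fv[["equiv_diam_mm"]] - 8), 0.5)
})

test_that("a spiculated nodule is less spherical with more radial variance", {
  smooth <- nodulePhantom(61, shape = c(32L, 48L, 48L), noiseSigma = 0)
  spic <- nodulePhantom(61, shape = c(32L, 48L, 48L), noiseSigma = 0,
                        spiculated = TRUE)
  fS <- extractFeatures(smooth$volume,
                        screenCandidates(smooth$noduleMask, c(1, 1, 1),
                                         returnAll = TRUE)[[1]])
  fP <- extractFeatures(spic$volume,
                        screenCandidates(spic$noduleMask, c(1, 1, 1),
                                         returnAll = TRUE)[[1]])
  expect_lt(fP[["sphericity"]], fS[["sphericity"]])
  expect_gt(fP[["radvar_axial"]] + fP[["radvar_coronal"]] +
              fP[["radvar_sagittal"]],
            fS[["radvar_axial"]] + fS[["radvar_coronal"]] +
              fS[["radvar_sagittal"]])
})

test_that("features are invariant to translating the candidate", {
  ph <- generatePhantom(phantomSpec(shape = c(32, 48, 48), noiseSigma = 0,
                                    seed = 3,
                                    nodules = list(noduleSpec(8))))
  cand <- screenCandidates(ph$noduleMask, c(1, 1, 1))[[1]]
  f1 <- extractFeatures(ph$volume, cand)
  # shift mask and intensities by the same offset
  sh <- c(3L, -4L, 5L)
  vox2 <- sweep(cand@voxelIndex, 2, sh, `+`)
  vol2 <- array(ph$volume@voxels[1], dim(ph$volume@voxels))
  vol2[vox2] <- ph$volume@voxels[cand@voxelIndex]
  cand2 <- new("NoduleCandidate", id = 1L, voxelIndex = vox2,
               centroid = colMeans(vox2),
               equivDiameterMm = cand@equivDiameterMm,
               circularity = cand@circularity, retained = TRUE,
               features = numeric(0))
  f2 <- extractFeatures(CTVolume(vol2, ph$volume@spacing), cand2)
  expect_equal(f1, f2, tolerance = 1e-12)
})

test_that("single-voxel candidates are rejected", {
  ph <- generatePhantom(phantomSpec(shape = c(8, 8, 8), seed = 1))
  cand <- new("NoduleCandidate", id = 1L,
              voxelIndex = matrix(c(4L, 4L, 4L), 1, 3),
              centroid = c(4, 4, 4), equivDiameterMm = 1,
              circularity = c(axial = 1, coronal = 1, sagittal = 1),
              retained = TRUE, features = numeric(0))
  expect_error(extractFeatures(ph$volume, cand), "single-voxel")
})

test_that("screening keeps overwhelming effects and drops null ones", {
  set.seed(40)
  y <- rep(c(0, 1), each = 20)
  X <- data.frame(
    same = rnorm(40),                       # no effect
    huge = rnorm(40) + 10 * y,              # 10 pooled SDs apart
    flat = rep(1, 40)                       # constant
  )
  expect_warning(keep <- screenFeatures(X, y), "constant")
  expect_true("huge" %in% keep)
  expect_false("same" %in% keep)
  expect_false("flat" %in% keep)
  # identical distribution in both classes is never retained
  X2 <- data.frame(id = rep(c(1, 2), 20))
  expect_false("id" %in% screenFeatures(X2, y))
})

test_that("screening respects its type-I error rate on null features", {
  set.seed(41)
  y <- rep(c(0, 1), each = 20)
  X <- as.data.frame(matrix(rnorm(40 * 1000), 40, 1000))
  keep <- screenFeatures(X, y, alpha = 0.05)
  rate <- length(keep) / 1000
  expect_lt(abs(rate - 0.05), 0.015)
})

test_that("screening retention is monotone in alpha", {
  set.seed(42)
  y <- rep(c(0, 1), each = 15)
  X <- as.data.frame(matrix(rnorm(30 * 50), 30, 50))
  X$inf1 <- rnorm(30) + 1.5 * y
  prev <- character(0)
  for (a in c(0.001, 0.01, 0.05, 0.2, 0.5)) {
    cur <- screenFeatures(X, y, alpha = a)
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("chi-square screening retains an associated categorical feature", {
  set.seed(43)
  y <- rep(c(0, 1), each = 30)
  X <- data.frame(cat = factor(ifelse(y == 1,
                                      sample(c("a", "b"), 60, TRUE, c(.9, .1)),
                                      sample(c("a", "b"), 60, TRUE, c(.1, .9)))))
  expect_true("cat" %in% screenFeatures(X, y))
})

test_that("perfectly separable data cross-validates at 100/100", {
  set.seed(44)
  n <- 40
  y <- rep(c(0, 1), each = n / 2)
  X <- data.frame(fo_mean = rnorm(n) + 8 * y,
                  fo_var = rnorm(n),
                  c2d_axial = rnorm(n) - 8 * y,
                  radvar_axial = rnorm(n))
  m <- fitSignModel(X, y, folds = 5, seed = 3)
  expect_equal(unname(m$cvPooled[c("SEN", "SPE")]), c(100, 100))
})

test_that("the sign model refuses to fit when nothing survives screening", {
  set.seed(45)
  y <- rep(c(0, 1), each = 10)
  X <- data.frame(fo_mean = rep(1, 20), c2d_axial = rep(2, 20))
  expect_error(suppressWarnings(fitSignModel(X, y, folds = 5, seed = 1)),
               "relax alpha")
})

test_that("sign-model fits are reproducible under a fixed seed", {
  d <- deskSignData()
  m1 <- fitSignModel(d$X, d$y, folds = 10, seed = 7)
  m2 <- fitSignModel(d$X, d$y, folds = 10, seed = 7)
  expect_identical(m1$cvScores, m2$cvScores)
  expect_identical(m1$selected, m2$selected)
})

test_that("selection recovers informative features among noise", {
  set.seed(46)
  hit <- 0
  reps <- 8
  for (r in 1:reps) {
    n <- 200
    X <- matrix(rnorm(n * 20), n, 20)
    colnames(X) <- paste0("fo_f", 1:20)     # all routed to one submodel
    eta <- 1.5 * X[, 1] - 1.5 * X[, 2] + 1.5 * X[, 3]
    y <- rbinom(n, 1, plogis(eta))
    m <- fitSignModel(as.data.frame(X), y, folds = 5, seed = r)
    if (all(paste0("fo_f", 1:3) %in% m$radiomics$features)) hit <- hit + 1
  }
  expect_gte(hit / reps, 0.8)
})

test_that("the OR rule fuses per-position sign decisions monotonically", {
  expect_false(fuseSignDecisions(c(FALSE, FALSE, FALSE)))
  expect_true(fuseSignDecisions(c(TRUE, FALSE, FALSE)))
  expect_true(fuseSignDecisions(c(TRUE, TRUE, TRUE)))
  expect_error(fuseSignDecisions(c(TRUE, FALSE)), "three")
  # monotone: flipping any position to TRUE never flips the output to FALSE
  for (i in 1:3) {
    base <- c(FALSE, FALSE, FALSE)
    up <- base; up[i] <- TRUE
    expect_gte(fuseSignDecisions(up), fuseSignDecisions(base))
  }
})
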