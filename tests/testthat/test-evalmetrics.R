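test_that("identical masks score perfect overlap for random masks", {
  set.seed(20)
  for (rep in 1:20) {
    m <- array(runif(60) > 0.5, c(3, 4, 5))
    if (!any(m)) m[1] <- TRUE
    sc <- segScores(m, m)
    expect_equal(unname(sc), c(100, 0, 0, 100))
  }
})

test_that("seg scores match the set-cardinality hand example", {
  Eg <- array(FALSE, c(1, 20, 10))
  Es <- array(FALSE, c(1, 20, 10))
  Eg[1, 1:10, 1:10] <- TRUE                  # |Eg| = 100
  Es[1, 1:7, 1:10] <- TRUE                   # 70 overlapping
  Es[1, 11, 1:10] <- TRUE                    # 10 outside -> |Es| = 80
  sc <- segScores(Eg, Es)
  expect_equal(sc[["Md"]], 70 / 110 * 100, tolerance = 0.01)
  expect_equal(sc[["Vd"]], 50.0, tolerance = 0.01)
  expect_equal(sc[["Ud"]], 40.0, tolerance = 0.01)
  expect_equal(sc[["CM"]], (63.6364 + 50 + 60) / 3, tolerance = 0.01)
})

test_that("disjoint equal-size masks push Vd/Ud beyond 100 as the formulas force", {
  Eg <- array(FALSE, c(1, 4, 4)); Es <- Eg
  Eg[1, 1:2, ] <- TRUE
  Es[1, 3:4, ] <- TRUE
  sc <- segScores(Eg, Es)
  expect_equal(unname(sc), c(0, 200, 200, (0 - 100 - 100) / 3))
})

test_that("seg scores obey the swap symmetries", {
  set.seed(21)
  for (rep in 1:10) {
    a <- array(runif(60) > 0.4, c(3, 4, 5)); if (!any(a)) a[1] <- TRUE
    b <- array(runif(60) > 0.4, c(3, 4, 5)); if (!any(b)) b[2] <- TRUE
    s1 <- segScores(a, b); s2 <- segScores(b, a)
    expect_equal(s1[["Md"]], s2[["Md"]])
    expect_equal(s1[["Vd"]], s2[["Ud"]])
    expect_equal(s1[["Ud"]], s2[["Vd"]])
  }
})

test_that("empty masks raise the documented errors", {
  full <- array(TRUE, c(2, 2, 2)); none <- array(FALSE, c(2, 2, 2))
  expect_error(segScores(none, full), "ground-truth")
  expect_error(segScores(full, none), "Vd")
  expect_error(segScores(full, array(TRUE, c(2, 2, 1))), "shape")
})

test_that("dice loss matches hand evaluation and its limits", {
  expect_equal(diceLoss(c(0.8, 0.2), c(1, 0)), 1 - 1.6 / (0.68 + 1 + 1),
               tolerance = 1e-12)
  g <- rep(1, 5000)
  expect_lte(diceLoss(g, g), 1 / sum(g))     # perfect, bounded by eps/sum
  expect_gt(diceLoss(c(1, 0), c(0, 1)), 0.99 * 1)  # disjoint supports
  expect_error(diceLoss(matrix(0.5, 2, 2), matrix(1, 2, 3)), "shape")
})

test_that("dice loss decreases as predictions move toward the truth", {
  set.seed(22)
  g <- rbinom(100, 1, 0.4)
  p0 <- runif(100, 0.05, 0.95)
  prev <- diceLoss(p0, g)
  for (lambda in seq(0.2, 1, by = 0.2)) {
    p <- (1 - lambda) * p0 + lambda * g
    cur <- diceLoss(p, g)
    expect_lt(cur, prev + 1e-12)
    prev <- cur
  }
})

test_that("recognition scores follow their defining ratios", {
  expect_equal(unname(recognitionScores(TP = 10, FP = 0, TN = 10, FN = 0)),
               c(100, 100, 0))
  expect_equal(unname(recognitionScores(TP = 9, FP = 2, TN = 8, FN = 1)),
               c(90, 80, 15))
  expect_equal(recognitionScores(TP = 0, FP = 2, TN = 8, FN = 10)[["SEN"]], 0)
  expect_error(recognitionScores(TP = 0, FP = 1, TN = 1, FN = 0), "SEN")
  expect_error(recognitionScores(TP = 1, FP = 0, TN = 0, FN = 1), "SPE")
})

test_that("the misclassified fraction equals 100 minus accuracy", {
  set.seed(23)
  for (rep in 1:200) {
    cts <- rmultinom(1, 50, c(0.3, 0.2, 0.3, 0.2))[, 1] + 1
    sc <- recognitionScores(TP = cts[1], FP = cts[2], TN = cts[3],
                            FN = cts[4])
    acc <- (cts[1] + cts[3]) / sum(cts) * 100
    expect_equal(sc[["FPF"]], 100 - acc, tolerance = 1e-12)
  }
})

test_that("ROC handles separation, chance and ties correctly", {
  r <- rocCurve(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0))
  expect_equal(r$auc, 1)
  expect_true(all(diff(r$points$fpr) >= 0) && all(diff(r$points$tpr) >= 0))
  expect_equal(r$points$fpr[1], 0)
  expect_equal(tail(r$points$tpr, 1), 1)
  # all-equal scores: single step from (0,0) to (1,1), area exactly 0.5
  expect_equal(rocCurve(rep(1, 10), rep(c(0, 1), 5))$auc, 0.5)
  expect_error(rocCurve(1:4, c(1, 1, 1, 1)), "both classes")
  # labels independent of scores: area ~ 0.5
  set.seed(24)
  s <- runif(4000); l <- rbinom(4000, 1, 0.5)
  expect_lt(abs(rocCurve(s, l)$auc - 0.5), 0.05)
})

test_that("ROC area matches an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(25)
  s <- rnorm(200)
  l <- rbinom(200, 1, plogis(s))
  ours <- rocCurve(s, l)$auc
  ref <- as.numeric(suppressMessages(pROC::auc(l, s,
                                               direction = "<",
                                               levels = c(0, 1))))
  expect_equal(ours, ref, tolerance = 1e-10)
})
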