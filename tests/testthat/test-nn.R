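# Network building blocks: attention gate, DAC block, receptive fields,
# sampling blocks, Mish, fusion weights, and whole-net contracts.

test_that("attention gate reproduces the scalar hand-worked value", {
  g <- newAttentionGate(1, 1, inter = 1)
  g$wx$w[] <- 1; g$wg$w[] <- 1; g$wg$b[] <- 0
  g$psi$w[] <- 1; g$psi$b[] <- 0
  x <- array(1, c(1, 1, 1)); gg <- array(1, c(1, 1, 1))
  out <- attentionGate(g, x, gg)
  # alpha = sigmoid(relu(1 + 1)) = sigmoid(2)
  expect_equal(attr(out, "alpha"), plogis(2), tolerance = 1e-12)
  expect_equal(as.numeric(out), plogis(2), tolerance = 1e-12)
})

test_that("attention coefficients live strictly in (0,1) and only attenuate", {
  set.seed(5)
  g <- newAttentionGate(3, 3)
  x <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
  gg <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
  out <- attentionGate(g, x, gg)
  a <- attr(out, "alpha")
  expect_true(all(a > 0 & a < 1))
  expect_true(all(abs(out) <= abs(x) + 1e-12))
})

test_that("attention gate saturates to identity/null in the bias limits", {
  set.seed(6)
  g <- newAttentionGate(2, 2, inter = 2)
  x <- array(rnorm(4 * 4 * 2), c(4, 4, 2))
  gg <- array(rnorm(4 * 4 * 2), c(4, 4, 2))
  g$psi$b[] <- 40                     # alpha -> 1
  expect_equal(as.numeric(attentionGate(g, x, gg)), as.numeric(x),
               tolerance = 1e-8)
  g$psi$b[] <- -40                    # alpha -> 0
  expect_equal(max(abs(attentionGate(g, x, gg))), 0, tolerance = 1e-8)
})

test_that("DAC block with zero weights is an exact residual passthrough", {
  blk <- newDacBlock(2)
  for (br in blk$branches) for (L in br) { L$w[] <- 0; L$b[] <- 0 }
  x <- array(rnorm(12 * 12 * 2), c(12, 12, 2))
  expect_equal(dacBlock(blk, x), x)
})

test_that("DAC block preserves spatial size for 64x64 and 200x200 inputs", {
  blk <- newDacBlock(1)
  for (s in c(64, 200)) {
    y <- dacBlock(blk, array(0.1, c(s, s, 1)))
    expect_equal(dim(y), c(s, s, 1L))
  }
})

test_that("receptive fields of the four DAC branches are exactly 3/7/9/19", {
  expect_identical(vapply(dacBranches(), receptiveField, integer(1)),
                   c(3L, 7L, 9L, 19L))
})

test_that("receptive-field arithmetic handles edge cases", {
  expect_equal(receptiveField(list()), 1L)
  expect_equal(receptiveField(list(c(1, 1))), 1L)
  expect_equal(receptiveField(list(c(3, 1))), 3L)
  expect_equal(receptiveField(list(c(3, 1), c(3, 3), c(3, 5), c(1, 1))), 19L)
  expect_error(receptiveField(list(c(4, 1))), "odd")
  expect_error(receptiveField(list(c(3, 0))), "dilation")
})

test_that("mish matches its defining formula, asymptotes and minimum", {
  expect_equal(mish(0), 0)
  expect_lt(abs(mish(10) - 10), 1e-3)
  expect_equal(mish(-5), -5 * tanh(log1p(exp(-5))), tolerance = 1e-12)
  expect_lt(abs(mish(-5) - (-0.03357)), 1e-4)
  # numerically stable at large magnitudes
  expect_equal(mish(500), 500)
  expect_equal(mish(-500), 0, tolerance = 1e-12)
  # single negative minimum ~ -0.3088 near x ~ -1.19; f >= -0.31 everywhere
  xx <- seq(-5, 0, by = 1e-4)
  mm <- xx * tanh(log(1 + exp(xx)))       # independent naive evaluation
  expect_lt(abs(min(mish(xx)) - min(mm)), 1e-9)
  expect_lt(abs(xx[which.min(mish(xx))] - (-1.19)), 0.01)
  expect_true(all(mish(seq(-50, 50, by = 0.01)) >= -0.31))
  # strictly increasing for x >= 0
  expect_true(all(diff(mish(seq(0, 10, by = 0.01))) > 0))
})

test_that("both networks keep output size equal to input size", {
  set.seed(7)
  pnet <- buildParenchymaNet(levels = 3, baseChannels = 2)
  nnet <- buildNoduleNet(levels = 3, baseChannels = 2, pyramidWidth = 2)
  for (s in list(c(16, 16), c(24, 40), c(50, 50), c(37, 61))) {
    for (net in list(pnet, nnet)) {
      p <- netForward(net, matrix(0.3, s[1], s[2]))
      expect_equal(unname(dim(p)), as.integer(s))
      expect_true(all(p > 0 & p < 1))
    }
  }
})

test_that("networks are pure functions in evaluation mode", {
  set.seed(8)
  net <- buildNoduleNet(levels = 3, baseChannels = 2, pyramidWidth = 2)
  x <- matrix(runif(32 * 32), 32, 32)
  expect_identical(netForward(net, x), netForward(net, x))
})

test_that("parenchyma net without autoPad names the required padding", {
  set.seed(9)
  net <- buildParenchymaNet(levels = 3, baseChannels = 2, autoPad = FALSE)
  expect_error(netForward(net, matrix(0, 30, 30)), "pad to 32x32")
})

test_that("nodule net rejects inputs smaller than its downsampling depth", {
  set.seed(10)
  net <- buildNoduleNet(levels = 3, baseChannels = 2, pyramidWidth = 2)
  expect_error(netForward(net, matrix(0, 2, 2)), "minimum size")
})

test_that("an all-zero input with a zeroed head gives a uniform 0.5 map", {
  set.seed(11)
  net <- buildNoduleNet(levels = 3, baseChannels = 2, pyramidWidth = 2)
  net$blocks$headOut$w[] <- 0
  net$blocks$headOut$b[] <- 0
  p <- netForward(net, matrix(0, 16, 16))
  expect_true(all(p == 0.5))
})

test_that("pyramid fusion weights are nonnegative and sum to ~1", {
  nets <- deskNoduleNets()
  nf <- asNamespace("noduleflow")
  for (net in nets) {
    fuses <- Filter(function(L) L$kind == "fuse",
                    nf$collectLayers(net$blocks))
    expect_gt(length(fuses), 0)
    for (L in fuses) {
      w <- nf$fuseWeights(L)
      expect_true(all(w >= 0))
      expect_equal(sum(w), 1, tolerance = 1e-3)
    }
  }
})

test_that("layer gradients agree with central finite differences", {
  nf <- asNamespace("noduleflow")
  set.seed(12)
  loss <- function(y) sum(y^2)
  # dilated conv
  L <- nf$newConv(2, 2, k = 3, dil = 2, act = "relu")
  x <- array(rnorm(6 * 6 * 2), c(6, 6, 2))
  y <- nf$convFwd(L, x)
  nf$zeroGrads(list(L))
  gx <- nf$convBwd(L, 2 * y)
  h <- 1e-6
  for (i in sample(length(x), 4)) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    num <- (loss(nf$convFwd(L, xp)) - loss(nf$convFwd(L, xm))) / (2 * h)
    expect_equal(num, gx[i], tolerance = 1e-4)
  }
  # transposed conv weight gradients
  Lt <- nf$newTConv(2, 2, k = 4, stride = 2, pad = 1)
  y <- nf$tconvFwd(Lt, x)
  nf$zeroGrads(list(Lt))
  nf$tconvBwd(Lt, 2 * y)
  for (i in sample(length(Lt$w), 4)) {
    w0 <- Lt$w[i]
    Lt$w[i] <- w0 + h; lp <- loss(nf$tconvFwd(Lt, x))
    Lt$w[i] <- w0 - h; lm <- loss(nf$tconvFwd(Lt, x))
    Lt$w[i] <- w0
    expect_equal((lp - lm) / (2 * h), Lt$gw[i], tolerance = 1e-4)
  }
})

test_that("whole-network gradients agree with finite differences", {
  nf <- asNamespace("noduleflow")
  set.seed(123)
  g <- matrix(rbinom(256, 1, 0.3), 16, 16)
  x <- matrix(runif(256), 16, 16)
  for (net in list(buildParenchymaNet(levels = 3, baseChannels = 3),
                   buildNoduleNet(levels = 3, baseChannels = 2,
                                  pyramidWidth = 3))) {
    lossNet <- function() {
      p <- netForward(net, x)
      nf$.diceGrad(p, g)$loss
    }
    layers <- nf$collectLayers(net$blocks)
    nf$zeroGrads(layers)
    p <- netForward(net, x)
    r <- nf$.diceGrad(p, g)
    nf$netBackward(net, r$gp)
    set.seed(99)
    h <- 1e-6
    for (L in sample(layers, 6)) {
      slot <- if (L$kind == "fuse") "u" else "w"
      i <- sample(length(L[[slot]]), 1)
      w0 <- L[[slot]][i]
      L[[slot]][i] <- w0 + h; lp <- lossNet()
      L[[slot]][i] <- w0 - h; lm <- lossNet()
      L[[slot]][i] <- w0
      ana <- if (slot == "u") L$gu[i] else L$gw[i]
      expect_equal((lp - lm) / (2 * h), ana, tolerance = 1e-3)
    }
  }
})
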