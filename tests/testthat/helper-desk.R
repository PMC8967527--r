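# Shared desk-scale fixtures: small trained networks and feature tables are
# expensive, so they are trained lazily on first use and cached for the
# whole test session. All sizes/seeds here are the package's documented
# desk-scale study conditions.

.deskCache <- new.env(parent = emptyenv())

# Attention U-Net trained on 40 parenchyma slices (64x64), reduced channels.
deskParenchymaNet <- function() {
  if (is.null(.deskCache$pnet)) {
    train <- phantomSliceSet(40, size = 64, seed = 100)
    set.seed(11)
    net <- buildParenchymaNet(levels = 3, baseChannels = 4)
    r <- trainSegmenter(net, train, epochs = 30, lr = 1e-3, batchSize = 8,
                        seed = 11)
    .deskCache$pnet <- net
    .deskCache$pnetHistory <- r$history
    .deskCache$pnetTrain <- train
  }
  .deskCache$pnet
}

deskParenchymaHistory <- function() {
  deskParenchymaNet()
  .deskCache$pnetHistory
}

deskParenchymaTrain <- function() {
  deskParenchymaNet()
  .deskCache$pnetTrain
}

# Per-position nodule networks trained on 8 single-nodule phantoms.
deskNoduleNets <- function() {
  if (is.null(.deskCache$nnets)) {
    trainPh <- lapply(1:8, function(i) nodulePhantom(seed = 200 + i))
    nets <- list()
    for (p in c("axial", "coronal", "sagittal")) {
      pairs <- do.call(c, lapply(seq_along(trainPh), function(i)
        noduleSliceSet(trainPh[[i]], p, negatives = 2, seed = i)))
      set.seed(42)
      net <- buildNoduleNet(levels = 3, baseChannels = 4, pyramidWidth = 8)
      trainSegmenter(net, pairs, epochs = 12, lr = 2e-3, batchSize = 8,
                     seed = 42)
      nets[[p]] <- net
    }
    .deskCache$nnets <- nets
  }
  .deskCache$nnets
}

# Feature table for 60 synthetic nodules (30 spiculated / 30 smooth).
deskSignData <- function() {
  if (is.null(.deskCache$sign)) {
    feats <- list(); labs <- integer(0)
    for (i in 1:60) {
      spic <- i <= 30
      ph <- nodulePhantom(seed = 500 + i, shape = c(32L, 48L, 48L),
                          spiculated = spic)
      cands <- screenCandidates(ph$noduleMask, c(1, 1, 1), returnAll = TRUE)
      feats[[i]] <- extractFeatures(ph$volume, cands[[1]])
      labs[i] <- as.integer(spic)
    }
    .deskCache$sign <- list(X = do.call(rbind, feats), y = labs)
  }
  .deskCache$sign
}

# Analytic cylinder/sphere masks for the multiposition disambiguation check.
analyticCylSphere <- function(shape = c(48L, 64L, 64L)) {
  arr <- array(FALSE, shape)
  gz <- slice.index(arr, 1); gy <- slice.index(arr, 2); gx <- slice.index(arr, 3)
  cyl <- (gy - 20)^2 + (gx - 20)^2 <= 2^2 & gz >= 5 & gz <= 44
  sph <- (gz - 24)^2 + (gy - 45)^2 + (gx - 45)^2 <= 4^2
  list(cyl = cyl, sph = sph)
}
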