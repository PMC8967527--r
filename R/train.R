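# Training loop (Adam on the Dice loss) and single-file checkpoints.

#' @noRd
.diceGrad <- function(p, g, eps = 1) {
  num <- 2 * sum(p * g)
  den <- sum(p^2) + sum(g^2) + eps
  loss <- 1 - num / den
  gp <- -(2 * g) / den + (num / den^2) * 2 * p
  list(loss = loss, gp = gp)
}

#' Train a segmentation network with the Dice loss
#'
#' Minimizes the soft Dice loss
#' \eqn{1 - 2\sum p_i g_i / (\sum p_i^2 + \sum g_i^2 + \epsilon)}
#' with Adam. Training is deterministic for a fixed `seed` on one machine:
#' the only stochastic ingredient is the minibatch shuffle.
#'
#' @param net a network from [buildParenchymaNet()] or [buildNoduleNet()]
#'   (modified in place and also returned).
#' @param data list of training pairs, each `list(x = <H x W matrix of
#'   intensities in [0,1]>, y = <H x W binary mask>)`.
#' @param epochs number of passes over the data.
#' @param lr Adam learning rate; `lr = 0` leaves the weights unchanged.
#' @param batchSize minibatch size (gradients averaged within a batch).
#' @param seed integer seed for the shuffle; `NULL` uses the current RNG
#'   state.
#' @param verbose print the per-epoch mean loss.
#' @return invisibly, `list(net, history)` where `history` is a data frame
#'   with columns `epoch` and `loss` (mean Dice loss that epoch).
#' @export
trainSegmenter <- function(net, data, epochs = 30L, lr = 1e-3,
                           batchSize = 8L, seed = NULL, verbose = FALSE) {
  stopifnot(inherits(net, "noduleflowNet"))
  if (length(data) == 0L) stop("no training pairs supplied")
  fg <- vapply(data, function(d) sum(d$y) > 0, logical(1))
  if (!any(fg)) {
    stop("all training masks are background-only; nothing to segment")
  }
  if (!is.null(seed)) set.seed(seed)
  layers <- collectLayers(net$blocks)
  state <- adamInit(layers)
  t <- 0L
  history <- numeric(epochs)
  n <- length(data)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    losses <- numeric(0)
    for (start in seq(1L, n, by = batchSize)) {
      idx <- ord[start:min(start + batchSize - 1L, n)]
      zeroGrads(layers)
      for (i in idx) {
        p <- netForward(net, data[[i]]$x)
        r <- .diceGrad(p, data[[i]]$y)
        losses <- c(losses, r$loss)
        netBackward(net, r$gp / length(idx))
      }
      if (lr > 0) {
        t <- t + 1L
        state <- adamStep(layers, state, t, lr)
      }
    }
    history[ep] <- mean(losses)
    if (verbose) message(sprintf("epoch %d: dice loss %.4f", ep, history[ep]))
  }
  invisible(list(net = net,
                 history = data.frame(epoch = seq_len(epochs),
                                      loss = history)))
}

#' Save / load a network checkpoint
#'
#' A checkpoint is a single RDS file holding the architecture configuration
#' and every parameter array, so `loadNet(saveNet(net, f))` reconstructs a
#' functionally identical network.
#'
#' @param net a network object.
#' @param path file path for the checkpoint.
#' @return `saveNet` returns `path` invisibly; `loadNet` returns the network.
#' @export
saveNet <- function(net, path) {
  stopifnot(inherits(net, "noduleflowNet"))
  layers <- collectLayers(net$blocks)
  params <- lapply(layers, function(L) {
    if (L$kind == "fuse") list(u = L$u) else list(w = L$w, b = L$b)
  })
  cfg <- net[c("arch", "levels", "baseChannels", "inChannels")]
  if (net$arch == "nodule") cfg$pyramidWidth <- net$pyramidWidth
  if (net$arch == "parenchyma") cfg$autoPad <- net$autoPad
  saveRDS(list(config = cfg, params = params), path)
  invisible(path)
}

#' @rdname saveNet
#' @export
loadNet <- function(path) {
  ck <- readRDS(path)
  cfg <- ck$config
  net <- if (cfg$arch == "parenchyma") {
    buildParenchymaNet(cfg$levels, cfg$baseChannels, cfg$inChannels,
                       cfg$autoPad)
  } else {
    buildNoduleNet(cfg$levels, cfg$baseChannels, cfg$pyramidWidth,
                   cfg$inChannels)
  }
  layers <- collectLayers(net$blocks)
  stopifnot(length(layers) == length(ck$params))
  for (i in seq_along(layers)) {
    L <- layers[[i]]; p <- ck$params[[i]]
    if (L$kind == "fuse") L$u <- p$u else { L$w <- p$w; L$b <- p$b }
  }
  net
}
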