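# Attention-gated encoder-decoder for lung-parenchyma segmentation:
# per-level double convolutions, multiscale parallel sampling blocks for the
# scale changes, a dense atrous convolution bottleneck, and attention gates
# on every skip connection. The head is a 1x1 convolution + sigmoid, so the
# network emits a per-pixel probability map the size of its input.

#' Build the attention-gated parenchyma segmentation network
#'
#' Encoder-decoder with `levels` resolution levels. Scale changes use
#' multiscale parallel (transposed-)convolution sampling blocks, the
#' bottleneck is a dense atrous convolution block (receptive fields
#' 3/7/9/19), and every skip connection passes through an additive attention
#' gate before concatenation. Output is a probability map the same spatial
#' size as the input.
#'
#' @param levels number of resolution levels (>= 2); default 4.
#' @param baseChannels channels at the first level; doubled per level.
#' @param inChannels input channels (1 for CT slices).
#' @param autoPad if `TRUE` (default) inputs whose sides are not divisible by
#'   `2^(levels-1)` are edge-padded internally and the output cropped back;
#'   if `FALSE` such inputs raise an error naming the required padding.
#' @return a network object; apply it with [netForward()] and train it with
#'   [trainSegmenter()].
#' @examples
#' set.seed(1)
#' net <- buildParenchymaNet(levels = 2, baseChannels = 2)
#' p <- netForward(net, matrix(0, 16, 16))
#' stopifnot(dim(p) == c(16, 16), all(p > 0 & p < 1))
#' @export
buildParenchymaNet <- function(levels = 4L, baseChannels = 16L,
                               inChannels = 1L, autoPad = TRUE) {
  stopifnot(levels >= 2L, baseChannels >= 1L)
  ch <- baseChannels * 2L^(seq_len(levels) - 1L)
  enc <- lapply(seq_len(levels), function(i) {
    cin <- if (i == 1L) inChannels else ch[i - 1L]
    list(c1 = newConv(cin, ch[i], act = "relu"),
         c2 = newConv(ch[i], ch[i], act = "relu"))
  })
  down <- lapply(seq_len(levels - 1L), function(i) newDownBlock(ch[i], ch[i]))
  dac <- newDacBlock(ch[levels])
  up <- lapply(seq_len(levels - 1L), function(i) newUpBlock(ch[i + 1L], ch[i]))
  ag <- lapply(seq_len(levels - 1L), function(i) newAttentionGate(ch[i], ch[i]))
  dec <- lapply(seq_len(levels - 1L), function(i) {
    list(c1 = newConv(2L * ch[i], ch[i], act = "relu"),
         c2 = newConv(ch[i], ch[i], act = "relu"))
  })
  head <- newConv(ch[1], 1L, k = 1L, act = "linear")
  net <- list(arch = "parenchyma", levels = levels,
              baseChannels = baseChannels, inChannels = inChannels,
              autoPad = autoPad, mult = 2L^(levels - 1L),
              blocks = list(enc = enc, down = down, dac = dac, up = up,
                            ag = ag, dec = dec, head = head),
              env = new.env(parent = emptyenv()))
  class(net) <- "noduleflowNet"
  net
}

#' @noRd
.parenchymaFwd <- function(net, x) {
  b <- net$blocks
  x <- .as3d(x)
  H <- dim(x)[1]; W <- dim(x)[2]
  if ((H %% net$mult != 0L || W %% net$mult != 0L) && !net$autoPad) {
    stop(sprintf(
      "input %dx%d not divisible by %d; pad to %dx%d or enable autoPad",
      H, W, net$mult, ceiling(H / net$mult) * net$mult,
      ceiling(W / net$mult) * net$mult))
  }
  xp <- padToMultiple(x, net$mult)
  skips <- vector("list", net$levels - 1L)
  h <- xp
  for (i in seq_len(net$levels)) {
    h <- convFwd(b$enc[[i]]$c1, h)
    h <- convFwd(b$enc[[i]]$c2, h)
    if (i < net$levels) {
      skips[[i]] <- h
      h <- downBlockFwd(b$down[[i]], h)
    }
  }
  h <- dacBlock(b$dac, h)
  for (i in rev(seq_len(net$levels - 1L))) {
    h <- upBlockFwd(b$up[[i]], h)
    gated <- attentionGate(b$ag[[i]], skips[[i]], h)
    h2 <- array(c(h, gated), dim = c(dim(h)[1:2], dim(h)[3] + dim(gated)[3]))
    h <- convFwd(b$dec[[i]]$c1, h2)
    h <- convFwd(b$dec[[i]]$c2, h)
  }
  z <- convFwd(b$head, h)
  p <- 1 / (1 + exp(-z))
  net$env$padH <- dim(xp)[1]; net$env$padW <- dim(xp)[2]
  net$env$H <- H; net$env$W <- W
  net$env$p <- p
  cropTo(p[, , 1], H, W)
}

#' @noRd
.parenchymaBwd <- function(net, gp) {
  b <- net$blocks
  e <- net$env
  p <- e$p
  gpFull <- zeroPadTo(gp, e$padH, e$padW)
  gz <- gpFull * p * (1 - p)
  g <- convBwd(b$head, gz)
  gSkip <- vector("list", net$levels - 1L)
  for (i in seq_len(net$levels - 1L)) {
    g <- convBwd(b$dec[[i]]$c2, g)
    g <- convBwd(b$dec[[i]]$c1, g)
    ch <- dim(g)[3] %/% 2L
    gH <- g[, , seq_len(ch), drop = FALSE]
    gGated <- g[, , ch + seq_len(ch), drop = FALSE]
    r <- attentionGateBwd(b$ag[[i]], gGated)
    gSkip[[i]] <- r$gx
    g <- upBlockBwd(b$up[[i]], gH + r$gg)
  }
  g <- dacBlockBwd(b$dac, g)
  g <- convBwd(b$enc[[net$levels]]$c2, g)
  g <- convBwd(b$enc[[net$levels]]$c1, g)
  for (i in rev(seq_len(net$levels - 1L))) {
    g <- downBlockBwd(b$down[[i]], g)
    g <- g + gSkip[[i]]
    g <- convBwd(b$enc[[i]]$c2, g)
    g <- convBwd(b$enc[[i]]$c1, g)
  }
  invisible(g)
}

#' Run a network forward
#'
#' Applies a network built by [buildParenchymaNet()] or [buildNoduleNet()] to
#' a single 2D slice and returns the per-pixel probability map. Evaluation is
#' deterministic: identical weights and input give identical output.
#'
#' @param net a network object.
#' @param x numeric matrix (H x W) or H x W x C array.
#' @return numeric matrix of probabilities in (0,1), same spatial size as
#'   `x`.
#' @export
netForward <- function(net, x) {
  stopifnot(inherits(net, "noduleflowNet"))
  switch(net$arch,
    parenchyma = .parenchymaFwd(net, x),
    nodule = .noduleFwd(net, x),
    stop("unknown architecture: ", net$arch)
  )
}

#' @noRd
netBackward <- function(net, gp) {
  switch(net$arch,
    parenchyma = .parenchymaBwd(net, gp),
    nodule = .noduleBwd(net, gp),
    stop("unknown architecture: ", net$arch)
  )
}

#' @exportS3Method base::print
print.noduleflowNet <- function(x, ...) {
  layers <- collectLayers(x$blocks)
  npar <- sum(vapply(layers, function(L) {
    if (L$kind == "fuse") length(L$u) else length(L$w) + length(L$b)
  }, numeric(1)))
  cat(sprintf("<noduleflow %s network: %d levels, base %d channels, %d parameters>\n",
              x$arch, x$levels, x$baseChannels, npar))
  invisible(x)
}
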