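# Five-level same-size U-Net with Mish activation and a bidirectional
# enhanced feature pyramid. The encoder yields one feature map per
# resolution level; 1x1 lateral projections bring them to a common pyramid
# width; a top-down pass then a bottom-up pass fuse features across scales
# with fast normalized fusion weights; a light decoder consumes the enhanced
# pyramid as skip connections and emits a probability map the same size as
# the input (edge padding everywhere, no cropping of feature maps).

#' Mish activation
#'
#' Smooth non-monotonic activation \eqn{f(x) = x \tanh(\ln(1+e^x))},
#' evaluated with a numerically stable softplus so large magnitudes do not
#' overflow. \eqn{f(0)=0}, \eqn{f(x)\to x} for large positive `x`, and the
#' function has a single negative minimum of about -0.3088 near
#' \eqn{x \approx -1.19}.
#'
#' @param x numeric vector, matrix or array.
#' @return object of the same shape with Mish applied elementwise.
#' @examples
#' mish(0)            # 0
#' mish(10)           # ~10
#' mish(-5)           # ~ -0.0336
#' @export
mish <- function(x) {
  sp <- ifelse(x > 20, x, log1p(exp(pmin(x, 20))))
  x * tanh(sp)
}

#' @noRd
mishGrad <- function(x) {
  sp <- ifelse(x > 20, x, log1p(exp(pmin(x, 20))))
  t <- tanh(sp)
  t + x * (1 - t^2) * stats::plogis(x)
}

#' Build the multiposition nodule segmentation network
#'
#' Same-size U-Net of `levels` resolution levels (5 by default) with Mish
#' activations and a bidirectional enhanced feature pyramid between encoder
#' and decoder. All convolutions use edge padding so the output probability
#' map has exactly the input's spatial size; inputs not divisible by
#' `2^(levels-1)` are padded internally and cropped back.
#'
#' @param levels resolution levels; 5 in the full model, >= 3 accepted for
#'   reduced test configurations.
#' @param baseChannels encoder channels at full resolution; doubled per
#'   level.
#' @param pyramidWidth channel width of the feature pyramid; default
#'   `2 * baseChannels`.
#' @param inChannels input channels.
#' @return a network object for [netForward()] / [trainSegmenter()].
#' @export
buildNoduleNet <- function(levels = 5L, baseChannels = 16L,
                           pyramidWidth = 2L * baseChannels,
                           inChannels = 1L) {
  stopifnot(levels >= 3L, baseChannels >= 1L, pyramidWidth >= 1L)
  ch <- baseChannels * 2L^(seq_len(levels) - 1L)
  P <- as.integer(pyramidWidth)
  enc <- lapply(seq_len(levels), function(i) {
    cin <- if (i == 1L) inChannels else ch[i - 1L]
    list(c1 = newConv(cin, ch[i], act = "mish"),
         c2 = newConv(ch[i], ch[i], act = "mish"))
  })
  pool <- lapply(seq_len(levels - 1L), function(i) newPool())
  lat <- lapply(seq_len(levels), function(i)
    newConv(ch[i], P, k = 1L, act = "linear"))
  tdUp <- lapply(seq_len(levels - 1L), function(i)
    newTConv(P, P, k = 2L, stride = 2L))
  tdFuse <- lapply(seq_len(levels - 1L), function(i) newFuse(2L))
  tdConv <- lapply(seq_len(levels - 1L), function(i)
    newConv(P, P, act = "mish"))
  buPool <- c(list(NULL), lapply(2:levels, function(i) newPool()))
  buFuse <- c(list(NULL), lapply(2:levels, function(i)
    newFuse(if (i < levels) 3L else 2L)))
  buConv <- c(list(NULL), lapply(2:levels, function(i)
    newConv(P, P, act = "mish")))
  decUp <- lapply(seq_len(levels - 1L), function(i)
    newTConv(P, P, k = 2L, stride = 2L))
  decConv <- lapply(seq_len(levels - 1L), function(i)
    newConv(2L * P, P, act = "mish"))
  headConv <- newConv(P, P, act = "mish")
  headOut <- newConv(P, 1L, k = 1L, act = "linear")
  net <- list(arch = "nodule", levels = levels, baseChannels = baseChannels,
              pyramidWidth = P, inChannels = inChannels,
              mult = 2L^(levels - 1L),
              blocks = list(enc = enc, pool = pool, lat = lat, tdUp = tdUp,
                            tdFuse = tdFuse, tdConv = tdConv, buPool = buPool,
                            buFuse = buFuse, buConv = buConv, decUp = decUp,
                            decConv = decConv, headConv = headConv,
                            headOut = headOut),
              env = new.env(parent = emptyenv()))
  class(net) <- "noduleflowNet"
  net
}

#' @noRd
.noduleFwd <- function(net, x) {
  b <- net$blocks
  x <- .as3d(x)
  H <- dim(x)[1]; W <- dim(x)[2]
  if (H < net$mult || W < net$mult) {
    stop(sprintf("input %dx%d too small for %d levels; minimum size is %dx%d",
                 H, W, net$levels, net$mult, net$mult))
  }
  xp <- padToMultiple(x, net$mult)
  L <- net$levels
  encOut <- vector("list", L)
  h <- xp
  for (i in seq_len(L)) {
    h <- convFwd(b$enc[[i]]$c1, h)
    h <- convFwd(b$enc[[i]]$c2, h)
    encOut[[i]] <- h
    if (i < L) h <- poolFwd(b$pool[[i]], h)
  }
  lat <- lapply(seq_len(L), function(i) convFwd(b$lat[[i]], encOut[[i]]))
  td <- vector("list", L)
  td[[L]] <- lat[[L]]
  for (i in rev(seq_len(L - 1L))) {
    u <- tconvFwd(b$tdUp[[i]], td[[i + 1L]])
    f <- fuseFwd(b$tdFuse[[i]], list(lat[[i]], u))
    td[[i]] <- convFwd(b$tdConv[[i]], f)
  }
  bu <- vector("list", L)
  bu[[1]] <- td[[1]]
  for (i in 2:L) {
    d <- poolFwd(b$buPool[[i]], bu[[i - 1L]])
    ins <- if (i < L) list(lat[[i]], td[[i]], d) else list(lat[[i]], d)
    f <- fuseFwd(b$buFuse[[i]], ins)
    bu[[i]] <- convFwd(b$buConv[[i]], f)
  }
  dcd <- vector("list", L)
  dcd[[L]] <- bu[[L]]
  for (i in rev(seq_len(L - 1L))) {
    u <- tconvFwd(b$decUp[[i]], dcd[[i + 1L]])
    h2 <- array(c(u, bu[[i]]), dim = c(dim(u)[1:2], 2L * dim(u)[3]))
    dcd[[i]] <- convFwd(b$decConv[[i]], h2)
  }
  hh <- convFwd(b$headConv, dcd[[1]])
  z <- convFwd(b$headOut, hh)
  p <- 1 / (1 + exp(-z))
  net$env$padH <- dim(xp)[1]; net$env$padW <- dim(xp)[2]
  net$env$p <- p
  cropTo(p[, , 1], H, W)
}

#' @noRd
.addInto <- function(acc, g) if (is.null(acc)) g else acc + g

#' @noRd
.noduleBwd <- function(net, gp) {
  b <- net$blocks
  e <- net$env
  L <- net$levels
  p <- e$p
  gz <- zeroPadTo(gp, e$padH, e$padW) * p * (1 - p)
  g <- convBwd(b$headOut, gz)
  g <- convBwd(b$headConv, g)
  gD <- vector("list", L)
  gD[[1]] <- g
  gB <- vector("list", L)
  for (i in seq_len(L - 1L)) {
    g <- convBwd(b$decConv[[i]], gD[[i]])
    P <- dim(g)[3] %/% 2L
    gU <- g[, , seq_len(P), drop = FALSE]
    gB[[i]] <- .addInto(gB[[i]], g[, , P + seq_len(P), drop = FALSE])
    gD[[i + 1L]] <- .addInto(gD[[i + 1L]], tconvBwd(b$decUp[[i]], gU))
  }
  gB[[L]] <- .addInto(gB[[L]], gD[[L]])
  gLat <- vector("list", L)
  gT <- vector("list", L)
  for (i in rev(2:L)) {
    g <- convBwd(b$buConv[[i]], gB[[i]])
    gs <- fuseBwd(b$buFuse[[i]], g)
    if (i < L) {
      gLat[[i]] <- .addInto(gLat[[i]], gs[[1]])
      gT[[i]] <- .addInto(gT[[i]], gs[[2]])
      gd <- gs[[3]]
    } else {
      gLat[[i]] <- .addInto(gLat[[i]], gs[[1]])
      gd <- gs[[2]]
    }
    gB[[i - 1L]] <- .addInto(gB[[i - 1L]], poolBwd(b$buPool[[i]], gd))
  }
  gT[[1]] <- .addInto(gT[[1]], gB[[1]])
  for (i in seq_len(L - 1L)) {
    g <- convBwd(b$tdConv[[i]], gT[[i]])
    gs <- fuseBwd(b$tdFuse[[i]], g)
    gLat[[i]] <- .addInto(gLat[[i]], gs[[1]])
    gT[[i + 1L]] <- .addInto(gT[[i + 1L]], tconvBwd(b$tdUp[[i]], gs[[2]]))
  }
  gLat[[L]] <- .addInto(gLat[[L]], gT[[L]])
  gEnc <- vector("list", L)
  for (i in seq_len(L)) gEnc[[i]] <- convBwd(b$lat[[i]], gLat[[i]])
  gPoolBack <- vector("list", L)
  g <- NULL
  for (i in rev(seq_len(L))) {
    g <- gEnc[[i]]
    # gradient arriving from the pooled path into the level above
    if (i < L) g <- g + gPoolBack[[i]]
    g <- convBwd(b$enc[[i]]$c2, g)
    g <- convBwd(b$enc[[i]]$c1, g)
    if (i > 1L) gPoolBack[[i - 1L]] <- poolBwd(b$pool[[i - 1L]], g)
  }
  invisible(g)
}
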